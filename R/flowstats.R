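new_ploidy_histogram <- function(ploidy_c, n) {
  stopifnot(length(ploidy_c) == length(n))
  out <- tibble(ploidy_c = as.double(ploidy_c), n = as.double(n)) |>
    arrange(.data$ploidy_c) |>
    mutate(fraction = .data$n / sum(.data$n))
  structure(out, class = c("ploidy_histogram", class(out)),
            n_events = sum(n))
}

# Histogram straight from a vector of power-of-two ploidies.
ploidy_histogram_values <- function(ploidy) {
  k <- as.integer(round(log2(ploidy)))
  k0 <- min(k)
  counts <- tabulate(k - k0 + 1L)
  keep <- counts > 0
  new_ploidy_histogram(2^(k0 + which(keep) - 1L), counts[keep])
}

peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    base <- -Inf
    for (side in c(-1L, 1L)) {
      i <- p
      low <- y[p]
      repeat {
        i <- i + side
        if (i < 1 || i > length(y)) break
        if (y[i] > y[p]) break
        low <- min(low, y[i])
      }
      base <- max(base, low)
    }
    y[p] - base
  }, numeric(1))
}

#' Calibrate the DNA-content reference from a mixed-stage sample
#'
#' Ploidy peaks in DAPI intensity sit at 2-fold spacings, so on a log2 axis
#' they are unit-spaced. The reference (1C-equivalent) intensity is taken as
#' the mode of the lowest significant peak of a kernel-density estimate of
#' log2 intensity. A peak is a local maximum whose prominence is at least
#' `prominence` times the global density maximum. Peaks whose offsets from
#' the lowest peak deviate from integers by more than 0.2 log2 units raise
#' a warning with diagnostics.
#'
#' @param events Event table (data frame) with a strictly positive
#'   `dapi_intensity` column; typically a co-stained pool of all cycle
#'   stages.
#' @param prominence Minimum peak prominence, as a fraction of the global
#'   KDE maximum. Default 0.05.
#' @param bin_tolerance Half-width of the ploidy bins in log2 units, stored
#'   on the calibration for downstream binning (0 < tol <= 0.5).
#' @param bw Bandwidth rule for [stats::density()] (Silverman's `"nrd0"` by
#'   default).
#' @param max_bw Upper cap on the KDE bandwidth, in log2 units (default
#'   0.25, a quarter of the known unit peak spacing). Whole-sample
#'   bandwidth rules oversmooth many-peaked mixtures and bias the edge
#'   peak inward; the cap keeps the peaks resolved.
#'
#' @return An object of class `ploidy_calibration`: a list with
#'   `reference_intensity`, `bin_tolerance` and a `peaks` tibble
#'   (`log2_intensity`, `intensity`, `density`, `prominence`).
#' @examples
#' ev <- tibble::tibble(dapi_intensity = 100 * rep(c(1, 2, 4), each = 200) *
#'                        exp(rnorm(600, 0, 0.05)))
#' calibrate_reference(ev)$reference_intensity
#' @export
calibrate_reference <- function(events, prominence = 0.05,
                                bin_tolerance = 0.5, bw = "nrd0",
                                max_bw = 0.25) {
  stopifnot(is.data.frame(events), "dapi_intensity" %in% names(events))
  if (!(bin_tolerance > 0 && bin_tolerance <= 0.5)) {
    abort("`bin_tolerance` must be in (0, 0.5].",
          class = "coenocycle_invalid_input")
  }
  x <- events$dapi_intensity
  if (any(!is.finite(x) | x <= 0)) {
    abort("`dapi_intensity` must be strictly positive and finite.",
          class = "coenocycle_invalid_input")
  }
  h <- if (is.character(bw)) {
    switch(bw,
           nrd0 = stats::bw.nrd0(log2(x)),
           SJ = stats::bw.SJ(log2(x)),
           stats::bw.nrd0(log2(x)))
  } else {
    as.double(bw)
  }
  d <- density(log2(x), bw = min(h, max_bw))
  y <- d$y
  n <- length(y)
  cand <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  prom <- peak_prominence(y, cand)
  keep <- prom >= prominence * max(y)
  if (!any(keep)) {
    abort("No significant intensity peak found; cannot calibrate.",
          class = "coenocycle_calibration_failure")
  }
  peaks <- tibble(
    log2_intensity = d$x[cand[keep]],
    intensity = 2^d$x[cand[keep]],
    density = y[cand[keep]],
    prominence = prom[keep]
  ) |> arrange(.data$log2_intensity)

  offsets <- peaks$log2_intensity - peaks$log2_intensity[1]
  dev <- abs(offsets - round(offsets))
  if (any(dev > 0.2)) {
    warn(paste0(
      "Detected peaks are not spaced at ~1 log2-unit multiples ",
      "(max deviation ", format(max(dev), digits = 3),
      "); calibration may be unreliable. Peak log2 intensities: ",
      paste(format(peaks$log2_intensity, digits = 4), collapse = ", ")
    ), class = "coenocycle_calibration_warning")
  }

  structure(
    list(reference_intensity = 2^peaks$log2_intensity[1],
         bin_tolerance = bin_tolerance,
         peaks = peaks),
    class = "ploidy_calibration"
  )
}

#' @export
print.ploidy_calibration <- function(x, ...) {
  cat("<ploidy_calibration> reference intensity:",
      format(x$reference_intensity, digits = 5),
      "| bin tolerance:", x$bin_tolerance, "log2 units |",
      nrow(x$peaks), "peak(s)\n")
  invisible(x)
}

#' Assign events to discrete ploidy bins
#'
#' An event of intensity I belongs to bin `2^k` with
#' `k = round(log2(I / reference))`. Events whose log2 residual from the
#' nearest bin exceeds `bin_tolerance`, or that fall below the 1C bin
#' (k < 0), are flagged as debris — never silently dropped.
#'
#' @param events Event table with a positive `dapi_intensity` column.
#' @param cal A `ploidy_calibration` from [calibrate_reference()], or a
#'   positive number used directly as the reference intensity.
#' @param quiet Suppress the retained/debris count message.
#'
#' @return The input tibble with added columns `log2_ratio`, `ploidy_c`
#'   (NA for debris) and `debris` (logical), and an attribute
#'   `binning_counts = c(retained, debris)`.
#' @examples
#' ev <- tibble::tibble(dapi_intensity = c(100, 412, 145, 30))
#' assign_ploidy(ev, 100, quiet = TRUE)
#' @export
assign_ploidy <- function(events, cal, quiet = FALSE) {
  if (is.numeric(cal)) {
    cal <- list(reference_intensity = cal, bin_tolerance = 0.5)
  }
  stopifnot(is.data.frame(events), "dapi_intensity" %in% names(events),
            cal$reference_intensity > 0)
  r <- log2(events$dapi_intensity / cal$reference_intensity)
  k <- round(r)
  debris <- abs(r - k) > cal$bin_tolerance | k < 0
  out <- as_tibble(events) |>
    mutate(log2_ratio = r,
           ploidy_c = ifelse(debris, NA_real_, 2^k),
           debris = debris)
  counts <- c(retained = sum(!debris), debris = sum(debris))
  if (!quiet) {
    inform(sprintf("assign_ploidy: %d events retained, %d flagged as debris.",
                   counts[["retained"]], counts[["debris"]]))
  }
  attr(out, "binning_counts") <- counts
  out
}

#' Ploidy histogram of binned events
#'
#' Fractions of retained (non-debris) events per discrete ploidy bin, for
#' a single time point / condition. Fractions sum to one.
#'
#' @param binned Output of [assign_ploidy()] (or any data frame with a
#'   `ploidy_c` column and optionally a logical `debris` column), already
#'   restricted to one time point and condition.
#'
#' @return A tibble of class `ploidy_histogram` with columns `ploidy_c`,
#'   `n`, `fraction` and attribute `n_events`.
#' @examples
#' binned <- tibble::tibble(ploidy_c = c(2, 2, 4, 4), debris = FALSE)
#' ploidy_histogram(binned)
#' @export
ploidy_histogram <- function(binned) {
  stopifnot(is.data.frame(binned), "ploidy_c" %in% names(binned))
  p <- binned$ploidy_c
  if ("debris" %in% names(binned)) p <- p[!binned$debris]
  p <- p[!is.na(p)]
  if (length(p) == 0) {
    abort("All events are debris; cannot build a ploidy histogram.",
          class = "coenocycle_empty_histogram")
  }
  ploidy_histogram_values(p)
}

check_histogram <- function(hist) {
  stopifnot(is.data.frame(hist),
            all(c("ploidy_c", "fraction") %in% names(hist)))
  if (abs(sum(hist$fraction) - 1) > 1e-9 || any(hist$fraction < 0)) {
    abort("Histogram fractions must be non-negative and sum to 1.",
          class = "coenocycle_invalid_input")
  }
  hist
}

#' Log2 geometric mean of DNA content
#'
#' `sum(f_i * log2(x_i))` over the ploidy bins `x_i` with fractions `f_i`.
#'
#' @param hist A `ploidy_histogram` (or any data frame with `ploidy_c` and
#'   `fraction` columns summing to 1).
#' @return The log2 geometric mean, in log2 C units.
#' @examples
#' log2_geommean(tibble::tibble(ploidy_c = c(2, 4), fraction = c(.5, .5)))
#' @export
log2_geommean <- function(hist) {
  hist <- check_histogram(hist)
  sum(hist$fraction * log2(hist$ploidy_c))
}

#' Geometric-standard-deviation asynchrony of DNA content
#'
#' The population-asynchrony metric: the spread of log2 ploidy around the
#' log2 geometric mean, `sum(f_i * (log2(x_i) - log2(geommean))^2)`. In the
#' default `"sqrt"` mode the square root of this quantity is returned, so
#' the value is a standard deviation on the log2 scale (equal to the
#' per-event population SD of log2 ploidy); `"literal"` mode returns the
#' unrooted variance-like sum.
#'
#' @inheritParams log2_geommean
#' @param mode `"sqrt"` (default) or `"literal"`.
#' @return Non-negative asynchrony value in log2 units.
#' @examples
#' h <- tibble::tibble(ploidy_c = c(2, 4), fraction = c(.5, .5))
#' log2_gsd(h)                   # 0.5
#' log2_gsd(h, mode = "literal") # 0.25
#' @export
log2_gsd <- function(hist, mode = c("sqrt", "literal")) {
  mode <- match.arg(mode)
  hist <- check_histogram(hist)
  gm <- sum(hist$fraction * log2(hist$ploidy_c))
  v <- sum(hist$fraction * (log2(hist$ploidy_c) - gm)^2)
  if (mode == "sqrt") sqrt(v) else v
}

#' Per-time-point ploidy summaries of binned events
#'
#' Groups binned events by `condition` and `time_h` and computes, per
#' group, the number of retained events, the log2 geometric mean and the
#' log2 GSD asynchrony. An optional trim excludes bins whose fraction falls
#' below `trim_floor` before computing the GSD (the metric is sensitive to
#' outlier bins).
#'
#' @param binned Output of [assign_ploidy()] with `time_h` and `condition`
#'   columns.
#' @inheritParams log2_gsd
#' @param trim_floor Minimum bin fraction retained for the GSD (default 0:
#'   no trimming).
#' @return A tibble with columns `condition`, `time_h`, `n_events`,
#'   `log2_geommean`, `log2_gsd`.
#' @export
summarize_ploidy <- function(binned, mode = c("sqrt", "literal"),
                             trim_floor = 0) {
  mode <- match.arg(mode)
  stopifnot(all(c("ploidy_c", "time_h", "condition") %in% names(binned)))
  binned |>
    filter(!.data$debris) |>
    group_by(.data$condition, .data$time_h) |>
    group_modify(function(df, key) {
      h <- ploidy_histogram_values(df$ploidy_c)
      if (trim_floor > 0) {
        h <- h |> filter(.data$fraction >= trim_floor)
        h <- new_ploidy_histogram(h$ploidy_c, h$n)
      }
      tibble(n_events = nrow(df),
             log2_geommean = log2_geommean(h),
             log2_gsd = log2_gsd(h, mode = mode))
    }) |>
    ungroup()
}

#' Nuclear doubling time by log-linear regression
#'
#' Ordinary least squares of the log2 geometric mean of DNA content on
#' time, restricted to a fitting window (default 0–36 h, before burst).
#' The doubling time is the reciprocal of the slope; its standard error is
#' propagated from the slope SE by the delta method.
#'
#' @param series Data frame with columns `time_h` and `log2_geommean`
#'   (e.g. from [summarize_ploidy()]).
#' @param window Length-2 numeric, inclusive fitting window in hours.
#'
#' @return An object of class `doubling_time_fit` with elements `slope`
#'   (log2 C units per hour), `slope_se`, `doubling_time_h`,
#'   `doubling_time_se`, `window`, `n_points` and the underlying `lm` fit.
#'   Supports [tidy()] and [glance()].
#' @examples
#' s <- tibble::tibble(time_h = seq(0, 36, 3),
#'                     log2_geommean = 0.5 + seq(0, 36, 3) / 11)
#' fit_doubling_time(s)
#' @export
fit_doubling_time <- function(series, window = c(0, 36)) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "log2_geommean") %in% names(series)),
            length(window) == 2)
  sub <- series |>
    filter(.data$time_h >= window[1], .data$time_h <= window[2])
  if (nrow(sub) < 3) {
    abort("Need at least 3 time points inside the fitting window.",
          class = "coenocycle_invalid_input")
  }
  fit <- lm(log2_geommean ~ time_h, data = sub)
  sm <- quiet_lm_summary(fit)
  slope <- unname(coef(fit)["time_h"])
  slope_se <- sm$coefficients["time_h", "Std. Error"]
  if (!is.finite(slope) || slope <= 0) {
    abort("Fitted slope is not positive: the series is not growing.",
          class = "coenocycle_non_growing_series")
  }
  structure(
    list(slope = slope, slope_se = slope_se,
         doubling_time_h = 1 / slope,
         doubling_time_se = slope_se / slope^2,
         window = as.double(window), n_points = nrow(sub), fit = fit),
    class = "doubling_time_fit"
  )
}

#' @export
print.doubling_time_fit <- function(x, ...) {
  cat(sprintf(
    "<doubling_time_fit> doubling time %.2f h (slope %.4f +/- %.4f log2C/h, %d points in [%g, %g] h)\n",
    x$doubling_time_h, x$slope, x$slope_se, x$n_points,
    x$window[1], x$window[2]))
  invisible(x)
}

#' Increase of asynchrony relative to t = 0
#'
#' Subtracts the t = 0 log2(GSD) from every time point, so the series
#' starts at exactly 0 and measures the growth of population asynchrony.
#'
#' @param series Data frame with columns `time_h` and `log2_gsd`,
#'   containing a t = 0 row.
#' @return A tibble of class `asynchrony_series` with columns `time_h`,
#'   `log2_gsd`, `delta_log2gsd`.
#' @examples
#' delta_asynchrony(tibble::tibble(time_h = c(0, 24, 48),
#'                                 log2_gsd = c(0.4, 0.5, 0.7)))
#' @export
delta_asynchrony <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "log2_gsd") %in% names(series)))
  i0 <- which(abs(series$time_h) < 1e-9)
  if (length(i0) == 0) {
    abort("`series` must contain a t = 0 time point.",
          class = "coenocycle_invalid_input")
  }
  base <- series$log2_gsd[i0[1]]
  out <- as_tibble(series) |>
    mutate(delta_log2gsd = .data$log2_gsd - base) |>
    arrange(.data$time_h)
  structure(out, class = c("asynchrony_series", class(out)))
}

#' Upper bound on division-timing CV from simulated envelopes
#'
#' Compares an observed asynchrony-increase series against simulated
#' envelopes over a grid of CV values and returns the smallest CV whose
#' band is compatible with every observed value at every shared time point
#' at or after `start_time`. If no envelope qualifies, the largest grid CV
#' is returned with `bounded = FALSE`.
#'
#' With the default `sides = "upper"`, compatibility means the observed
#' increase of asynchrony never exceeds the envelope's upper edge
#' (mean + SD): the value is an upper bound on the division-timing CV, so
#' only excess asynchrony disqualifies an envelope. `sides = "both"`
#' additionally requires the observation to stay above the lower edge;
#' note that a single realization escapes its own matched-CV ± 1 SD band
#' frequently (per-time-point coverage of a replicate band is ~68%), so
#' the two-sided rule rarely certifies any envelope when bands are tight.
#'
#' @param observed An `asynchrony_series` from [delta_asynchrony()] (or any
#'   data frame with `time_h` and `delta_log2gsd`).
#' @param envelopes A list of [asynchrony_envelope()] objects (any order;
#'   sorted internally by CV).
#' @param start_time Earliest time point (hours) included in the
#'   containment check. Default 0.
#' @param sides `"upper"` (default): an envelope qualifies when the
#'   observation never exceeds its mean + SD edge; `"both"`: the
#'   observation must lie inside the full mean ± SD band.
#'
#' @return A one-row tibble with columns `cv` and `bounded`.
#' @export
cv_upper_bound <- function(observed, envelopes, start_time = 0,
                           sides = c("upper", "both")) {
  sides <- match.arg(sides)
  stopifnot(is.data.frame(observed),
            all(c("time_h", "delta_log2gsd") %in% names(observed)))
  if (inherits(envelopes, "asynchrony_envelope")) {
    envelopes <- list(envelopes)
  }
  if (length(envelopes) == 0) {
    abort("`envelopes` must contain at least one envelope.",
          class = "coenocycle_invalid_input")
  }
  cvs <- vapply(envelopes, function(e) attr(e, "cv"), numeric(1))
  envelopes <- envelopes[order(cvs)]
  cvs <- sort(cvs)
  obs <- observed |> filter(.data$time_h >= start_time)
  for (i in seq_along(envelopes)) {
    env <- envelopes[[i]]
    m <- match(round(obs$time_h, 9), round(env$time_h, 9))
    if (anyNA(m)) {
      abort("Observed time points must be a subset of the envelope grid.",
            class = "coenocycle_invalid_input")
    }
    lo <- env$mean_delta_log2gsd[m] - env$sd_delta_log2gsd[m]
    hi <- env$mean_delta_log2gsd[m] + env$sd_delta_log2gsd[m]
    ok <- obs$delta_log2gsd <= hi
    if (sides == "both") ok <- ok & obs$delta_log2gsd >= lo
    if (all(ok)) {
      return(tibble(cv = cvs[i], bounded = TRUE))
    }
  }
  tibble(cv = cvs[length(cvs)], bounded = FALSE)
}
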
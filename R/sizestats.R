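#' Volume of a spherical cell
#'
#' Cells are spherical, so volume is `(4/3) * pi * r^3`.
#'
#' @param radius Radius in micrometers (vectorized, all > 0).
#' @return Volume in cubic micrometers.
#' @examples
#' sphere_volume(1)   # 4 * pi / 3
#' sphere_volume(10)
#' @export
sphere_volume <- function(radius) {
  if (any(!is.finite(radius) | radius <= 0)) {
    abort("`radius` must be strictly positive.",
          class = "coenocycle_invalid_input")
  }
  (4 / 3) * pi * radius^3
}

#' @rdname sphere_volume
#' @param volume Volume in cubic micrometers (> 0).
#' @export
sphere_radius <- function(volume) {
  if (any(!is.finite(volume) | volume <= 0)) {
    abort("`volume` must be strictly positive.",
          class = "coenocycle_invalid_input")
  }
  (3 * volume / (4 * pi))^(1 / 3)
}

#' @rdname sphere_volume
#' @param perimeter Measured cell perimeter in micrometers (> 0); the
#'   radius is `perimeter / (2 * pi)`.
#' @export
perimeter_to_radius <- function(perimeter) {
  if (any(!is.finite(perimeter) | perimeter <= 0)) {
    abort("`perimeter` must be strictly positive.",
          class = "coenocycle_invalid_input")
  }
  perimeter / (2 * pi)
}

#' Derive volume and nuclei-to-volume ratio for microscopy records
#'
#' Takes per-cell microscopy records (nuclei count and radius) and adds the
#' spherical volume (`volume_um3`) and the nuclei-to-volume ratio
#' (`nuclei_per_um3`), the compactness measure that rises when cells grow
#' more slowly at unchanged nuclear content.
#'
#' @param cells Data frame with columns `n_nuclei` and `radius_um`.
#' @return The input as a tibble with `volume_um3` and `nuclei_per_um3`
#'   columns added.
#' @examples
#' nuclei_volume_ratio(tibble::tibble(n_nuclei = 8, radius_um = 10))
#' @export
nuclei_volume_ratio <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("n_nuclei", "radius_um") %in% names(cells)))
  as_tibble(cells) |>
    mutate(volume_um3 = sphere_volume(.data$radius_um),
           nuclei_per_um3 = .data$n_nuclei / .data$volume_um3)
}

#' Relative area of time-lapse series
#'
#' Normalizes each cell's area series to its area at t = 0, so every
#' series starts at exactly 1 and the value is a dimensionless growth
#' factor. Scale-invariant by construction.
#'
#' @param series Data frame with columns `cell_id`, `time_h`, `area_um2`
#'   (grouping columns such as `condition` are carried through).
#' @return A tibble with a `relative_area` column added.
#' @examples
#' s <- tibble::tibble(cell_id = 1, time_h = c(0, 12, 24),
#'                     area_um2 = c(100, 150, 220))
#' relative_area(s)
#' @export
relative_area <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("cell_id", "time_h", "area_um2") %in% names(series)))
  if (any(series$area_um2 <= 0)) {
    abort("Areas must be strictly positive.",
          class = "coenocycle_invalid_input")
  }
  out <- as_tibble(series) |>
    group_by(.data$cell_id) |>
    mutate(.a0 = .data$area_um2[match(TRUE, abs(.data$time_h) < 1e-9)]) |>
    ungroup()
  if (anyNA(out$.a0)) {
    abort("Every cell needs an area at t = 0 to normalize against.",
          class = "coenocycle_invalid_input")
  }
  out |>
    mutate(relative_area = .data$area_um2 / .data$.a0) |>
    select(-".a0")
}

# Exact null distribution of the rank-sum of n items chosen from the
# (doubled, hence integer) mid-rank scores: dynamic programme over
# subset sums. Returns the two-sided p for observed doubled rank-sum w2.
ranksum_exact_p <- function(scores2, n, w2) {
  total <- sum(scores2)
  f <- matrix(0, nrow = n + 1, ncol = total + 1)
  f[1, 1] <- 1
  for (s in scores2) {
    jmax <- min(n, nrow(f) - 1)
    for (j in jmax:1) {
      idx <- (s + 1):(total + 1)
      f[j + 1, idx] <- f[j + 1, idx] + f[j, idx - s]
    }
  }
  dist <- f[n + 1, ]
  tot <- sum(dist)
  sums <- 0:total
  p_le <- sum(dist[sums <= w2 + 1e-9]) / tot
  p_ge <- sum(dist[sums >= w2 - 1e-9]) / tot
  min(1, 2 * min(p_le, p_ge))
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Two-sided Mann–Whitney/Wilcoxon rank-sum test with mid-rank handling of
#' ties. For group sizes up to `exact_max` the p-value is exact, computed
#' by enumeration of the null distribution of the rank sum over all
#' subsets (a subset-sum dynamic programme, so ties are handled exactly);
#' for larger groups the normal approximation with continuity and tie
#' correction is used. The two-sided exact p is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param a,b Numeric vectors of measurements (both non-empty).
#' @param exact_max Largest per-group size for the exact path (default 20).
#'
#' @return A one-row tibble: `n_a`, `n_b`, `statistic` (Mann–Whitney U for
#'   group a), `p_value`, `method` ("exact" or "normal"), and `direction`
#'   (sign of the rank-sum shift of a relative to b: "a>b", "a<b" or
#'   "none").
#' @examples
#' compare_groups(c(1, 2, 3), c(10, 11, 12))  # p = 0.1 exact
#' @export
compare_groups <- function(a, b, exact_max = 20) {
  a <- as.double(a); b <- as.double(b)
  if (length(a) == 0 || length(b) == 0) {
    abort("Both samples must be non-empty.",
          class = "coenocycle_invalid_input")
  }
  n <- length(a); m <- length(b); N <- n + m
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  if (n <= exact_max && m <= exact_max) {
    p <- ranksum_exact_p(as.integer(round(2 * r)), n, round(2 * w))
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n * m / 12 * ((N + 1) - tie_term))
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  direction <- if (w > mu) "a>b" else if (w < mu) "a<b" else "none"
  tibble(n_a = n, n_b = m,
         statistic = w - n * (n + 1) / 2,  # Mann-Whitney U of group a
         p_value = p, method = method, direction = direction)
}

#' Side-scatter summaries per ploidy bin at scheduled time points
#'
#' Summarizes the SSC cell-size proxy for each DNA-content bin at the time
#' point where that bin is most abundant (the schedule), per condition.
#' Bins with fewer than `min_events` retained events at their scheduled
#' time are reported as missing, never silently pooled with other times.
#'
#' @param binned Output of [assign_ploidy()] with `ssc`, `time_h` and
#'   `condition` columns.
#' @param schedule Data frame with columns `ploidy_c` and `time_h`: the
#'   representative time point for each bin.
#' @param min_events Minimum retained events per scheduled bin
#'   (default 250).
#'
#' @return A tibble with one row per condition × scheduled bin:
#'   `condition`, `ploidy_c`, `time_h`, `n`, `ssc_median`, `ssc_q1`,
#'   `ssc_q3`, `missing`. Quartiles use linear interpolation (Tukey
#'   boxplot convention).
#' @export
ssc_by_ploidy <- function(binned, schedule, min_events = 250) {
  stopifnot(is.data.frame(binned),
            all(c("ploidy_c", "ssc", "time_h", "condition") %in%
                  names(binned)),
            is.data.frame(schedule),
            all(c("ploidy_c", "time_h") %in% names(schedule)))
  keep <- binned |> filter(!.data$debris)
  conditions <- unique(keep$condition)
  purrr::map_dfr(conditions, function(cond) {
    purrr::pmap_dfr(schedule[c("ploidy_c", "time_h")], function(ploidy_c,
                                                                time_h) {
      sub <- keep |>
        filter(.data$condition == cond,
               .data$ploidy_c == !!ploidy_c,
               abs(.data$time_h - !!time_h) < 1e-9)
      if (nrow(sub) < min_events) {
        tibble(condition = cond, ploidy_c = ploidy_c, time_h = time_h,
               n = nrow(sub), ssc_median = NA_real_, ssc_q1 = NA_real_,
               ssc_q3 = NA_real_, missing = TRUE)
      } else {
        q <- quantile(sub$ssc, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        tibble(condition = cond, ploidy_c = ploidy_c, time_h = time_h,
               n = nrow(sub), ssc_median = q[2], ssc_q1 = q[1],
               ssc_q3 = q[3], missing = FALSE)
      }
    })
  })
}
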
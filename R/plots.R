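#' Plot a ploidy histogram
#'
#' Bars of population fraction per discrete DNA-content bin, on a log2
#' ploidy axis.
#'
#' @param object A `ploidy_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ploidy_histogram <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$ploidy_c,
                                labels = paste0(sort(.data$ploidy_c), "C")),
                     y = .data$fraction)) +
    geom_col(fill = "steelblue") +
    labs(x = "DNA content", y = "Fraction of population") +
    theme_minimal()
}

#' Plot an asynchrony envelope, optionally with observed series
#'
#' Ribbon of mean ± SD of the simulated increase of log2(GSD) asynchrony
#' over replicate populations; observed series are overlaid as lines with
#' points.
#'
#' @param object An `asynchrony_envelope` (or list of envelopes for
#'   [plot_asynchrony()]).
#' @param observed Optional `asynchrony_series` (or data frame with
#'   `time_h`, `delta_log2gsd`) to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.asynchrony_envelope <- function(object, observed = NULL, ...) {
  plot_asynchrony(list(object), observed = observed)
}

#' @rdname autoplot.asynchrony_envelope
#' @param envelopes List of `asynchrony_envelope` objects (one ribbon per
#'   CV).
#' @export
plot_asynchrony <- function(envelopes, observed = NULL) {
  if (inherits(envelopes, "asynchrony_envelope")) {
    envelopes <- list(envelopes)
  }
  bands <- purrr::map_dfr(envelopes, function(e) {
    as_tibble(e) |> mutate(cv = attr(e, "cv"))
  })
  p <- ggplot(bands, aes(x = .data$time_h)) +
    geom_ribbon(aes(ymin = .data$mean_delta_log2gsd - .data$sd_delta_log2gsd,
                    ymax = .data$mean_delta_log2gsd + .data$sd_delta_log2gsd,
                    fill = factor(.data$cv)), alpha = 0.25) +
    geom_line(aes(y = .data$mean_delta_log2gsd, colour = factor(.data$cv))) +
    labs(x = "Time (h)", y = expression(Delta * log[2] * "(GSD)"),
         colour = "CV", fill = "CV") +
    theme_minimal()
  if (!is.null(observed)) {
    p <- p +
      geom_line(data = observed, aes(y = .data$delta_log2gsd),
                colour = "black") +
      geom_point(data = observed, aes(y = .data$delta_log2gsd),
                 colour = "black")
  }
  p
}

#' Plot a doubling-time fit
#'
#' Observed log2 geometric mean versus time with the fitted regression
#' line over the fitting window.
#'
#' @param object A `doubling_time_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.doubling_time_fit <- function(object, ...) {
  dat <- object$fit$model
  ggplot(dat, aes(x = .data$time_h, y = .data$log2_geommean)) +
    geom_point() +
    geom_abline(intercept = coef(object$fit)[1], slope = object$slope,
                colour = "firebrick") +
    labs(x = "Time (h)", y = expression(log[2] * "(geometric mean DNA content)"),
         subtitle = sprintf("Doubling time %.2f h (slope SE %.4f)",
                            object$doubling_time_h, object$slope_se)) +
    theme_minimal()
}
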
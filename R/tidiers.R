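#' Tidy a doubling-time fit
#'
#' @param x A `doubling_time_fit` from [fit_doubling_time()].
#' @param ... Unused.
#' @return A tibble with one row per quantity (`slope`,
#'   `doubling_time_h`), with `estimate` and `std.error` columns.
#' @exportS3Method generics::tidy
tidy.doubling_time_fit <- function(x, ...) {
  tibble(
    term = c("slope", "doubling_time_h"),
    estimate = c(x$slope, x$doubling_time_h),
    std.error = c(x$slope_se, x$doubling_time_se)
  )
}

#' Glance at a doubling-time fit
#'
#' @inheritParams tidy.doubling_time_fit
#' @return A one-row tibble: `slope`, `slope_se`, `doubling_time_h`,
#'   `doubling_time_se`, `r.squared`, `n_points`, `window_start`,
#'   `window_end`.
#' @exportS3Method generics::glance
glance.doubling_time_fit <- function(x, ...) {
  tibble(
    slope = x$slope, slope_se = x$slope_se,
    doubling_time_h = x$doubling_time_h,
    doubling_time_se = x$doubling_time_se,
    r.squared = quiet_lm_summary(x$fit)$r.squared,
    n_points = x$n_points,
    window_start = x$window[1], window_end = x$window[2]
  )
}
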
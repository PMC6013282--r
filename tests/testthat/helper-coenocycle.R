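# Shared fixtures and independent oracles used across test files.

# Small experiment configuration: same biology as the defaults, fewer
# events, so unit tests stay fast.
tiny_config <- function(...) {
  experiment_config(
    events_per_timepoint = 800,
    cells_per_timepoint_microscopy = 40,
    timelapse_cells = 6,
    ...
  )
}

# Observed log2(GSD) series of a simulated population, via the exact
# ploidy histogram at each time point.
gsd_series <- function(pop, mode = "sqrt") {
  pop |>
    dplyr::group_by(time_h) |>
    dplyr::summarise(
      log2_gsd = log2_gsd(ploidy_histogram(data.frame(ploidy_c = ploidy_c)),
                          mode = mode),
      .groups = "drop"
    )
}

# Brute-force two-sided rank-sum p-value by exhaustive enumeration of all
# choose(n + m, n) assignments of the pooled mid-ranks to group a.
# Independent of the package's dynamic-programming implementation.
ranksum_enum_p <- function(a, b) {
  n <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])
  ws <- apply(utils::combn(length(r), n), 2, function(i) sum(r[i]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Analytic renewal expectation of the number of divisions by time t for
# i.i.d. Normal(mean, cv * mean) intervals with a fresh interval at t = 0
# (ignoring the negligible positivity truncation at small cv).
renewal_expected_divisions <- function(t, mean, cv, kmax = 50) {
  k <- seq_len(kmax)
  sum(stats::pnorm((t - k * mean) / (cv * mean * sqrt(k))))
}
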
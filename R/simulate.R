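# Draw an n x k matrix of division intervals, cell-major (row i holds the
# consecutive draws of cell i), redrawing non-positive values.
draw_intervals <- function(n, k, mean, sd) {
  m <- matrix(rnorm(n * k, mean, sd), nrow = n, ncol = k, byrow = TRUE)
  bad <- which(m <= 0)
  while (length(bad) > 0) {
    m[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[m[bad] <= 0]
  }
  m
}

row_cumsum <- function(m) {
  if (ncol(m) > 1) {
    for (j in 2:ncol(m)) m[, j] <- m[, j - 1] + m[, j]
  }
  m
}

# Cumulative division times for n cells, guaranteed to extend past t_max.
draw_division_times <- function(n, t_max, mean, sd) {
  k <- max(2L, ceiling(t_max / mean * 1.5) + 3L)
  cum <- row_cumsum(draw_intervals(n, k, mean, sd))
  while (any(cum[, ncol(cum)] <= t_max)) {
    extra <- row_cumsum(draw_intervals(n, 2L, mean, sd))
    cum <- cbind(cum, cum[, ncol(cum)] + extra)
  }
  cum
}

#' Simulate the division times of a single coenocyte
#'
#' Draws successive division intervals from the timer model (independent
#' normal draws; non-positive values redrawn) starting a fresh interval at
#' t = 0, the starvation-release convention. Uses the current RNG state;
#' wrap in [withr::with_seed()] for reproducibility.
#'
#' @param model A [division_model()].
#' @param initial_ploidy Starting DNA content in C units (a power of two).
#' @param t_max Simulation horizon in hours (> 0).
#'
#' @return Numeric vector of division times (hours), strictly increasing,
#'   all `<= t_max`. The cell's ploidy at time t is
#'   `initial_ploidy * 2^(number of division times <= t)`; see [ploidy_at()].
#' @examples
#' simulate_cell(division_model(11, 0), initial_ploidy = 1, t_max = 34)
#' @export
simulate_cell <- function(model, initial_ploidy = 1, t_max = 48) {
  stopifnot(inherits(model, "division_model"))
  if (!is_power_of_two(initial_ploidy)) {
    abort("`initial_ploidy` must be a power of two (C units).",
          class = "coenocycle_invalid_input")
  }
  if (!is.numeric(t_max) || length(t_max) != 1 || t_max <= 0) {
    abort("`t_max` must be a single positive number of hours.",
          class = "coenocycle_invalid_input")
  }
  sd <- model$cv * model$mean_doubling_time
  times <- numeric(0)
  t <- 0
  repeat {
    dt <- rnorm(1, model$mean_doubling_time, sd)
    while (dt <= 0) dt <- rnorm(1, model$mean_doubling_time, sd)
    t <- t + dt
    if (t > t_max) break
    times <- c(times, t)
  }
  times
}

#' Ploidy at given times from a division schedule
#'
#' Divisions are counted closed on the right: a division at exactly time t
#' has already happened at t.
#'
#' @param division_times Increasing numeric vector of division times (hours).
#' @param time Numeric vector of query times (hours).
#' @param initial_ploidy Starting ploidy in C units.
#' @return Numeric vector of ploidies (C units), one per query time.
#' @examples
#' ploidy_at(c(11, 22, 33), time = c(0, 12, 34), initial_ploidy = 1)
#' @export
ploidy_at <- function(division_times, time, initial_ploidy = 1) {
  initial_ploidy * 2^findInterval(time, sort(division_times))
}

validate_time_grid <- function(time_grid) {
  if (length(time_grid) == 0) {
    abort("`time_grid` must not be empty.", class = "coenocycle_invalid_input")
  }
  if (is.unsorted(time_grid, strictly = TRUE) || time_grid[1] != 0) {
    abort("`time_grid` must be strictly increasing and start at 0.",
          class = "coenocycle_invalid_input")
  }
  as.double(time_grid)
}

# Initial ploidies for n cells: deterministic largest-remainder
# apportionment (default) or multinomial draws.
initial_ploidies <- function(init, n_cells, method = c("deterministic",
                                                       "multinomial")) {
  method <- match.arg(method)
  counts <- switch(method,
    deterministic = apportion_counts(init$fraction, n_cells),
    multinomial = as.integer(stats::rmultinom(1, n_cells, init$fraction))
  )
  rep(init$ploidy_c, counts)
}

# Internal fast path: matrix of ploidies (cells x time points).
simulate_ploidy_matrix <- function(model, init, n_cells, time_grid, seed,
                                   init_method = "deterministic") {
  t_max <- max(time_grid)
  sd <- model$cv * model$mean_doubling_time
  withr::with_seed(seed, {
    p0 <- initial_ploidies(init, n_cells, init_method)
    cum <- draw_division_times(n_cells, t_max, model$mean_doubling_time, sd)
    ndiv <- vapply(time_grid, function(t) rowSums(cum <= t),
                   numeric(n_cells))
    p0 * 2^ndiv
  })
}

#' Simulate a population of coenocytes
#'
#' Each cell starts from an initial ploidy apportioned from `init`
#' (largest-remainder rounding by default, so the realized composition
#' matches the target fractions exactly up to integer rounding; multinomial
#' sampling is available) and divides according to the timer model.
#' Reproducible: the same `seed` yields identical trajectories.
#'
#' @inheritParams simulate_cell
#' @param init An [initial_ploidy_distribution()], or a named fraction
#'   vector coercible to one.
#' @param n_cells Number of cells (>= 1).
#' @param time_grid Strictly increasing vector of sampling times starting
#'   at 0 (hours).
#' @param seed Integer seed.
#' @param init_method `"deterministic"` (default) or `"multinomial"`
#'   assignment of initial ploidies.
#'
#' @return A tibble of class `ploidy_trajectory_set` in long format with
#'   columns `cell_id`, `time_h`, `ploidy_c`, carrying the seed and model
#'   as attributes. Ploidy is non-decreasing in time for every cell and
#'   always a power of two.
#' @examples
#' simulate_population(division_model(11, 0), initial_ploidy_distribution(),
#'                     n_cells = 4, time_grid = seq(0, 24, 3), seed = 1)
#' @export
simulate_population <- function(model, init = initial_ploidy_distribution(),
                                n_cells, time_grid, seed,
                                init_method = c("deterministic",
                                                "multinomial")) {
  stopifnot(inherits(model, "division_model"), n_cells >= 1)
  init <- as_initial_distribution(init)
  time_grid <- validate_time_grid(time_grid)
  init_method <- match.arg(init_method)
  pm <- simulate_ploidy_matrix(model, init, n_cells, time_grid, seed,
                               init_method)
  out <- tibble(
    cell_id = rep(seq_len(n_cells), times = length(time_grid)),
    time_h = rep(time_grid, each = n_cells),
    ploidy_c = as.vector(pm)
  )
  structure(out,
            class = c("ploidy_trajectory_set", class(out)),
            seed = seed, model = model, time_grid = time_grid)
}

#' Simulated asynchrony envelope over replicate populations
#'
#' Repeats the population simulation `n_replicates` times; for each
#' replicate computes log2(GSD) of the exact ploidy histogram at every time
#' point (via [log2_gsd()]), subtracts the replicate's own t = 0 baseline,
#' and summarizes the increase of asynchrony as its mean and standard
#' deviation across replicates. This is the simulated band against which
#' observed asynchrony series are compared.
#'
#' @inheritParams simulate_population
#' @param n_replicates Number of replicate simulations (>= 2).
#' @param gsd_mode Passed to [log2_gsd()]: `"sqrt"` (default) or
#'   `"literal"`.
#'
#' @return A tibble of class `asynchrony_envelope` with columns `time_h`,
#'   `mean_delta_log2gsd`, `sd_delta_log2gsd`, plus attributes `cv`,
#'   `n_replicates`, `gsd_mode` and `seed`. The mean band is exactly 0 at
#'   t = 0 by construction.
#' @examples
#' asynchrony_envelope(division_model(11, 0.1),
#'                     n_cells = 200, n_replicates = 5,
#'                     time_grid = seq(0, 24, 6), seed = 1)
#' @export
asynchrony_envelope <- function(model, init = initial_ploidy_distribution(),
                                n_cells, n_replicates, time_grid, seed,
                                gsd_mode = c("sqrt", "literal"),
                                init_method = c("deterministic",
                                                "multinomial")) {
  stopifnot(inherits(model, "division_model"))
  if (n_replicates < 2) {
    abort("`n_replicates` must be at least 2.",
          class = "coenocycle_invalid_input")
  }
  init <- as_initial_distribution(init)
  time_grid <- validate_time_grid(time_grid)
  gsd_mode <- match.arg(gsd_mode)
  init_method <- match.arg(init_method)

  deltas <- vapply(seq_len(n_replicates), function(r) {
    pm <- simulate_ploidy_matrix(model, init, n_cells, time_grid,
                                 seed = mix_seed(seed, r), init_method)
    gsd <- apply(pm, 2, function(p) log2_gsd(ploidy_histogram_values(p),
                                             mode = gsd_mode))
    gsd - gsd[1]
  }, numeric(length(time_grid)))

  out <- tibble(
    time_h = time_grid,
    mean_delta_log2gsd = rowMeans(deltas),
    sd_delta_log2gsd = apply(deltas, 1, sd)
  )
  structure(out,
            class = c("asynchrony_envelope", class(out)),
            cv = model$cv, n_replicates = n_replicates,
            gsd_mode = gsd_mode, seed = seed)
}
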
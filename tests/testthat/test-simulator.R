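test_that("deterministic timer divides at exact multiples of the period", {
  m <- division_model(11, 0)
  withr::with_seed(1, {
    expect_equal(simulate_cell(m, 1, 34), c(11, 22, 33))
    expect_equal(ploidy_at(c(11, 22, 33), 34, 1), 8)
    expect_length(simulate_cell(m, 4, 10), 0)
  })
  # division exactly at a query time counts (closed on the right)
  expect_equal(ploidy_at(c(11, 22), c(10.999, 11, 22), 1), c(1, 2, 4))
})

test_that("invalid inputs are rejected with classed errors", {
  m <- division_model(11, 0.1)
  expect_error(simulate_cell(m, 3, 48), class = "coenocycle_invalid_input")
  expect_error(simulate_cell(m, 1, 0), class = "coenocycle_invalid_input")
  expect_error(division_model(-1, 0.1), class = "coenocycle_invalid_input")
  expect_error(division_model(11, -0.1), class = "coenocycle_invalid_input")
  expect_error(initial_ploidy_distribution(c("3" = 1)),
               class = "coenocycle_invalid_input")
  expect_error(initial_ploidy_distribution(c("1" = 0.6, "2" = 0.6)),
               class = "coenocycle_invalid_input")
  expect_error(
    simulate_population(m, n_cells = 10, time_grid = numeric(0), seed = 1),
    class = "coenocycle_invalid_input")
  expect_error(
    simulate_population(m, n_cells = 10, time_grid = c(3, 6), seed = 1),
    class = "coenocycle_invalid_input")
})

test_that("mean division count matches the analytic renewal expectation", {
  # closed-form oracle: E N(t) = sum_k Phi((t - k mu) / (sigma sqrt(k)))
  expected <- renewal_expected_divisions(48, 11, 0.1)
  pop <- simulate_population(division_model(11, 0.1),
                             initial_ploidy_distribution(c("1" = 1)),
                             n_cells = 4000, time_grid = c(0, 48), seed = 7)
  ndiv <- log2(pop$ploidy_c[pop$time_h == 48])
  # MC standard error ~ sd/sqrt(n) ~ 0.008; allow 5 SEs
  expect_equal(mean(ndiv), expected, tolerance = 0.045 / expected)
  # the naive t/mean value (4.36) ignores the renewal transient and is
  # far from the truth; make sure we are near the oracle, not near it
  expect_lt(abs(mean(ndiv) - expected), abs(mean(ndiv) - 48 / 11) / 4)
})

test_that("population trajectories obey conservation and determinism", {
  m <- division_model(11, 0.12)
  grid <- seq(0, 48, 3)
  pop1 <- simulate_population(m, n_cells = 300, time_grid = grid, seed = 42)
  pop2 <- simulate_population(m, n_cells = 300, time_grid = grid, seed = 42)
  expect_identical(pop1$ploidy_c, pop2$ploidy_c)

  # every value a power of two; non-decreasing along time per cell;
  # log2 increments are integers
  expect_true(all(abs(log2(pop1$ploidy_c) -
                        round(log2(pop1$ploidy_c))) < 1e-9))
  steps <- pop1 |>
    dplyr::arrange(cell_id, time_h) |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(ok = all(diff(log2(ploidy_c)) >= 0 &
                                abs(diff(log2(ploidy_c)) -
                                      round(diff(log2(ploidy_c)))) < 1e-9))
  expect_true(all(steps$ok))

  # deterministic apportionment hits the target composition exactly
  init0 <- pop1 |> dplyr::filter(time_h == 0) |> dplyr::count(ploidy_c)
  expect_equal(init0$n, c(75, 150, 75))
})

test_that("zero-variability populations are perfectly synchronous", {
  grid <- seq(0, 48, 3)
  pop <- simulate_population(division_model(11, 0), n_cells = 50,
                             time_grid = grid,
                             init = initial_ploidy_distribution(c("1" = 1)),
                             seed = 5)
  per_time <- pop |> dplyr::group_by(time_h) |>
    dplyr::summarise(n_distinct = dplyr::n_distinct(ploidy_c))
  expect_true(all(per_time$n_distinct == 1))
  expect_true(all(gsd_series(pop)$log2_gsd == 0))

  env <- asynchrony_envelope(division_model(11, 0), n_cells = 50,
                             n_replicates = 3, time_grid = grid, seed = 5)
  expect_true(all(env$mean_delta_log2gsd == 0))
  expect_true(all(env$sd_delta_log2gsd == 0))
})

test_that("asynchrony envelopes are baseline-subtracted, reproducible and rise with CV", {
  grid <- seq(0, 48, 6)
  e1 <- asynchrony_envelope(division_model(11, 0.05), n_cells = 1000,
                            n_replicates = 20, time_grid = grid, seed = 3)
  e2 <- asynchrony_envelope(division_model(11, 0.05), n_cells = 1000,
                            n_replicates = 20, time_grid = grid, seed = 3)
  e3 <- asynchrony_envelope(division_model(11, 0.15), n_cells = 1000,
                            n_replicates = 20, time_grid = grid, seed = 3)
  expect_identical(e1$mean_delta_log2gsd, e2$mean_delta_log2gsd)
  expect_identical(e1$mean_delta_log2gsd[1], 0)
  expect_true(all(e1$sd_delta_log2gsd >= 0))
  # higher cell-to-cell variability -> faster growth of asynchrony
  expect_lt(e1$mean_delta_log2gsd[grid == 48], e3$mean_delta_log2gsd[grid == 48])
  expect_error(
    asynchrony_envelope(division_model(11, 0.05), n_cells = 10,
                        n_replicates = 1, time_grid = grid, seed = 1),
    class = "coenocycle_invalid_input")
})
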
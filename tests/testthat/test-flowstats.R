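test_that("calibration recovers the reference intensity of known mixtures", {
  withr::with_seed(11, {
    # three-stage mixture, 5% multiplicative noise
    ev3 <- tibble::tibble(
      dapi_intensity = 100 * rep(c(1, 2, 4), each = 1500) *
        exp(rnorm(4500, 0, sqrt(log1p(0.05^2)))))
    cal3 <- calibrate_reference(ev3)
    expect_equal(cal3$reference_intensity, 100, tolerance = 0.03)

    # single tight peak
    ev1 <- tibble::tibble(dapi_intensity = 250 * exp(rnorm(800, 0, 0.02)))
    expect_equal(calibrate_reference(ev1)$reference_intensity, 250,
                 tolerance = 0.02)

    # full eight-peak ladder: reference recovered, peaks at integer offsets
    ev8 <- tibble::tibble(
      dapi_intensity = 100 * rep(2^(0:7), each = 700) *
        exp(rnorm(5600, 0, sqrt(log1p(0.07^2)))))
    cal8 <- calibrate_reference(ev8)
    expect_equal(cal8$reference_intensity, 100, tolerance = 0.03)
    offsets <- cal8$peaks$log2_intensity - cal8$peaks$log2_intensity[1]
    expect_true(all(abs(offsets - round(offsets)) < 0.1))
    expect_equal(sort(round(offsets)), 0:7)
  })
})

test_that("calibration fails cleanly and warns on off-grid peak spacing", {
  ev <- tibble::tibble(dapi_intensity = 100 * exp(rnorm(500, 0, 0.02)))
  expect_error(calibrate_reference(ev, prominence = 2),
               class = "coenocycle_calibration_failure")
  withr::with_seed(2, {
    bad <- tibble::tibble(
      dapi_intensity = 100 * rep(c(1, 2^1.5), each = 1000) *
        exp(rnorm(2000, 0, 0.05)))
    expect_warning(calibrate_reference(bad),
                   class = "coenocycle_calibration_warning")
  })
  expect_error(calibrate_reference(tibble::tibble(dapi_intensity = c(1, -2))),
               class = "coenocycle_invalid_input")
})

test_that("ploidy binning follows the nearest-power-of-two rule with debris flags", {
  ev <- tibble::tibble(dapi_intensity = c(100, 412, 145, 30, 260, 100 * 2^1.55))
  b <- assign_ploidy(ev, 100, quiet = TRUE)
  # 412: log2(4.12) = 2.04 -> 4C; 145: residual to 2C is 0.464 <= 0.5 -> 2C;
  # 30: below the 1C bin -> debris; 260 -> 2C; 2^1.55 -> residual 0.45 -> 4C
  expect_equal(b$ploidy_c, c(1, 4, 2, NA, 2, 4))
  expect_equal(b$debris, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(attr(b, "binning_counts"),
               c(retained = 5L, debris = 1L))

  # round trip at exact intensities: zero debris, exact bins
  k <- rep(0:7, each = 10)
  exact <- assign_ploidy(tibble::tibble(dapi_intensity = 100 * 2^k), 100,
                         quiet = TRUE)
  expect_false(any(exact$debris))
  expect_equal(exact$ploidy_c, 2^k)

  # binning message reports counts
  expect_message(assign_ploidy(ev, 100), "5 events retained")
})

test_that("ploidy histograms normalize and reject all-debris input", {
  h <- ploidy_histogram(tibble::tibble(ploidy_c = rep(c(2, 4), each = 50),
                                       debris = FALSE))
  expect_s3_class(h, "ploidy_histogram")
  expect_equal(h$fraction, c(0.5, 0.5))
  expect_equal(attr(h, "n_events"), 100)
  expect_error(
    ploidy_histogram(tibble::tibble(ploidy_c = NA_real_, debris = TRUE)),
    class = "coenocycle_empty_histogram")
})

test_that("log2 geometric mean and GSD match their closed forms", {
  h24 <- tibble::tibble(ploidy_c = c(2, 4), fraction = c(0.5, 0.5))
  expect_identical(log2_geommean(h24), 1.5)
  expect_identical(log2_gsd(h24), 0.5)
  expect_identical(log2_gsd(h24, mode = "literal"), 0.25)
  expect_identical(log2_geommean(tibble::tibble(ploidy_c = 8, fraction = 1)), 3)
  expect_identical(log2_gsd(tibble::tibble(ploidy_c = 4, fraction = 1)), 0)
  expect_identical(
    log2_geommean(tibble::tibble(ploidy_c = c(1, 2, 4),
                                 fraction = c(0.25, 0.5, 0.25))), 1)
  expect_error(log2_geommean(tibble::tibble(ploidy_c = 2, fraction = 0.7)),
               class = "coenocycle_invalid_input")
})

test_that("histogram formulas equal the event-wise mean and population SD", {
  withr::with_seed(99, {
    for (i in 1:50) {
      p <- 2^sample(0:7, 200, replace = TRUE)
      h <- ploidy_histogram(tibble::tibble(ploidy_c = p))
      expect_equal(log2_geommean(h), mean(log2(p)), tolerance = 1e-12)
      expect_equal(log2_gsd(h),
                   sqrt(mean((log2(p) - mean(log2(p)))^2)),
                   tolerance = 1e-12)
    }
  })
})

test_that("doubling-time regression recovers noiseless and noisy lines", {
  tt <- seq(0, 36, 3)
  exact <- tibble::tibble(time_h = tt, log2_geommean = 0.5 + tt / 11)
  f <- fit_doubling_time(exact)
  expect_equal(f$slope, 1 / 11, tolerance = 1e-10)
  expect_equal(f$doubling_time_h, 11, tolerance = 1e-10)
  expect_lt(f$slope_se, 1e-10)
  expect_equal(f$n_points, 13L)

  # Monte-Carlo: additive noise leaves the estimator unbiased on a line
  withr::with_seed(21, {
    dts <- replicate(100, {
      noisy <- exact |>
        dplyr::mutate(log2_geommean = log2_geommean + rnorm(13, 0, 0.05))
      fit_doubling_time(noisy)$doubling_time_h
    })
  })
  expect_gt(mean(dts), 10.5)
  expect_lt(mean(dts), 11.5)

  # tidiers
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "doubling_time_h"], 11,
               tolerance = 1e-10)
  gl <- glance(f)
  expect_equal(gl$r.squared, 1, tolerance = 1e-10)

  expect_error(fit_doubling_time(exact[1:2, ]),
               class = "coenocycle_invalid_input")
  falling <- tibble::tibble(time_h = tt, log2_geommean = 5 - tt / 11)
  expect_error(fit_doubling_time(falling),
               class = "coenocycle_non_growing_series")
})

test_that("delta asynchrony subtracts the t = 0 baseline exactly", {
  s <- tibble::tibble(time_h = c(0, 24, 48), log2_gsd = c(0.4, 0.5, 0.7))
  d <- delta_asynchrony(s)
  expect_equal(d$delta_log2gsd, c(0, 0.1, 0.3))
  expect_identical(d$delta_log2gsd[1], 0)
  expect_error(delta_asynchrony(s[-1, ]), class = "coenocycle_invalid_input")
  const <- tibble::tibble(time_h = c(0, 12, 24), log2_gsd = 0.6)
  expect_true(all(delta_asynchrony(const)$delta_log2gsd == 0))
})

test_that("CV upper bound picks the smallest compatible envelope", {
  grid <- seq(0, 48, 6)
  init <- initial_ploidy_distribution()
  envs <- lapply(c(0.05, 0.15), function(cv) {
    asynchrony_envelope(division_model(11, cv), init, n_cells = 800,
                        n_replicates = 15, time_grid = grid, seed = 17)
  })
  # a perfectly synchronous observation is below every upper edge
  flat <- tibble::tibble(time_h = grid, delta_log2gsd = 0)
  b0 <- cv_upper_bound(flat, envs)
  expect_equal(b0$cv, 0.05)
  expect_true(b0$bounded)

  # an observation wilder than the largest envelope is not bounded
  wild <- tibble::tibble(time_h = grid, delta_log2gsd = 5)
  bw <- cv_upper_bound(wild, envs)
  expect_false(bw$bounded)
  expect_equal(bw$cv, 0.15)

  # a high-CV observation must not certify the small-CV envelope
  pop <- simulate_population(division_model(11, 0.15), init, 2000, grid,
                             seed = 4)
  obs <- delta_asynchrony(gsd_series(pop))
  bh <- cv_upper_bound(obs, envs)
  expect_gte(bh$cv, 0.15)

  expect_error(cv_upper_bound(flat, list()),
               class = "coenocycle_invalid_input")
  off_grid <- tibble::tibble(time_h = c(0, 5), delta_log2gsd = 0)
  expect_error(cv_upper_bound(off_grid, envs),
               class = "coenocycle_invalid_input")
})
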
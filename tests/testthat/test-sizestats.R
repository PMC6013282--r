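test_that("sphere geometry follows the closed forms and round-trips", {
  expect_equal(sphere_volume(1), 4 * pi / 3, tolerance = 1e-12)
  expect_equal(sphere_volume(10), 4188.790205, tolerance = 1e-9)
  expect_equal(sphere_volume(2) / sphere_volume(1), 8, tolerance = 1e-12)
  r <- c(0.5, 1, 7.3, 40)
  expect_equal(sphere_radius(sphere_volume(r)), r, tolerance = 1e-12)
  expect_equal(perimeter_to_radius(2 * pi), 1, tolerance = 1e-12)
  expect_error(sphere_volume(c(1, -1)), class = "coenocycle_invalid_input")
  expect_error(sphere_radius(0), class = "coenocycle_invalid_input")
})

test_that("nuclei-to-volume ratio scales with nuclear count", {
  cells <- tibble::tibble(n_nuclei = c(8, 16), radius_um = 10)
  out <- nuclei_volume_ratio(cells)
  expect_equal(out$volume_um3, rep(4188.790205, 2), tolerance = 1e-9)
  expect_equal(out$nuclei_per_um3[1], 8 / 4188.790205, tolerance = 1e-9)
  expect_equal(out$nuclei_per_um3[2], 2 * out$nuclei_per_um3[1])
})

test_that("relative area normalizes to t = 0 and is scale invariant", {
  s <- tibble::tibble(cell_id = "c1", time_h = c(0, 12, 24),
                      area_um2 = c(100, 150, 220))
  r <- relative_area(s)
  expect_equal(r$relative_area, c(1, 1.5, 2.2))
  expect_identical(r$relative_area[1], 1)

  # scale invariance per cell
  s10 <- s |> dplyr::mutate(area_um2 = area_um2 * 13.7)
  expect_equal(relative_area(s10)$relative_area, r$relative_area)

  const <- tibble::tibble(cell_id = "c2", time_h = c(0, 6), area_um2 = 50)
  expect_true(all(relative_area(const)$relative_area == 1))
  expect_error(relative_area(s[-1, ]), class = "coenocycle_invalid_input")
})

test_that("rank-sum test matches hand-checked exact cases", {
  expect_equal(compare_groups(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")
  expect_equal(same$method, "exact")
  expect_error(compare_groups(numeric(0), 1),
               class = "coenocycle_invalid_input")
  # direction reflects the shift
  expect_equal(compare_groups(c(10, 11, 12), c(1, 2, 3))$direction, "a>b")
})

test_that("exact rank-sum p-values agree with stats::wilcox.test when tie-free", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(2:10, 1); m <- sample(2:10, 1)
      a <- rnorm(n); b <- rnorm(m, sample(c(0, 1), 1))
      ours <- compare_groups(a, b)
      ref <- stats::wilcox.test(a, b, exact = TRUE)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(ours$statistic, unname(ref$statistic))
    }
  })
})

test_that("large samples fall back to the corrected normal approximation", {
  withr::with_seed(32, {
    a <- rnorm(60); b <- rnorm(55, 0.3)
    ours <- compare_groups(a, b)
    expect_equal(ours$method, "normal")
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    # ties handled via the tie-corrected variance
    at <- round(a, 1); bt <- round(b, 1)
    expect_equal(compare_groups(at, bt)$p_value,
                 stats::wilcox.test(at, bt, exact = FALSE,
                                    correct = TRUE)$p.value,
                 tolerance = 1e-10)
  })
  # Monte-Carlo power: clearly separated samples are always detected
  withr::with_seed(33, {
    ps <- replicate(10, {
      compare_groups(rnorm(300, 0), rnorm(300, 0.5))$p_value
    })
  })
  expect_true(all(ps < 0.01))
})

test_that("SSC summaries respect the per-bin schedule and minimum counts", {
  ev <- tibble::tibble(
    ploidy_c = rep(c(16, 16, 32), each = 30),
    ssc = rep(c(5, 9, 7), each = 30),
    time_h = rep(c(36, 48, 36), each = 30),
    condition = "1x",
    debris = FALSE
  )
  sched <- tibble::tibble(ploidy_c = c(16, 32, 64), time_h = c(36, 36, 48))
  out <- ssc_by_ploidy(ev, sched, min_events = 20)
  # 16C summarized only from its scheduled 36 h events (ssc = 5, not 9)
  expect_equal(out$ssc_median[out$ploidy_c == 16], 5)
  expect_equal(out$ssc_q3[out$ploidy_c == 16] -
                 out$ssc_q1[out$ploidy_c == 16], 0)
  expect_equal(out$n[out$ploidy_c == 16], 30)
  # absent scheduled bin flagged missing, not pooled
  expect_true(out$missing[out$ploidy_c == 64])
  expect_true(is.na(out$ssc_median[out$ploidy_c == 64]))
  # below min_events flagged missing
  strict <- ssc_by_ploidy(ev, sched, min_events = 50)
  expect_true(all(strict$missing))
})
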
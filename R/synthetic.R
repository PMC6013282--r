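media_label <- function(level) {
  vapply(level, function(l) {
    frac <- 1 / l
    if (abs(frac - round(frac)) < 1e-9 && round(frac) > 1) {
      paste0("1/", round(frac), "x")
    } else {
      paste0(format(l, trim = TRUE), "x")
    }
  }, character(1))
}

# Log-normal multiplier with mean exactly 1 and the given CV.
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Configuration of the synthetic coenocytic-growth experiment
#'
#' Bundles every parameter of the generative model: the nuclear-division
#' timer, the starvation-synchronized starting population, media levels
#' with their (nutrient-dependent) exponential volume growth rates, the
#' burst rule, and instrument-level noise for the emitted flow-cytometry,
#' microscopy and time-lapse tables. Defaults reproduce the study
#' conditions: an 11 h timer with 10% CV, a 1C/2C/4C starting mixture,
#' four media dilutions, cellularization thresholds of 64–128C with burst
#' between 48 and 72 h, newborns of 2C (80%) or 4C (20%), ~5000 events per
#' time point sampled every 12 h over 0–72 h.
#'
#' @param division_model A [division_model()] (default mean 11 h, CV 0.10).
#' @param initial_distribution An [initial_ploidy_distribution()] (default
#'   1C:0.25, 2C:0.50, 4C:0.25).
#' @param media_levels Media concentrations as fractions of full strength.
#' @param volume_growth_rates Specific volume growth rate (per hour) for
#'   each media level; must be strictly increasing with concentration.
#' @param burst_ploidy_range Power-of-two range of per-cell cellularization
#'   thresholds (default 64–128C, drawn log-uniformly).
#' @param burst_window_h Burst window in hours (default 48–72): a cell
#'   bursts if the division reaching its threshold falls inside it.
#' @param newborn_ploidy_weights Named weights of newborn ploidies
#'   (default 2C: 0.8, 4C: 0.2).
#' @param intensity_reference DAPI intensity of 1C DNA content (arbitrary
#'   units, default 100).
#' @param intensity_cv Multiplicative log-normal CV of DAPI intensity
#'   (default 0.07).
#' @param ssc_exponent SSC scales as volume^exponent (default 2/3,
#'   surface-like scattering).
#' @param ssc_cv,fsc_cv Multiplicative noise CVs of the scatter channels.
#' @param debris_fraction Fraction of events replaced by low-intensity
#'   debris (default 0.02).
#' @param debris_intensity_range Debris intensity range as fractions of the
#'   reference, sampled log-uniformly (default 0.02–0.7, entirely below
#'   the 1C bin).
#' @param events_per_timepoint Events emitted per time point and media
#'   level (default 5000).
#' @param sample_times_h Flow-cytometry sampling times (default every 12 h
#'   over 0–72 h).
#' @param newborn_radius_um Radius of a newborn (1C-equivalent) cell.
#' @param initial_volume_cv Log-normal CV of starting volumes.
#' @param partition_cv Log-normal CV of volume partitioning at burst.
#' @param cells_per_timepoint_microscopy Microscopy cells sampled per time
#'   point and media level.
#' @param radius_cv Measurement CV of microscopy radii.
#' @param timelapse_cells Tracked cells per media level.
#' @param timelapse_hours,timelapse_step_h Time-lapse horizon and step
#'   (default 36 h every 15 min).
#' @param area_cv Measurement CV of time-lapse areas.
#'
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(
    division_model = coenocycle::division_model(11, 0.10),
    initial_distribution = initial_ploidy_distribution(),
    media_levels = c(1, 1 / 2, 1 / 4, 1 / 16),
    volume_growth_rates = c(0.044, 0.033, 0.024, 0.012),
    burst_ploidy_range = c(64, 128),
    burst_window_h = c(48, 72),
    newborn_ploidy_weights = c("2" = 0.8, "4" = 0.2),
    intensity_reference = 100,
    intensity_cv = 0.07,
    ssc_exponent = 2 / 3,
    ssc_cv = 0.10,
    fsc_cv = 0.15,
    debris_fraction = 0.02,
    debris_intensity_range = c(0.02, 0.7),
    events_per_timepoint = 5000,
    sample_times_h = seq(0, 72, by = 12),
    newborn_radius_um = 4,
    initial_volume_cv = 0.15,
    partition_cv = 0.05,
    cells_per_timepoint_microscopy = 60,
    radius_cv = 0.02,
    timelapse_cells = 30,
    timelapse_hours = 36,
    timelapse_step_h = 0.25,
    area_cv = 0.03) {
  cfg <- list(
    division_model = division_model,
    initial_distribution = as_initial_distribution(initial_distribution),
    media_levels = as.double(media_levels),
    volume_growth_rates = as.double(volume_growth_rates),
    burst_ploidy_range = as.double(burst_ploidy_range),
    burst_window_h = as.double(burst_window_h),
    newborn_ploidy_weights = newborn_ploidy_weights,
    intensity_reference = intensity_reference,
    intensity_cv = intensity_cv,
    ssc_exponent = ssc_exponent,
    ssc_cv = ssc_cv,
    fsc_cv = fsc_cv,
    debris_fraction = debris_fraction,
    debris_intensity_range = as.double(debris_intensity_range),
    events_per_timepoint = as.integer(events_per_timepoint),
    sample_times_h = as.double(sample_times_h),
    newborn_radius_um = newborn_radius_um,
    initial_volume_cv = initial_volume_cv,
    partition_cv = partition_cv,
    cells_per_timepoint_microscopy =
      as.integer(cells_per_timepoint_microscopy),
    radius_cv = radius_cv,
    timelapse_cells = as.integer(timelapse_cells),
    timelapse_hours = timelapse_hours,
    timelapse_step_h = timelapse_step_h,
    area_cv = area_cv
  )
  validate_experiment_config(cfg)
}

validate_experiment_config <- function(cfg) {
  stopifnot(inherits(cfg$division_model, "division_model"))
  if (length(cfg$volume_growth_rates) != length(cfg$media_levels)) {
    abort("Need one volume growth rate per media level.",
          class = "coenocycle_invalid_config")
  }
  ord <- order(cfg$media_levels)
  if (any(diff(cfg$volume_growth_rates[ord]) <= 0)) {
    abort("Volume growth rates must increase strictly with media concentration.",
          class = "coenocycle_invalid_config")
  }
  if (any(!is_power_of_two(cfg$burst_ploidy_range)) ||
      cfg$burst_ploidy_range[1] > cfg$burst_ploidy_range[2]) {
    abort("`burst_ploidy_range` must be an increasing pair of powers of two.",
          class = "coenocycle_invalid_config")
  }
  if (cfg$burst_window_h[1] >= cfg$burst_window_h[2] ||
      cfg$burst_window_h[2] > max(cfg$sample_times_h) + 24) {
    abort("`burst_window_h` must be increasing and near the sampling horizon.",
          class = "coenocycle_invalid_config")
  }
  if (any(!is_power_of_two(as.double(names(cfg$newborn_ploidy_weights))))) {
    abort("Newborn ploidies must be powers of two.",
          class = "coenocycle_invalid_config")
  }
  noise <- c(cfg$intensity_cv, cfg$ssc_cv, cfg$fsc_cv, cfg$initial_volume_cv,
             cfg$partition_cv, cfg$radius_cv, cfg$area_cv)
  if (any(noise < 0)) {
    abort("Noise CVs must be non-negative.",
          class = "coenocycle_invalid_config")
  }
  if (cfg$debris_fraction < 0 || cfg$debris_fraction > 1) {
    abort("`debris_fraction` must be a fraction in [0, 1].",
          class = "coenocycle_invalid_config")
  }
  if (cfg$debris_intensity_range[2] > 1 / (2^0.5) + 1e-9) {
    warn("Debris intensities above reference/sqrt(2) will be binned as 1C.")
  }
  structure(cfg, class = "experiment_config")
}

# Mother cohort shared across media: division schedules, burst thresholds
# and outcomes. Timing is media-independent by construction.
make_mother_cohort <- function(cfg, n, seed) {
  model <- cfg$division_model
  sd <- model$cv * model$mean_doubling_time
  horizon <- max(cfg$sample_times_h, cfg$burst_window_h[2])
  withr::with_seed(mix_seed(seed, 1), {
    p0 <- initial_ploidies(cfg$initial_distribution, n)
    cum <- draw_division_times(n, horizon, model$mean_doubling_time, sd)
    thr_pows <- 2^seq(log2(cfg$burst_ploidy_range[1]),
                      log2(cfg$burst_ploidy_range[2]))
    threshold <- sample(thr_pows, n, replace = TRUE)
    nb_p <- as.double(names(cfg$newborn_ploidy_weights))
    newborn_ploidy <- sample(nb_p, n, replace = TRUE,
                             prob = cfg$newborn_ploidy_weights)
    v0 <- sphere_volume(cfg$newborn_radius_um) * p0^(2 / 3) *
      lnorm_noise(n, cfg$initial_volume_cv)
  })
  # division index at which the threshold is reached
  d_need <- pmax(0L, as.integer(round(log2(threshold / p0))))
  reach_time <- ifelse(d_need == 0L, 0,
                       cum[cbind(seq_len(n), pmax(d_need, 1L))])
  bursts <- reach_time >= cfg$burst_window_h[1] &
    reach_time <= cfg$burst_window_h[2]
  list(
    n = n,
    cum = cum,
    cells = tibble(
      cell_id = seq_len(n),
      initial_ploidy = p0,
      burst_threshold = threshold,
      reach_time_h = reach_time,
      bursts = bursts,
      burst_time_h = ifelse(bursts, reach_time, NA_real_),
      newborn_ploidy = ifelse(bursts, newborn_ploidy, NA_real_),
      brood_size = ifelse(bursts, threshold / newborn_ploidy, NA_real_),
      v0_um3 = v0
    )
  )
}

# Capped ploidy of every mother at time t.
mother_ploidy_at <- function(cohort, t) {
  nd <- rowSums(cohort$cum <= t)
  pmin(cohort$cells$initial_ploidy * 2^nd, cohort$cells$burst_threshold)
}

# Sample one event table (one media level, one time point).
sample_event_table <- function(cohort, cfg, media, rate, t, n_events) {
  cells <- cohort$cells
  burst_done <- !is.na(cells$burst_time_h) & cells$burst_time_h <= t
  weight <- ifelse(burst_done, cells$brood_size, 1)
  idx <- sample(cohort$n, n_events, replace = TRUE, prob = weight)
  from_newborn <- burst_done[idx]

  ploidy <- volume <- numeric(n_events)
  # mothers (cellularization cap applies)
  if (any(!from_newborn)) {
    mi <- idx[!from_newborn]
    nd <- rowSums(cohort$cum[mi, , drop = FALSE] <= t)
    ploidy[!from_newborn] <- pmin(cells$initial_ploidy[mi] * 2^nd,
                                  cells$burst_threshold[mi])
    volume[!from_newborn] <- cells$v0_um3[mi] * exp(rate * t)
  }
  # newborns: fresh timer from the burst, partitioned volume
  if (any(from_newborn)) {
    ni <- idx[from_newborn]
    dt <- t - cells$burst_time_h[ni]
    kmax <- max(1L, ceiling(max(dt) / cfg$division_model$mean_doubling_time)
                + 2L)
    iv <- row_cumsum(draw_intervals(length(ni), kmax,
                                    cfg$division_model$mean_doubling_time,
                                    cfg$division_model$cv *
                                      cfg$division_model$mean_doubling_time))
    nd <- rowSums(iv <= dt)
    ploidy[from_newborn] <- cells$newborn_ploidy[ni] * 2^nd
    v_birth <- cells$v0_um3[ni] * exp(rate * cells$burst_time_h[ni]) /
      cells$brood_size[ni] * lnorm_noise(length(ni), cfg$partition_cv)
    volume[from_newborn] <- v_birth * exp(rate * dt)
  }

  intensity <- cfg$intensity_reference * ploidy *
    lnorm_noise(n_events, cfg$intensity_cv)
  n_debris <- round(cfg$debris_fraction * n_events)
  if (n_debris > 0) {
    di <- sample(n_events, n_debris)
    lo <- log(cfg$debris_intensity_range[1])
    hi <- log(cfg$debris_intensity_range[2])
    intensity[di] <- cfg$intensity_reference * exp(runif(n_debris, lo, hi))
  }
  ssc <- volume^cfg$ssc_exponent * lnorm_noise(n_events, cfg$ssc_cv)
  fsc <- volume^(1 / 3) * lnorm_noise(n_events, cfg$fsc_cv)
  tibble(
    event_id = NA_character_,  # filled by caller
    dapi_intensity = intensity,
    ssc = ssc,
    fsc = fsc,
    time_h = t,
    condition = media
  )
}

#' Generate a full synthetic coenocytic-growth experiment
#'
#' Runs the generative model end to end: a shared cohort of cells with
#' timer-driven division schedules (identical across media levels — the
#' decoupling of nuclear cycles from growth is built in), media-dependent
#' exponential volume growth, per-cell cellularization thresholds with
#' burst into newborn cells inside the burst window, and instrument-level
#' noise. Emits the three tables the analysis modules consume plus the
#' ground truth that tests compare against.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed; all outputs are reproducible from it.
#'
#' @return A list of class `coenocycle_experiment` with elements
#'   `events` (flow-cytometry-like event table: `event_id`,
#'   `dapi_intensity`, `ssc`, `fsc`, `time_h`, `condition`),
#'   `cells` (microscopy table: `cell_id`, `n_nuclei`, `radius_um`,
#'   `time_h`, `condition`), `areas` (time-lapse table: `cell_id`,
#'   `time_h`, `area_um2`, `condition`), and `ground_truth` (per-cell
#'   division schedules, burst outcomes, volumes; never read by the
#'   analysis code).
#' @examples
#' cfg <- experiment_config(events_per_timepoint = 200,
#'                          cells_per_timepoint_microscopy = 10,
#'                          timelapse_cells = 3)
#' exp <- generate_experiment(cfg, seed = 1)
#' dplyr::count(exp$events, condition)
#' @export
generate_experiment <- function(config = experiment_config(), seed = 1) {
  cfg <- validate_experiment_config(config)
  cohort <- make_mother_cohort(cfg, cfg$events_per_timepoint, seed)
  labels <- media_label(cfg$media_levels)

  events <- purrr::map_dfr(seq_along(cfg$media_levels), function(i) {
    purrr::map_dfr(seq_along(cfg$sample_times_h), function(j) {
      t <- cfg$sample_times_h[j]
      withr::with_seed(mix_seed(seed, 2, i, j), {
        sample_event_table(cohort, cfg, labels[i],
                           cfg$volume_growth_rates[i], t,
                           cfg$events_per_timepoint)
      })
    })
  }) |>
    mutate(event_id = sprintf("ev%07d", dplyr::row_number()))

  # Microscopy: sample cells directly (nuclei counts are true ploidies,
  # radii carry their own small measurement noise).
  cells <- purrr::map_dfr(seq_along(cfg$media_levels), function(i) {
    rate <- cfg$volume_growth_rates[i]
    purrr::map_dfr(seq_along(cfg$sample_times_h), function(j) {
      t <- cfg$sample_times_h[j]
      withr::with_seed(mix_seed(seed, 4, i, j), {
        n <- cfg$cells_per_timepoint_microscopy
        cdat <- cohort$cells
        burst_done <- !is.na(cdat$burst_time_h) & cdat$burst_time_h <= t
        weight <- ifelse(burst_done, cdat$brood_size, 1)
        idx <- sample(cohort$n, n, replace = TRUE, prob = weight)
        nb <- burst_done[idx]
        ploidy <- volume <- numeric(n)
        if (any(!nb)) {
          mi <- idx[!nb]
          ndv <- rowSums(cohort$cum[mi, , drop = FALSE] <= t)
          ploidy[!nb] <- pmin(cdat$initial_ploidy[mi] * 2^ndv,
                              cdat$burst_threshold[mi])
          volume[!nb] <- cdat$v0_um3[mi] * exp(rate * t)
        }
        if (any(nb)) {
          ni <- idx[nb]
          dt <- t - cdat$burst_time_h[ni]
          kmax <- max(1L,
                      ceiling(max(dt) /
                                cfg$division_model$mean_doubling_time) + 2L)
          iv <- row_cumsum(draw_intervals(
            length(ni), kmax, cfg$division_model$mean_doubling_time,
            cfg$division_model$cv * cfg$division_model$mean_doubling_time))
          ndv <- rowSums(iv <= dt)
          ploidy[nb] <- cdat$newborn_ploidy[ni] * 2^ndv
          v_birth <- cdat$v0_um3[ni] * exp(rate * cdat$burst_time_h[ni]) /
            cdat$brood_size[ni] * lnorm_noise(length(ni), cfg$partition_cv)
          volume[nb] <- v_birth * exp(rate * dt)
        }
        tibble(
          cell_id = sprintf("mc_%s_t%02d_%03d", labels[i], j, seq_len(n)),
          n_nuclei = as.integer(ploidy),
          radius_um = sphere_radius(volume) * lnorm_noise(n, cfg$radius_cv),
          time_h = t,
          condition = labels[i]
        )
      })
    })
  })

  times_tl <- seq(0, cfg$timelapse_hours, by = cfg$timelapse_step_h)
  areas <- purrr::map_dfr(seq_along(cfg$media_levels), function(i) {
    rate <- cfg$volume_growth_rates[i]
    withr::with_seed(mix_seed(seed, 5, i), {
      idx <- sample(cohort$n, cfg$timelapse_cells)
      purrr::map_dfr(seq_along(idx), function(kk) {
        v <- cohort$cells$v0_um3[idx[kk]] * exp(rate * times_tl)
        tibble(
          cell_id = sprintf("tl_%s_%03d", labels[i], kk),
          time_h = times_tl,
          area_um2 = pi * sphere_radius(v)^2 *
            lnorm_noise(length(times_tl), cfg$area_cv),
          condition = labels[i]
        )
      })
    })
  })

  division_times <- apply(cohort$cum, 1, function(x) {
    paste(format(round(x, 4), trim = TRUE), collapse = ";")
  })
  ground_truth <- list(
    cells = cohort$cells |> mutate(division_times_h = division_times),
    media = tibble(condition = labels,
                   media_level = cfg$media_levels,
                   volume_growth_rate = cfg$volume_growth_rates),
    config = cfg,
    seed = seed
  )
  structure(
    list(events = events, cells = cells, areas = areas,
         ground_truth = ground_truth, config = cfg, seed = seed),
    class = "coenocycle_experiment"
  )
}

#' Mixed-stage calibration sample with known reference
#'
#' Pools events uniformly across ploidy bins (by default every power of
#' two from 1C up to the maximum burst threshold) so that each bin is
#' represented, emulating a co-stained mixture of all coenocytic-cycle
#' stages. The true reference intensity is attached as attribute
#' `reference_intensity` (ground truth for tests only).
#'
#' @param config An [experiment_config()].
#' @param n_events Number of pooled events (>= 100).
#' @param seed Integer seed.
#' @param ploidies Optional vector of ploidies to pool over (powers of
#'   two); defaults to `2^(0:log2(max burst threshold))`.
#'
#' @return An event tibble (`event_id`, `dapi_intensity`, `ssc`, `fsc`,
#'   `time_h`, `condition`) with `condition = "mixed"`.
#' @export
generate_mixed_calibration_sample <- function(config = experiment_config(),
                                              n_events = 5000, seed = 1,
                                              ploidies = NULL) {
  cfg <- validate_experiment_config(config)
  if (n_events < 100) {
    abort("`n_events` must be at least 100 for a usable calibration pool.",
          class = "coenocycle_invalid_input")
  }
  ploidies <- ploidies %||% 2^(0:round(log2(cfg$burst_ploidy_range[2])))
  if (any(!is_power_of_two(ploidies))) {
    abort("`ploidies` must be powers of two.",
          class = "coenocycle_invalid_input")
  }
  withr::with_seed(mix_seed(seed, 9), {
    ploidy <- rep_len(ploidies, n_events)
    intensity <- cfg$intensity_reference * ploidy *
      lnorm_noise(n_events, cfg$intensity_cv)
    vol <- sphere_volume(cfg$newborn_radius_um) * ploidy
    out <- tibble(
      event_id = sprintf("mix%06d", seq_len(n_events)),
      dapi_intensity = intensity,
      ssc = vol^cfg$ssc_exponent * lnorm_noise(n_events, cfg$ssc_cv),
      fsc = vol^(1 / 3) * lnorm_noise(n_events, cfg$fsc_cv),
      time_h = NA_real_,
      condition = "mixed"
    )
  })
  attr(out, "reference_intensity") <- cfg$intensity_reference
  out
}
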
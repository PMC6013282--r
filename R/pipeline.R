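default_pipeline_config <- function() {
  list(
    experiment = list(),          # overrides passed to experiment_config()
    mean_doubling_time = 11,
    cv = 0.10,
    calibration_events = 5000,
    fit_window = c(0, 36),
    gsd_mode = "sqrt",
    cv_grid = c(0.025, 0.05, 0.10, 0.15),
    envelope_replicates = 100,
    envelope_cells = 5000,
    compare_ploidy = 16
  )
}

load_pipeline_config <- function(config = NULL) {
  base <- default_pipeline_config()
  user <- list()
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("Config file not found: ", config),
            class = "coenocycle_missing_input")
    }
    user <- yaml::read_yaml(config)
  } else if (is.list(config)) {
    user <- config
  } else if (!is.null(config)) {
    abort("`config` must be NULL, a file path, or a list.",
          class = "coenocycle_invalid_config")
  }
  utils::modifyList(base, user)
}

write_stage <- function(x, path) {
  readr::write_tsv(x, path)
  path
}

#' Run the full synthetic-experiment analysis pipeline
#'
#' Orchestrates generate → calibrate/bin → flow statistics → simulation
#' envelopes → size statistics, writing all intermediates and a summary to
#' `out_dir`. Every stage is driven by the single `seed`; re-running with
#' the same configuration and seed reproduces identical outputs. A
#' manifest (JSON) records the configuration, seed, package version and
#' per-stage output files with checksums.
#'
#' @param config `NULL` for defaults, a path to a YAML file, or a list of
#'   overrides. Recognized top-level keys: `experiment` (list passed to
#'   [experiment_config()]), `mean_doubling_time`, `cv`,
#'   `calibration_events`, `fit_window`, `gsd_mode`, `cv_grid`,
#'   `envelope_replicates`, `envelope_cells`, `compare_ploidy`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for every stochastic stage.
#' @param quiet Suppress progress messages.
#'
#' @return (Invisibly) a list with the key results: `calibration`,
#'   `ploidy_summary`, `doubling_times`, `cv_bound`, `size_comparisons`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = NULL, out_dir = "coenocycle-run",
                         seed = 1, quiet = FALSE) {
  cfg <- load_pipeline_config(config)
  say <- function(...) if (!quiet) inform(paste0("[coenocycle] ", ...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)

  model <- division_model(cfg$mean_doubling_time, cfg$cv)
  exp_cfg <- do.call(experiment_config,
                     c(list(division_model = model), cfg$experiment))

  say("stage generate: synthesizing experiment (seed ", seed, ")")
  exper <- generate_experiment(exp_cfg, seed = seed)
  mixed <- generate_mixed_calibration_sample(exp_cfg,
                                             n_events = cfg$calibration_events,
                                             seed = seed)
  outputs <- c(outputs,
               write_stage(exper$events, file.path(out_dir, "events.tsv")),
               write_stage(exper$cells, file.path(out_dir, "cells.tsv")),
               write_stage(exper$areas, file.path(out_dir, "areas.tsv")),
               write_stage(mixed, file.path(out_dir, "mixed.tsv")),
               write_stage(exper$ground_truth$cells,
                           file.path(out_dir, "ground_truth.tsv")))

  say("stage analyze-flow: calibration, binning, doubling times, asynchrony")
  cal <- calibrate_reference(mixed)
  binned <- assign_ploidy(exper$events, cal, quiet = TRUE)
  summaries <- summarize_ploidy(binned, mode = cfg$gsd_mode)
  outputs <- c(outputs,
               write_stage(summaries, file.path(out_dir,
                                                "ploidy_summary.tsv")))

  fits <- summaries |>
    group_by(.data$condition) |>
    group_modify(function(df, key) {
      glance(fit_doubling_time(df, window = cfg$fit_window))
    }) |>
    ungroup()
  outputs <- c(outputs,
               write_stage(fits, file.path(out_dir, "doubling_times.tsv")))
  jsonlite::write_json(fits, file.path(out_dir, "doubling_times.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, file.path(out_dir, "doubling_times.json"))

  say("stage simulate: asynchrony envelopes on CV grid {",
      paste(cfg$cv_grid, collapse = ", "), "}")
  grid_times <- exp_cfg$sample_times_h
  envelopes <- purrr::map(cfg$cv_grid, function(cv) {
    asynchrony_envelope(division_model(cfg$mean_doubling_time, cv),
                        init = exp_cfg$initial_distribution,
                        n_cells = cfg$envelope_cells,
                        n_replicates = cfg$envelope_replicates,
                        time_grid = grid_times,
                        seed = mix_seed(seed, 7, round(cv * 1000)),
                        gsd_mode = cfg$gsd_mode)
  })
  env_tbl <- purrr::map_dfr(envelopes, function(e) {
    as_tibble(e) |> mutate(cv = attr(e, "cv"),
                           n_replicates = attr(e, "n_replicates"))
  })
  outputs <- c(outputs,
               write_stage(env_tbl, file.path(out_dir, "envelopes.tsv")))

  # observed asynchrony: restrict to the pre-burst window so newborn cells
  # do not contaminate the GSD, then bound the timing CV
  obs_all <- summaries |>
    filter(.data$time_h <= cfg$fit_window[2])
  cv_bounds <- obs_all |>
    group_by(.data$condition) |>
    group_modify(function(df, key) {
      obs <- delta_asynchrony(df[c("time_h", "log2_gsd")])
      cv_upper_bound(obs, envelopes)
    }) |>
    ungroup()
  jsonlite::write_json(cv_bounds, file.path(out_dir, "cv_bounds.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, file.path(out_dir, "cv_bounds.json"))

  say("stage analyze-size: volumes, ratios, media comparisons")
  cells <- nuclei_volume_ratio(exper$cells)
  conds <- unique(cells$condition)
  rich <- conds[1]; poor <- conds[length(conds)]
  at_bin <- cells |> filter(.data$n_nuclei == cfg$compare_ploidy)
  size_cmp <- NULL
  if (all(table(factor(at_bin$condition, levels = c(rich, poor)))[c(rich, poor)] > 0)) {
    vol_cmp <- compare_groups(at_bin$volume_um3[at_bin$condition == rich],
                              at_bin$volume_um3[at_bin$condition == poor])
    ratio_cmp <- compare_groups(
      at_bin$nuclei_per_um3[at_bin$condition == poor],
      at_bin$nuclei_per_um3[at_bin$condition == rich])
    size_cmp <- bind_rows(
      vol_cmp |> mutate(quantity = "volume_um3",
                        groups = paste(rich, "vs", poor), .before = 1),
      ratio_cmp |> mutate(quantity = "nuclei_per_um3",
                          groups = paste(poor, "vs", rich), .before = 1)
    )
  }
  rel <- relative_area(exper$areas)
  rel_end <- rel |>
    group_by(.data$cell_id, .data$condition) |>
    summarise(final_relative_area = .data$relative_area[
      which.max(.data$time_h)], .groups = "drop")
  area_cmp <- compare_groups(
    rel_end$final_relative_area[rel_end$condition == rich],
    rel_end$final_relative_area[rel_end$condition == poor]) |>
    mutate(quantity = "final_relative_area",
           groups = paste(rich, "vs", poor), .before = 1)
  size_cmp <- bind_rows(size_cmp, area_cmp)
  jsonlite::write_json(size_cmp, file.path(out_dir, "size_comparisons.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, file.path(out_dir, "size_comparisons.json"))

  say("stage report: summary and manifest")
  summary_lines <- c(
    "coenocycle pipeline summary",
    sprintf("seed: %d", seed),
    "",
    "Nuclear doubling times (log2 geometric-mean OLS):",
    sprintf("  %-8s %6.2f h (slope SE %.4f, %d points)",
            fits$condition, fits$doubling_time_h, fits$slope_se,
            fits$n_points),
    "",
    "Division-timing CV upper bounds (vs simulated envelopes):",
    sprintf("  %-8s cv <= %.3f%s", cv_bounds$condition, cv_bounds$cv,
            ifelse(cv_bounds$bounded, "", " (not bounded by grid)")),
    "",
    "Size comparisons (Wilcoxon rank-sum):",
    sprintf("  %-20s %-18s p = %.3g (%s)", size_cmp$quantity,
            size_cmp$groups, size_cmp$p_value, size_cmp$direction)
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  outputs <- c(outputs, file.path(out_dir, "summary.txt"))

  manifest <- list(
    package = "coenocycle",
    version = as.character(utils::packageVersion("coenocycle")),
    seed = seed,
    config = cfg[setdiff(names(cfg), "experiment")],
    experiment_overrides = cfg$experiment,
    outputs = lapply(outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(calibration = cal, ploidy_summary = summaries,
                 doubling_times = fits, cv_bounds = cv_bounds,
                 size_comparisons = size_cmp, manifest = manifest))
}
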
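#' Build a validated pipeline run configuration
#'
#' All knobs of the end-to-end analysis in one serializable object. A snapshot
#' of the configuration is written alongside every run's outputs so results are
#' traceable to their settings.
#'
#' @param scoring_csv,meta_csv Paths to the scoring and per-cell metadata CSVs.
#' @param species Species label (must match the scoring file).
#' @param axis_cells,cold_setting,warm_setting Plate design parameters.
#' @param cell_temps_csv Optional measured cell temperatures overriding the
#'   nominal design values.
#' @param k Optional smooth basis dimension for every candidate (recommended 4
#'   for plates of <= 21 cells).
#' @param holdout_fraction,reps Monte Carlo holdout settings.
#' @param seed Master RNG seed for the resampling.
#' @param rule Model selection rule (\code{"min_rmse"}, \code{"min_mean_error"},
#'   \code{"manual"}).
#' @param manual_label Candidate label for manual selection.
#' @param climate_current_csv CSV of the current-climate series.
#' @param climate_future_csv CSV of future-model series (ensemble-averaged).
#' @param climate_scale Temperature scale factor for the climate CSVs.
#' @param extrapolation Prediction policy outside the plate's temperature range.
#' @param out_dir Output directory (created if missing).
#' @return A \code{run_config} list.
#' @export
run_config <- function(scoring_csv, meta_csv, species,
                       axis_cells, cold_setting = 5, warm_setting = 45,
                       cell_temps_csv = NULL, k = NULL,
                       holdout_fraction = 0.10, reps = 100, seed = 1,
                       rule = "min_rmse", manual_label = NULL,
                       climate_current_csv = NULL, climate_future_csv = NULL,
                       climate_scale = 1,
                       extrapolation = "clamp", out_dir = "tgpgerm_run") {
  cfg <- list(
    scoring_csv = scoring_csv, meta_csv = meta_csv, species = species,
    axis_cells = axis_cells, cold_setting = cold_setting,
    warm_setting = warm_setting, cell_temps_csv = cell_temps_csv, k = k,
    holdout_fraction = holdout_fraction, reps = reps, seed = seed,
    rule = rule, manual_label = manual_label,
    climate_current_csv = climate_current_csv,
    climate_future_csv = climate_future_csv, climate_scale = climate_scale,
    extrapolation = extrapolation, out_dir = out_dir
  )
  for (p in c("scoring_csv", "meta_csv")) {
    if (!file.exists(cfg[[p]])) {
      tgp_abort(sprintf("%s not found: %s", p, cfg[[p]]), "tgp_config_error")
    }
  }
  if (!is_scalar_number(cfg$holdout_fraction) || cfg$holdout_fraction <= 0 ||
      cfg$holdout_fraction >= 1) {
    tgp_abort("holdout_fraction must be in (0, 1)", "tgp_config_error")
  }
  if (!is_scalar_number(cfg$reps) || cfg$reps < 1) {
    tgp_abort("reps must be >= 1", "tgp_config_error")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the \code{\link{run_config}}
#'   arguments.
#' @return A validated \code{run_config}.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

pipeline_log <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(...))
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

#' Run the full TGP analysis pipeline
#'
#' Executes ingest, regularization, index computation, candidate GAM fitting,
#' Monte Carlo holdout evaluation, model selection, climate prediction and
#' plotting, writing every table as CSV (each figure has a CSV twin), the
#' figures as PNG, a log, and a JSON snapshot of the configuration. Rerunning
#' with the same config and seed reproduces the CSV outputs exactly.
#'
#' @param config A \code{\link{run_config}}.
#' @return A run report: list with the experiment, indices table, comparison
#'   table, selected model label, refitted selected surface, monthly
#'   predictions (when climate inputs were given), seasonal shift report and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  snap <- unclass(config)
  snap$package_version <- as.character(utils::packageVersion("tgpgerm"))
  jsonlite::write_json(snap, file.path(config$out_dir, "config_snapshot.json"),
                       auto_unbox = TRUE, null = "null")
  pipeline_log(log_path, "tgpgerm %s | seed %d | %s",
               snap$package_version, config$seed, config$species)

  design <- make_half_grid(config$axis_cells, config$cold_setting,
                           config$warm_setting)
  if (!is.null(config$cell_temps_csv)) {
    design <- set_cell_temperatures(design,
                                    read_cell_temps_csv(config$cell_temps_csv))
  }
  exp <- read_scoring_csv(config$scoring_csv, config$meta_csv, design,
                          species = config$species)
  pipeline_log(log_path, "ingest: %d cells scored", length(exp$series))

  idx <- indices_table(exp)
  write_indices_csv(idx, file.path(config$out_dir, "indices.csv"))

  cells <- model_table(exp)
  cells <- cells[cells$viable_n >= 1, , drop = FALSE]
  specs <- default_candidates(k = config$k)
  evals <- evaluate_candidates(specs, cells,
                               holdout_fraction = config$holdout_fraction,
                               reps = config$reps, seed = config$seed)
  comp <- comparison_table(evals, rule = config$rule,
                           manual_label = config$manual_label)
  utils::write.csv(comp, file.path(config$out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  selected <- comp$model[comp$selected]
  pipeline_log(log_path, "selected model (%s): %s", config$rule, selected)
  spec <- specs[[match(selected,
                       vapply(specs, function(s) s$label, character(1)))]]
  surface <- fit_surface(spec, cells)

  # quilt plots of observed and modelled final germination
  obs_q <- quilt_plot(
    data.frame(day_temp = cells$day_temp, night_temp = cells$night_temp,
               final_germination_proportion = cells$successes / cells$viable_n),
    title = "Observed final germination proportion")
  fit_q <- quilt_plot(
    data.frame(day_temp = cells$day_temp, night_temp = cells$night_temp,
               final_germination_proportion = surface$fitted),
    title = sprintf("Modelled: %s", selected))
  utils::write.csv(obs_q$grid, file.path(config$out_dir, "quilt_observed.csv"),
                   row.names = FALSE)
  utils::write.csv(fit_q$grid, file.path(config$out_dir, "quilt_modelled.csv"),
                   row.names = FALSE)
  save_plot_png(obs_q$plot, file.path(config$out_dir, "quilt_observed.png"))
  save_plot_png(fit_q$plot, file.path(config$out_dir, "quilt_modelled.png"))

  preds <- list()
  shift <- NULL
  if (!is.null(config$climate_current_csv)) {
    cur <- ensemble_average(read_climate_csv(config$climate_current_csv,
                                             scale = config$climate_scale))
    preds$current <- predict_monthly(surface, cur,
                                     extrapolation = config$extrapolation)
    if (!is.null(config$climate_future_csv)) {
      fut <- ensemble_average(read_climate_csv(config$climate_future_csv,
                                               scale = config$climate_scale))
      preds$future <- predict_monthly(surface, fut,
                                      extrapolation = config$extrapolation)
      shift <- seasonal_shift_report(preds$current, preds$future)
      jsonlite::write_json(shift,
                           file.path(config$out_dir, "seasonal_shift.json"),
                           auto_unbox = TRUE)
    }
    write_predictions_csv(preds,
                          file.path(config$out_dir, "monthly_predictions.csv"))
    save_plot_png(monthly_plot(preds),
                  file.path(config$out_dir, "monthly_predictions.png"))
    pipeline_log(log_path, "climate predictions written (%d scenario(s))",
                 length(preds))
  }
  pipeline_log(log_path, "done")
  list(experiment = exp, indices = idx, comparison = comp,
       selected = selected, surface = surface, predictions = preds,
       seasonal_shift = shift, out_dir = config$out_dir)
}

save_plot_png <- function(plot, path, width = 7, height = 5) {
  grDevices::png(path, width = width, height = height, units = "in", res = 120)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
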
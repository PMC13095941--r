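#' Run the full analysis pipeline
#'
#' Orchestrates data in, per-subject fits, group comparison, report:
#' validates the input trial table, fits every requested model to every
#' participant, runs the group-level comparison, and writes `fits.csv`,
#' `comparison.json`, one predicted-trajectory CSV per model, and a
#' `manifest.json` with the configuration, seeds, package version and a
#' checksum for every output file. Re-running with identical config and
#' inputs reproduces identical primary outputs.
#'
#' @param config Either a named list or the path to a YAML/JSON file with
#'   fields:
#'   * `input` — path to a long-format trial-table CSV with columns
#'     `participant`, `trial`, `trial_type`, `exertion_E` (or `auc_norm`),
#'     `rating` (optional `success`, `t_rest`, `effort_level`, `reward`);
#'   * `baselines` — optional path to a CSV with columns `participant`,
#'     `baseline`;
#'   * `out_dir` — output directory (created if needed);
#'   * `models` — character vector of model ids (default: all for the
#'     readout);
#'   * `readout` — `"fatigue"` (default) or `"effort"`;
#'   * `combination` — `"multiplicative"` (default) or `"additive"`;
#'   * `state_timing`, `include_failed`, `n_starts` — fitting options;
#'   * `prior_alpha`, `ep_samples`, `seed` — comparison options.
#' @return Invisibly, a list with the `fits` (`fatigue_cohort_fits`), the
#'   `comparison` (`fatigue_bms`) and the `manifest` list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop("`config` must be a list or the path to a YAML/JSON file",
         call. = FALSE)
  }
  for (field in c("input", "out_dir")) {
    if (is.null(config[[field]])) {
      stop("config is missing required field `", field, "`", call. = FALSE)
    }
  }
  if (!file.exists(config$input)) {
    stop("input file not found: ", config$input, call. = FALSE)
  }
  readout <- config$readout %||% "fatigue"
  combination <- config$combination %||% "multiplicative"
  models <- config$models %||% model_ids(readout)
  seed <- config$seed %||% 1L

  data <- utils::read.csv(config$input, stringsAsFactors = FALSE)
  if (!"participant" %in% names(data)) {
    stop("trial table `", config$input,
         "` is missing required column `participant`", call. = FALSE)
  }
  # validate the full schema up front so malformed input produces a clear
  # error before any output is written
  invisible(validate_trial_table(data))

  baselines <- NULL
  if (!is.null(config$baselines)) {
    bl <- utils::read.csv(config$baselines, stringsAsFactors = FALSE)
    if (!all(c("participant", "baseline") %in% names(bl))) {
      stop("baseline table needs columns `participant`, `baseline`",
           call. = FALSE)
    }
    baselines <- stats::setNames(bl$baseline, bl$participant)
  }

  fits <- fit_cohort(data, models = models, readout = readout,
                     combination = combination, baselines = baselines,
                     state_timing = config$state_timing %||% "post",
                     include_failed = config$include_failed %||% TRUE,
                     n_starts = config$n_starts %||% 6)
  comparison <- compare_fatigue_models(
    fits,
    prior_alpha = config$prior_alpha %||% 1,
    ep_samples = config$ep_samples %||% 1e6,
    seed = seed)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_files <- character(0)

  fits_path <- file.path(config$out_dir, "fits.csv")
  utils::write.csv(fits$table, fits_path, row.names = FALSE)
  out_files <- c(out_files, fits_path)

  for (m in models) {
    traj <- do.call(rbind, lapply(names(fits$fits), function(id) {
      tr <- fits$fits[[id]][[m]]$trajectory
      cbind(participant = id, tr)
    }))
    p <- file.path(config$out_dir, paste0("trajectory_", m, ".csv"))
    utils::write.csv(traj, p, row.names = FALSE)
    out_files <- c(out_files, p)
  }

  cmp_path <- file.path(config$out_dir, "comparison.json")
  jsonlite::write_json(list(
    models = comparison$models,
    n_subjects = comparison$n_subjects,
    summed_aic = as.list(comparison$summed_aic),
    best_count_aic = as.list(as.integer(comparison$best_count_aic)),
    best_count_rss = as.list(as.integer(comparison$best_count_rss)),
    dirichlet_alpha = as.list(comparison$alpha),
    expected_frequency = as.list(comparison$expected_frequency),
    exceedance_probability = as.list(comparison$exceedance_probability),
    bms_n_iter = comparison$bms_n_iter
  ), cmp_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out_files <- c(out_files, cmp_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fatiguedyn")),
    r_version = R.version.string,
    config = config[setdiff(names(config), NULL)],
    seed = seed,
    n_participants = length(fits$fits),
    n_models = length(models),
    n_fits = nrow(fits$table),
    files = lapply(out_files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  man_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(fits = fits, comparison = comparison, manifest = manifest))
}

#' Simulate, fit, compare, and report in one call
#'
#' Convenience wrapper chaining [simulate_cohort()], [fit_cohort()],
#' [compare_fatigue_models()] and [recovery_report()] — the standard
#' parameter/model-recovery experiment.
#'
#' @param config A [sim_config()].
#' @param models Models to fit (default: all for the readout).
#' @param ep_samples,seed Comparison options; `seed` defaults to the
#'   simulation seed.
#' @param ... Passed to [fit_cohort()].
#' @return List with `cohort`, `fits`, `comparison`, `report`.
#' @export
run_recovery <- function(config, models = NULL, ep_samples = 1e6,
                         seed = NULL, ...) {
  cohort <- simulate_cohort(config)
  fits <- fit_cohort(cohort, models = models, readout = config$readout,
                     combination = config$combination, ...)
  comparison <- if (length(fits$models) > 1L) {
    compare_fatigue_models(fits, ep_samples = ep_samples,
                           seed = seed %||% config$seed)
  } else NULL
  report <- recovery_report(cohort, fits, comparison)
  list(cohort = cohort, fits = fits, comparison = comparison,
       report = report)
}
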
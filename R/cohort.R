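#' Fit candidate models to every participant in a cohort
#'
#' Runs [fit_fatigue()] for each participant x model combination and
#' collects the results in a tidy table (one row per fit) plus the full
#' fit objects.
#'
#' @param data A `fatigue_cohort` from [simulate_cohort()], or a long trial
#'   table with a `participant` column (see [fit_fatigue()] for the other
#'   required columns).
#' @param models Character vector of model ids; default all models valid
#'   for the readout.
#' @param readout,combination,state_timing,include_failed,n_starts,control
#'   Passed to [fit_fatigue()].
#' @param baselines Named numeric vector of per-participant baseline
#'   ratings (names = participant ids); taken from the cohort object when
#'   one is supplied.
#' @param verbose Print one line per participant (default `FALSE`).
#' @return An object of class `fatigue_cohort_fits`: list with `table`
#'   (data frame: `participant`, `model`, one column per parameter, `rss`,
#'   `n_obs`, `n_params`, `aic`, `r_squared`) and `fits` (nested list,
#'   `fits[[participant]][[model]]`).
#' @export
fit_cohort <- function(data, models = NULL,
                       readout = c("fatigue", "effort"),
                       combination = c("multiplicative", "additive"),
                       baselines = NULL,
                       state_timing = c("post", "pre"),
                       include_failed = TRUE,
                       n_starts = 6,
                       control = list(),
                       verbose = FALSE) {
  readout <- match.arg(readout)
  combination <- match.arg(combination)
  state_timing <- match.arg(state_timing)
  if (inherits(data, "fatigue_cohort")) {
    if (is.null(baselines)) {
      baselines <- stats::setNames(data$participants$baseline,
                                   data$participants$participant)
    }
    data <- data$data
  }
  if (!"participant" %in% names(data)) {
    stop("`data` needs a `participant` column", call. = FALSE)
  }
  models <- models %||% model_ids(readout)
  ids <- unique(data$participant)
  fits <- stats::setNames(vector("list", length(ids)), ids)
  rows <- vector("list", length(ids) * length(models))
  r <- 0L
  for (id in ids) {
    d <- data[data$participant == id, , drop = FALSE]
    bl <- if (!is.null(baselines)) baselines[[as.character(id)]] else NULL
    if (!is.null(bl) && is.na(bl)) bl <- NULL
    fits[[as.character(id)]] <- stats::setNames(vector("list", length(models)),
                                                models)
    for (m in models) {
      fit <- fit_fatigue(d, model = m, readout = readout,
                         combination = combination, baseline = bl,
                         include_failed = include_failed,
                         state_timing = state_timing, n_starts = n_starts,
                         control = control)
      fits[[as.character(id)]][[m]] <- fit
      r <- r + 1L
      pars <- c(alpha = NA_real_, delta = NA_real_, theta = NA_real_,
                gamma = NA_real_)
      pars[names(fit$params)] <- fit$params
      rows[[r]] <- data.frame(
        participant = id, model = m, t(pars),
        rss = fit$rss, n_obs = fit$n_obs, n_params = fit$n_params,
        aic = fit$aic, r_squared = fit$r_squared,
        stringsAsFactors = FALSE
      )
    }
    if (verbose) {
      aics <- vapply(fits[[as.character(id)]], `[[`, numeric(1), "aic")
      message("participant ", id, ": best model by AIC = ",
              models[which.min(aics)])
    }
  }
  structure(list(table = do.call(rbind, rows[seq_len(r)]), fits = fits,
                 models = models, readout = readout,
                 combination = combination),
            class = "fatigue_cohort_fits")
}

#' @export
print.fatigue_cohort_fits <- function(x, ...) {
  cat("Cohort fits: ", length(x$fits), " participants x ",
      length(x$models), " models (", x$readout, " readout)\n", sep = "")
  cat("  median R^2 per model:\n")
  med <- tapply(x$table$r_squared, x$table$model, stats::median,
                na.rm = TRUE)
  print(round(med[x$models], 3))
  invisible(x)
}

#' Parameter- and model-recovery report
#'
#' Joins ground-truth parameters of a simulated cohort with the fitted
#' estimates and summarizes how well they were recovered: per-parameter
#' Pearson correlation, bias and RMSE, the fraction of participants whose
#' AIC-best model equals the generating model, and (when a comparison is
#' supplied) the generating model's exceedance probability.
#'
#' @param cohort A `fatigue_cohort` carrying ground truth.
#' @param fits A `fatigue_cohort_fits` covering the generating model.
#' @param comparison Optional `fatigue_bms` from
#'   [compare_fatigue_models()].
#' @return An object of class `recovery_report`: list with `parameters`
#'   (data frame: `parameter`, `correlation`, `bias`, `rmse`),
#'   `model_recovery` (fraction best-fit by the generating model, or `NA`
#'   if only one model was fitted), `generating_model`,
#'   `exceedance_probability` (of the generating model, or `NA`), and the
#'   joined `estimates` table.
#' @export
recovery_report <- function(cohort, fits, comparison = NULL) {
  stopifnot(inherits(cohort, "fatigue_cohort"),
            inherits(fits, "fatigue_cohort_fits"))
  gen <- cohort$config$model
  if (!gen %in% fits$models) {
    stop("fits do not cover the generating model '", gen, "'", call. = FALSE)
  }
  free <- free_params(gen, cohort$config$readout)
  tab <- fits$table[fits$table$model == gen, , drop = FALSE]
  joined <- merge(cohort$truth, tab, by = "participant",
                  suffixes = c("_true", "_hat"))
  if (!setequal(tab$participant, cohort$truth$participant) ||
      nrow(joined) != nrow(cohort$truth)) {
    stop("participant ids in fits do not match the cohort", call. = FALSE)
  }
  param_stats <- do.call(rbind, lapply(free, function(p) {
    tru <- joined[[paste0(p, "_true")]]
    hat <- joined[[paste0(p, "_hat")]]
    data.frame(
      parameter = p,
      correlation = if (stats::sd(tru) > 0 && stats::sd(hat) > 0) {
        stats::cor(tru, hat)
      } else NA_real_,
      bias = mean(hat - tru),
      rmse = sqrt(mean((hat - tru)^2))
    )
  }))
  model_rec <- NA_real_
  if (length(fits$models) > 1L) {
    ids <- unique(fits$table$participant)
    aic <- sapply(fits$models, function(m) {
      sub <- fits$table[fits$table$model == m, ]
      sub$aic[match(ids, sub$participant)]
    })
    best <- fits$models[apply(aic, 1L, which.min)]
    model_rec <- mean(best == gen)
  }
  ep <- NA_real_
  if (!is.null(comparison)) {
    stopifnot(inherits(comparison, "fatigue_bms"))
    ep <- unname(comparison$exceedance_probability[gen])
  }
  structure(list(
    parameters = param_stats,
    model_recovery = model_rec,
    generating_model = gen,
    exceedance_probability = ep,
    estimates = joined
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, digits = 3, ...) {
  cat("Recovery report (generating model: ", x$generating_model, ")\n",
      sep = "")
  tab <- x$parameters
  tab$correlation <- round(tab$correlation, digits)
  tab$bias <- signif(tab$bias, digits)
  tab$rmse <- signif(tab$rmse, digits)
  print(tab, row.names = FALSE)
  if (!is.na(x$model_recovery)) {
    cat("Model recovery (AIC-best == generating): ",
        round(100 * x$model_recovery, 1), "%\n", sep = "")
  }
  if (!is.na(x$exceedance_probability)) {
    cat("Exceedance probability of generating model: ",
        round(x$exceedance_probability, digits), "\n", sep = "")
  }
  invisible(x)
}
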
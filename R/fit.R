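#' AIC from a residual sum of squares
#'
#' \deqn{AIC = n \ln(RSS/n) + 2 d}
#' with n the number of observations (rated trials) and d the number of
#' fitted parameters. An RSS at or below `rss_floor` (which arises for
#' noiseless synthetic data) is replaced by the floor with a warning, since
#' the formula is undefined at RSS = 0; set `rss_floor = NULL` to treat
#' that case as an error instead.
#'
#' @param rss Residual sum of squares (> 0 in regular use).
#' @param n_obs Number of observations contributing to `rss`.
#' @param n_params Number of fitted parameters.
#' @param rss_floor Smallest admissible RSS; default `1e-12`.
#' @return The AIC value.
#' @examples
#' aic_rss(240, 120, 3) # 120 * log(2) + 6
#' @export
aic_rss <- function(rss, n_obs, n_params, rss_floor = 1e-12) {
  stopifnot_scalar_number(rss, "rss", lower = 0)
  stopifnot_scalar_number(n_obs, "n_obs", lower = 1)
  stopifnot_scalar_number(n_params, "n_params", lower = 0)
  if (is.null(rss_floor)) {
    if (rss <= 0) stop("AIC is undefined for rss == 0", call. = FALSE)
  } else if (rss < rss_floor) {
    warning("rss below floor (", format(rss_floor),
            "); AIC computed at the floor", call. = FALSE)
    rss <- rss_floor
  }
  n_obs * log(rss / n_obs) + 2 * n_params
}

#' Squared observed-predicted correlation
#'
#' The fit-quality index reported alongside AIC: the squared Pearson
#' correlation between observed and predicted ratings.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3 pairs).
#' @return Squared correlation in \[0, 1\], or `NA` with a warning when
#'   either vector has zero variance.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3L) {
    stop("need >= 3 paired observations", call. = FALSE)
  }
  ok <- is.finite(observed) & is.finite(predicted)
  if (stats::sd(observed[ok]) == 0 || stats::sd(predicted[ok]) == 0) {
    warning("zero variance: R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(observed[ok], predicted[ok])^2
}

#' Factorial grid of optimizer initialisations
#'
#' Multi-start fitting launches one simplex search from every point of a
#' full factorial grid with `n_per_param` equally spaced values (endpoints
#' included) between `lo` and `hi` for each free parameter.
#'
#' @param free Character vector of free parameter names.
#' @param n_per_param Number of values per parameter (default 6).
#' @param lo,hi Grid range (defaults 0 and 1).
#' @return Data frame with one column per free parameter and
#'   `n_per_param ^ length(free)` rows.
#' @examples
#' nrow(initialisation_grid(c("alpha", "delta", "theta", "gamma"))) # 1296
#' @export
initialisation_grid <- function(free, n_per_param = 6, lo = 0, hi = 1) {
  if (n_per_param < 2) stop("`n_per_param` must be >= 2", call. = FALSE)
  vals <- seq(lo, hi, length.out = n_per_param)
  grid <- expand.grid(rep(list(vals), length(free)), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- free
  grid
}

# Penalty returned by the objective for parameter vectors outside the
# non-negativity constraint: large, finite, and increasing with the
# violation so the simplex is steered back into the feasible region.
.NEG_PENALTY <- 1e12

# Build the RSS objective for one participant and model as a closure over
# precomputed trial vectors; `par` is the free-parameter vector in the
# order given by `free`.
make_rss_objective <- function(free, E, t_rest, is_work, observed, mask,
                               F_start, model, readout, combination,
                               state_timing) {
  tie_delta <- model %in% c("rf1", "uf_rf1")
  obs <- observed[mask]
  force(free)
  function(par) {
    if (any(par < 0)) {
      return(.NEG_PENALTY * (1 + sum(pmax(0, -par))))
    }
    p <- c(alpha = 0, delta = 0, theta = 0, gamma = 0)
    p[free] <- par
    if (tie_delta) p[["delta"]] <- p[["alpha"]]
    core <- .trajectory_core(p[["alpha"]], p[["delta"]], p[["theta"]],
                             p[["gamma"]], E, t_rest, is_work, F_start,
                             readout, combination, state_timing)
    sum((obs - core$predicted[mask])^2)
  }
}

#' Fit a fatigue model to one participant's ratings
#'
#' Estimates the model parameters by minimising the residual sum of squares
#' between the participant's trial-by-trial ratings and the model's
#' predicted trajectory, under the constraint that all parameters (and the
#' recoverable fatigue state) are non-negative. A derivative-free
#' Nelder-Mead search is launched from every point of a factorial grid of
#' initialisations ([initialisation_grid()]; 6 values in \[0, 1\] per
#' parameter by default) to reduce the risk of local minima, and the best
#' solution is refined once more with tight tolerances. Fitting is fully
#' deterministic given the data and settings.
#'
#' @param data Data frame with one row per trial, ordered by trial, with
#'   columns `trial_type` (`"work"`/`"rest"`), `rating`, and either
#'   `exertion_E` or `auc_norm` (`exertion_E = auc_norm * 10`). Optional
#'   columns: `trial`, `t_rest`, `success`.
#' @param model Model id; see [fatigue-models].
#' @param readout `"fatigue"` or `"effort"` depending on which rating scale
#'   the participant used.
#' @param combination Combination rule for the effort readout.
#' @param baseline Baseline fatigue rating (see [resolve_baseline()]);
#'   `NULL` when none was collected.
#' @param include_failed Include failed work trials in the residuals
#'   (default `TRUE`; the model consumes the force actually produced).
#'   Trials with missing ratings are always excluded.
#' @param state_timing Passed to [fatigue_trajectory()].
#' @param n_starts Grid resolution per free parameter (default 6).
#' @param start_range Grid range, default `c(0, 1)`.
#' @param control Named list of optimizer settings: `reltol` (default
#'   `1e-8`), `maxit_factor` (iterations per start are
#'   `maxit_factor * n_params`, default 200), `polish` (logical, default
#'   `TRUE`: refine the best start with `reltol 1e-12` and 5000
#'   iterations).
#' @return An object of class `fatigue_fit`: a list with elements `model`,
#'   `readout`, `combination`, `params` (named vector of estimates),
#'   `rss`, `n_obs`, `n_params`, `aic`, `r_squared`, `F_start`,
#'   `trajectory` (data frame from [fatigue_trajectory()] plus `observed`),
#'   `n_starts` (grid points), `converged_fraction`, `n_ties`, `data`, and
#'   the settings used. Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `plot`, `simulate`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 1, seed = 42))
#' d <- cohort$data[cohort$data$participant == 1, ]
#' fit <- fit_fatigue(d, model = "full", readout = "fatigue",
#'                    baseline = cohort$participants$baseline[1])
#' coef(fit)
#' @export
fit_fatigue <- function(data,
                        model = "full",
                        readout = c("fatigue", "effort"),
                        combination = c("multiplicative", "additive"),
                        baseline = NULL,
                        include_failed = TRUE,
                        state_timing = c("post", "pre"),
                        n_starts = 6,
                        start_range = c(0, 1),
                        control = list()) {
  readout <- match.arg(readout)
  combination <- match.arg(combination)
  state_timing <- match.arg(state_timing)
  model <- match_model(model, readout)
  ctrl <- utils::modifyList(
    list(reltol = 1e-8, maxit_factor = 200, polish = TRUE), control)

  data <- validate_trial_table(data)
  E <- data$exertion_E
  trial_type <- data$trial_type
  t_rest <- if ("t_rest" %in% names(data)) data$t_rest else rest_time(trial_type)
  observed <- data$rating
  mask <- !is.na(observed)
  if (!include_failed && "success" %in% names(data)) {
    mask <- mask & (data$success | trial_type == "rest")
  }
  if (!any(mask)) {
    stop("no rated trials to fit", call. = FALSE)
  }
  F_start <- resolve_baseline(baseline)
  free <- free_params(model, readout)
  d <- length(free)

  obj <- make_rss_objective(free, E, t_rest, trial_type == "work", observed,
                            mask, F_start, model, readout, combination,
                            state_timing)

  if (d == 0L) {
    stop("model has no free parameters to fit", call. = FALSE)
  }
  grid <- initialisation_grid(free, n_starts, start_range[1], start_range[2])
  best <- NULL
  n_conv <- 0L
  n_fail <- 0L
  n_ties <- 0L
  maxit <- ctrl$maxit_factor * d
  for (i in seq_len(nrow(grid))) {
    start <- as.numeric(grid[i, ])
    res <- tryCatch(
      suppressWarnings(stats::optim(start, obj, method = "Nelder-Mead",
                                    control = list(maxit = maxit,
                                                   reltol = ctrl$reltol))),
      error = function(e) NULL)
    if (is.null(res)) {
      n_fail <- n_fail + 1L
      next
    }
    if (res$convergence == 0L) n_conv <- n_conv + 1L
    if (is.null(best)) {
      best <- res
    } else if (res$value < best$value) {
      best <- res
    } else if (res$value == best$value && !identical(res$par, best$par)) {
      n_ties <- n_ties + 1L # tie: keep the earlier start in grid order
    }
  }
  if (is.null(best)) {
    stop("optimization failed from every initialisation (", n_fail,
         " starts); check the data for non-finite values", call. = FALSE)
  }
  if (isTRUE(ctrl$polish)) {
    pol <- tryCatch(
      suppressWarnings(stats::optim(best$par, obj, method = "Nelder-Mead",
                                    control = list(maxit = 5000,
                                                   reltol = 1e-12))),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= best$value) best <- pol
  }

  params <- pmax(0, best$par)
  names(params) <- free
  rss <- obj(params)
  traj <- fatigue_trajectory(params, data, F_start, model = model,
                             readout = readout, combination = combination,
                             state_timing = state_timing)
  traj$observed <- observed
  n_obs <- sum(mask)
  aic <- suppressWarnings(aic_rss(rss, n_obs, d))
  r2 <- suppressWarnings(tryCatch(
    r_squared(observed[mask], traj$predicted[mask]),
    error = function(e) NA_real_))

  structure(list(
    model = model, readout = readout, combination = combination,
    params = params, rss = rss, n_obs = n_obs, n_params = d,
    aic = aic, r_squared = r2, F_start = F_start,
    trajectory = traj, fit_mask = mask,
    n_starts = nrow(grid), converged_fraction = n_conv / nrow(grid),
    n_ties = n_ties, state_timing = state_timing,
    include_failed = include_failed, data = data,
    control = ctrl
  ), class = "fatigue_fit")
}

# Validate the long-format per-trial table consumed by the fitting and
# simulation code; derives exertion_E from auc_norm when absent.
validate_trial_table <- function(data, need_rating = TRUE) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop("`data` must be a non-empty data frame of trials", call. = FALSE)
  }
  if (!"trial_type" %in% names(data)) {
    stop("`data` is missing required column `trial_type`", call. = FALSE)
  }
  if (!"exertion_E" %in% names(data)) {
    if ("auc_norm" %in% names(data)) {
      data$exertion_E <- data$auc_norm * 10
    } else {
      stop("`data` needs an `exertion_E` or `auc_norm` column", call. = FALSE)
    }
  }
  if (need_rating && !"rating" %in% names(data)) {
    stop("`data` is missing required column `rating`", call. = FALSE)
  }
  data$trial_type <- match_trial_type(data$trial_type)
  if ("trial" %in% names(data) && is.unsorted(data$trial)) {
    data <- data[order(data$trial), , drop = FALSE]
  }
  data
}

#' Closed-form null-model effort weight
#'
#' For the null effort model the prediction is \eqn{(\gamma + F_{start}) E}
#' on work trials and 0 on rest trials, so the least-squares
#' \eqn{\hat\gamma} has the closed form
#' \eqn{\sum r E / \sum E^2 - F_{start}} over rated work trials (floored at
#' zero under the non-negativity constraint). Used as an independent check
#' on the simplex optimizer.
#'
#' @inheritParams fit_fatigue
#' @return The constrained least-squares estimate of \eqn{\gamma}.
#' @export
null_gamma_closed_form <- function(data, baseline = NULL) {
  data <- validate_trial_table(data)
  F_start <- resolve_baseline(baseline)
  work <- data$trial_type == "work" & !is.na(data$rating)
  E <- data$exertion_E[work]
  r <- data$rating[work]
  if (sum(E^2) == 0) {
    stop("no work-trial exertion: gamma is unidentified", call. = FALSE)
  }
  max(0, sum(r * E) / sum(E^2) - F_start)
}
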
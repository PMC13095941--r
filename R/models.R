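#' The candidate fatigue-model family
#'
#' Total fatigue on trial t decomposes into a fixed baseline plus a
#' recoverable component RF (rises with exertion, falls with rest, floored
#' at zero) and an unrecoverable component UF (only accumulates):
#' \deqn{F_t = F_{start} + RF_t + UF_t}
#' with per-trial updates
#' \deqn{RF_t = \max(0,\; RF_{t-1} + \alpha E_t - \delta T_{rest,t})}
#' \deqn{UF_t = UF_{t-1} + \theta E_t}
#' where E is the exertion (normalized force AUC times 10) and the rest
#' time is 7.5 s on rest trials, 2.5 s on work trials. Candidate models free
#' different parameter subsets:
#'
#' * `"null"` — no fatigue dynamics; only the static effort weight
#'   \eqn{\gamma} (effort readout only).
#' * `"uf"` — unrecoverable component only (\eqn{\theta}).
#' * `"rf"` — recoverable component only (\eqn{\alpha}, \eqn{\delta}).
#' * `"rf1"` — one-parameter recoverable component: a single \eqn{\alpha}
#'   scales both the exertion rise and the rest decline
#'   (\eqn{\delta \equiv \alpha}).
#' * `"uf_rf1"` — unrecoverable plus the one-parameter recoverable
#'   component (\eqn{\theta}, \eqn{\alpha}).
#' * `"full"` — both components (\eqn{\alpha}, \eqn{\delta}, \eqn{\theta}).
#'
#' With the `"fatigue"` readout the predicted rating is \eqn{F_t} itself.
#' With the `"effort"` readout the prediction on work trials is
#' \eqn{PE_t = (\gamma + F_t) E_t} (multiplicative combination) or
#' \eqn{PE_t = \gamma E_t + F_t} (additive combination), and 0 on rest
#' trials; \eqn{\gamma} is then an additional free parameter.
#'
#' @param model Model id string (see above).
#' @param readout `"effort"` or `"fatigue"`.
#' @return `free_params()` returns the character vector of free parameter
#'   names for the model/readout combination. `model_ids()` returns all
#'   model ids valid for a readout.
#' @examples
#' free_params("full", "effort")
#' model_ids("fatigue")
#' @name fatigue-models
NULL

.model_base_params <- list(
  null = character(0),
  uf = "theta",
  rf = c("alpha", "delta"),
  rf1 = "alpha",
  uf_rf1 = c("theta", "alpha"),
  full = c("alpha", "delta", "theta")
)

#' @rdname fatigue-models
#' @export
model_ids <- function(readout = c("effort", "fatigue")) {
  readout <- match.arg(readout)
  if (readout == "effort") names(.model_base_params) else
    setdiff(names(.model_base_params), "null")
}

#' @rdname fatigue-models
#' @export
free_params <- function(model, readout = c("effort", "fatigue")) {
  readout <- match.arg(readout)
  model <- match_model(model, readout)
  base <- .model_base_params[[model]]
  if (readout == "effort") c(base, "gamma") else base
}

match_model <- function(model, readout) {
  if (!is.character(model) || length(model) != 1L ||
      !model %in% names(.model_base_params)) {
    stop("`model` must be one of: ",
         paste(names(.model_base_params), collapse = ", "), call. = FALSE)
  }
  if (model == "null" && readout == "fatigue") {
    stop("the null model is only defined for the effort readout", call. = FALSE)
  }
  model
}

# Expand a named vector of fitted values into the full (alpha, delta, theta,
# gamma) vector the trajectory uses: non-free parameters are 0 and the
# one-parameter recoverable models tie delta to alpha.
resolve_params <- function(model, params, readout) {
  full <- c(alpha = 0, delta = 0, theta = 0, gamma = 0)
  if (length(params)) {
    if (is.null(names(params)) || !all(names(params) %in% names(full))) {
      stop("`params` must be named among alpha, delta, theta, gamma",
           call. = FALSE)
    }
    full[names(params)] <- params
  }
  free <- free_params(model, readout)
  full[setdiff(names(full), free)] <- 0
  if (model %in% c("rf1", "uf_rf1")) {
    full[["delta"]] <- full[["alpha"]]
  }
  full
}

#' Single-trial latent-state updates
#'
#' `update_recoverable()` applies the exertion rise and rest decline to the
#' recoverable fatigue component in one step, flooring the result at zero
#' (negative recoverable fatigue is not allowed). `update_unrecoverable()`
#' accumulates the unrecoverable component, which resting never restores.
#'
#' @param RF_prev,UF_prev Previous component value (>= 0).
#' @param exertion_E Exertion on this trial (normalized AUC x 10; 0 on
#'   rest trials).
#' @param t_rest Rest time on this trial in seconds (7.5 rest, 2.5 work).
#' @param alpha,delta,theta Non-negative sensitivity parameters.
#' @return Updated component value.
#' @examples
#' update_recoverable(1, exertion_E = 3, t_rest = 2.5, alpha = 0.1, delta = 0.2)
#' update_unrecoverable(0, exertion_E = 3, theta = 0.05)
#' @export
update_recoverable <- function(RF_prev, exertion_E, t_rest, alpha, delta) {
  pmax(0, RF_prev + alpha * exertion_E - delta * t_rest)
}

#' @rdname update_recoverable
#' @export
update_unrecoverable <- function(UF_prev, exertion_E, theta) {
  UF_prev + theta * exertion_E
}

#' Perceived effort readout
#'
#' Maps the current fatigue level and exertion to a predicted effort rating.
#' Rest trials are predicted as 0. On work trials the multiplicative
#' combination scales exertion by the fatigue-inflated weight,
#' \eqn{(\gamma + F) E}; the additive combination adds fatigue to the
#' weighted exertion, \eqn{\gamma E + F}.
#'
#' @param gamma Static effort weight (>= 0).
#' @param F_t Current total fatigue.
#' @param exertion_E Exertion on this trial.
#' @param trial_type `"work"` or `"rest"` (vectorized).
#' @param combination `"multiplicative"` or `"additive"`.
#' @return Predicted effort rating(s).
#' @export
predict_effort <- function(gamma, F_t, exertion_E, trial_type,
                           combination = c("multiplicative", "additive")) {
  combination <- match.arg(combination)
  trial_type <- match_trial_type(trial_type)
  pe <- if (combination == "multiplicative") {
    (gamma + F_t) * exertion_E
  } else {
    gamma * exertion_E + F_t
  }
  ifelse(trial_type == "rest", 0, pe)
}

#' Resolve the baseline fatigue level
#'
#' Fatigue experiments collect a baseline rating immediately before the
#' first trial; it anchors the model's fatigue level. A baseline of zero,
#' or a missing baseline (the effort-rating experiment collects none), is
#' replaced by 0.01 so the baseline is strictly positive.
#'
#' @param baseline_rating Integer rating on the experiment's scale, or
#'   `NULL`/`NA` when none was collected.
#' @return Strictly positive numeric baseline.
#' @examples
#' resolve_baseline(37) # 37
#' resolve_baseline(0)  # 0.01
#' resolve_baseline(NULL) # 0.01
#' @export
resolve_baseline <- function(baseline_rating = NULL) {
  if (is.null(baseline_rating) || length(baseline_rating) == 0L ||
      is.na(baseline_rating)) {
    return(0.01)
  }
  stopifnot_scalar_number(baseline_rating, "baseline_rating", lower = 0)
  if (baseline_rating == 0) 0.01 else as.numeric(baseline_rating)
}

# Fast vectorized trajectory core. The floored RF recursion
#   RF_t = max(0, RF_{t-1} + inc_t)
# is a Lindley recursion, so with S = cumsum(inc),
#   RF_t = S_t - min(0, min_{k<=t} S_k),
# which lets the whole trajectory be computed without an R-level loop.
# Returns list(RF, UF, F, predicted).
.trajectory_core <- function(alpha, delta, theta, gamma, E, t_rest, is_work,
                             F_start, readout, combination, state_timing) {
  inc <- alpha * E - delta * t_rest
  S <- cumsum(inc)
  RF <- S - pmin(0, cummin(S))
  UF <- cumsum(theta * E)
  F_tot <- F_start + RF + UF
  F_use <- if (state_timing == "post") {
    F_tot
  } else {
    c(F_start, F_tot[-length(F_tot)])
  }
  predicted <- if (readout == "fatigue") {
    F_use
  } else if (combination == "multiplicative") {
    ifelse(is_work, (gamma + F_use) * E, 0)
  } else {
    ifelse(is_work, gamma * E + F_use, 0)
  }
  list(RF = RF, UF = UF, F = F_tot, predicted = predicted)
}

#' Latent fatigue trajectory and predicted ratings
#'
#' Runs the trial-by-trial latent-state updates for one participant and one
#' candidate model, starting from RF = UF = 0, and returns the latent
#' states together with the model's predicted rating on every trial.
#'
#' @param params Named numeric vector with entries among `alpha`, `delta`,
#'   `theta`, `gamma`; parameters that are not free under `model` are
#'   ignored (held at 0), and the one-parameter recoverable models tie
#'   `delta` to `alpha`. All values must be non-negative.
#' @param data Data frame with columns `trial_type` (`"work"`/`"rest"`) and
#'   `exertion_E`; an optional `t_rest` column overrides [rest_time()].
#' @param F_start Baseline fatigue (> 0); see [resolve_baseline()].
#' @param model Model id; see [fatigue-models].
#' @param readout `"fatigue"` (predict the fatigue rating, i.e. F itself)
#'   or `"effort"` (predict perceived effort via [predict_effort()]).
#' @param combination Combination rule for the effort readout.
#' @param state_timing `"post"` (default) predicts trial t's rating from the
#'   state after trial t's update — ratings are given after exertion —
#'   `"pre"` uses the state carried into the trial.
#' @return Data frame with columns `trial`, `RF`, `UF`, `F`, `predicted`.
#' @examples
#' d <- data.frame(trial_type = c("work", "work", "rest"),
#'                 exertion_E = c(3, 6, 0))
#' fatigue_trajectory(c(alpha = 0.1, delta = 0.2, theta = 0.05), d,
#'                    F_start = 10, model = "full", readout = "fatigue")
#' @export
fatigue_trajectory <- function(params, data, F_start,
                               model = "full",
                               readout = c("fatigue", "effort"),
                               combination = c("multiplicative", "additive"),
                               state_timing = c("post", "pre")) {
  readout <- match.arg(readout)
  combination <- match.arg(combination)
  state_timing <- match.arg(state_timing)
  model <- match_model(model, readout)
  if (any(params < 0)) {
    stop("all parameters must be non-negative", call. = FALSE)
  }
  stopifnot_scalar_number(F_start, "F_start")
  if (F_start <= 0) {
    stop("`F_start` must be > 0; use resolve_baseline()", call. = FALSE)
  }
  if (!all(c("trial_type", "exertion_E") %in% names(data))) {
    stop("`data` needs columns trial_type and exertion_E", call. = FALSE)
  }
  trial_type <- match_trial_type(data$trial_type)
  E <- data$exertion_E
  if (any(!is.finite(E)) || any(E < 0)) {
    stop("`exertion_E` must be finite and non-negative", call. = FALSE)
  }
  t_rest <- if ("t_rest" %in% names(data)) data$t_rest else rest_time(trial_type)
  p <- resolve_params(model, params, readout)
  core <- .trajectory_core(p[["alpha"]], p[["delta"]], p[["theta"]],
                           p[["gamma"]], E, t_rest, trial_type == "work",
                           F_start, readout, combination, state_timing)
  data.frame(
    trial = if ("trial" %in% names(data)) data$trial else seq_along(E),
    RF = core$RF, UF = core$UF, F = core$F, predicted = core$predicted
  )
}
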
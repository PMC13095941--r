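#' Area under a force trace
#'
#' Integrates a grip-force trace over time by the trapezoidal rule, the
#' standard quantification of how much force was actually produced on a
#' trial. Forces are expressed as fractions of the participant's maximum
#' voluntary contraction (MVC), so the AUC has units of MVC-seconds.
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param force Numeric vector of non-negative force values
#'   (fraction of MVC), same length as `time`.
#' @return The trapezoidal integral, a non-negative scalar.
#' @examples
#' t <- seq(0, 5, by = 0.01)
#' force_auc(t, rep(0.4, length(t))) # 2.0
#' @export
force_auc <- function(time, force) {
  if (length(time) != length(force)) {
    stop("`time` and `force` must have the same length", call. = FALSE)
  }
  if (length(time) < 2L) {
    stop("a force trace needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(!is.finite(force))) {
    stop("force trace contains non-finite values", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (any(force < 0)) {
    stop("`force` must be non-negative", call. = FALSE)
  }
  pracma::trapz(time, force)
}

#' Normalize per-trial AUC values within a participant
#'
#' Divides each trial's force AUC by the maximum AUC that participant
#' produced across all their trials (including failed ones), mapping the
#' largest exertion to exactly 1. Multiplied by 10, the normalized AUC is
#' the exertion input E consumed by the fatigue models.
#'
#' @param auc Numeric vector of non-negative AUC values for one participant.
#' @return Numeric vector in \[0, 1\] with maximum exactly 1.
#' @examples
#' normalize_auc(c(2, 1, 4)) # 0.50 0.25 1.00
#' @export
normalize_auc <- function(auc) {
  if (length(auc) == 0L || any(!is.finite(auc)) || any(auc < 0)) {
    stop("`auc` must be a non-empty vector of finite, non-negative values",
         call. = FALSE)
  }
  m <- max(auc)
  if (m <= 0) {
    stop("all AUC values are zero: cannot normalize a participant who ",
         "never produced force", call. = FALSE)
  }
  auc / m
}

#' Judge whether a trial's force met the success criterion
#'
#' A work trial succeeds when the force meets or exceeds the required level
#' for a sum total of at least 3 s within the 5-s exertion window. Time at
#' or above threshold is accumulated over sample intervals whose two
#' endpoints are both at or above the threshold. Rest trials
#' (`required_fraction == 0`) always succeed.
#'
#' @param time,force Force trace as in [force_auc()].
#' @param required_fraction Required force level as a fraction of MVC
#'   (0 for rest trials).
#' @param min_hold Required cumulative time at or above threshold in
#'   seconds; default 3.
#' @return Logical scalar.
#' @export
judge_success <- function(time, force, required_fraction, min_hold = 3) {
  stopifnot_scalar_number(required_fraction, "required_fraction", lower = 0)
  if (required_fraction == 0) {
    return(TRUE)
  }
  if (length(time) != length(force) || length(time) < 2L) {
    stop("need a trace of at least 2 samples", call. = FALSE)
  }
  above <- force >= required_fraction
  n <- length(time)
  held <- sum(diff(time)[above[-n] & above[-1L]])
  held >= min_hold
}

#' Build per-trial observations from a task sequence and force AUCs
#'
#' Combines a planned [trial_sequence()] with per-trial raw AUCs and
#' success flags into the long-format observation table the fitting
#' functions consume: normalized AUC, exertion `E = auc_norm * 10`, and the
#' per-trial rest time.
#'
#' @param sequence A `task_sequence` data frame.
#' @param auc_raw Numeric vector of raw per-trial AUCs (MVC-seconds), one
#'   per trial; rest trials should be 0.
#' @param success Logical vector of per-trial success flags; rest trials
#'   are always successful.
#' @param rating Optional numeric vector of per-trial ratings.
#' @return Data frame with columns `trial`, `trial_type`, `effort_level`,
#'   `reward`, `success`, `auc_norm`, `exertion_E`, `t_rest` and (if given)
#'   `rating`.
#' @export
build_observations <- function(sequence, auc_raw, success = NULL,
                               rating = NULL) {
  n <- nrow(sequence)
  if (length(auc_raw) != n) {
    stop("`auc_raw` must have one value per trial", call. = FALSE)
  }
  auc_norm <- normalize_auc(auc_raw)
  auc_norm[sequence$trial_type == "rest"] <- 0
  if (is.null(success)) {
    success <- rep(TRUE, n)
  }
  success[sequence$trial_type == "rest"] <- TRUE
  out <- data.frame(
    trial = sequence$trial,
    trial_type = sequence$trial_type,
    effort_level = sequence$effort_level,
    reward = sequence$reward,
    success = as.logical(success),
    auc_norm = auc_norm,
    exertion_E = auc_norm * 10,
    t_rest = rest_time(sequence$trial_type),
    stringsAsFactors = FALSE
  )
  if (!is.null(rating)) {
    if (length(rating) != n) {
      stop("`rating` must have one value per trial", call. = FALSE)
    }
    out$rating <- rating
  }
  out
}
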
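#' Effort and reward levels of the grip-force task
#'
#' The task crosses four effort levels (rest plus three work levels set as
#' fractions of each participant's maximum voluntary contraction, MVC) with
#' three reward levels (credits). Effort levels are cued as filled pie-chart
#' segments: one segment signals rest, two to four segments signal 30%, 39%
#' and 48% of MVC.
#'
#' @format `effort_levels` is a data frame with one row per effort level and
#'   columns `effort_level` (integer cue code: 0 for rest, 2-4 for work) and
#'   `effort_fraction` (fraction of MVC: 0, 0.30, 0.39, 0.48).
#'   `reward_levels` is the integer vector of credit amounts (6, 8, 10).
#' @name task-levels
NULL

#' @rdname task-levels
#' @export
effort_levels <- data.frame(
  effort_level = c(0L, 2L, 3L, 4L),
  effort_fraction = c(0, 0.30, 0.39, 0.48)
)

#' @rdname task-levels
#' @export
reward_levels <- c(6L, 8L, 10L)

#' Rest time associated with a trial type
#'
#' The recoverable-fatigue dynamics treat every trial as providing some rest:
#' 7.5 s on rest trials and 2.5 s on work trials (the portion of the trial
#' not spent squeezing).
#'
#' @param trial_type Character vector with elements `"work"` or `"rest"`.
#' @return Numeric vector of rest durations in seconds.
#' @examples
#' rest_time(c("work", "rest"))
#' @export
rest_time <- function(trial_type) {
  trial_type <- match_trial_type(trial_type)
  ifelse(trial_type == "rest", 7.5, 2.5)
}

match_trial_type <- function(trial_type) {
  trial_type <- as.character(trial_type)
  bad <- !trial_type %in% c("work", "rest")
  if (any(bad)) {
    stop("`trial_type` must be 'work' or 'rest'; got: ",
         paste(unique(trial_type[bad]), collapse = ", "), call. = FALSE)
  }
  trial_type
}

#' Generate a counterbalanced pseudo-random trial sequence
#'
#' Builds the planned trial list for one run of the grip-force task. The 12
#' effort-by-reward combinations (4 effort levels including rest, 3 reward
#' levels) are counterbalanced by blocked randomization: within each
#' consecutive block of 12 trials every combination occurs exactly once, so
#' repetitions are distributed evenly across the task. The generated sequence
#' is a pure function of `(n_trials, seed, experiment)`; in the original
#' design all participants share one sequence, which is achieved by reusing
#' one seed.
#'
#' @param n_trials Number of trials; must be a positive multiple of 12.
#'   Default 120.
#' @param seed Integer seed controlling the pseudo-random order.
#' @param experiment One of `"exp1"`, `"exp2"`, `"exp3"`. Experiments 1 and 2
#'   show the reward before exertion; Experiment 3 reveals it only
#'   afterwards, which sets `reward_shown_before = FALSE` so that simulated
#'   force cannot be modulated by the reward on offer.
#' @return A data frame of class `task_sequence` with columns `trial`
#'   (1-based), `trial_type`, `effort_level`, `effort_fraction`, `reward`,
#'   `reward_shown_before`, and attributes `seed` and `experiment`.
#' @examples
#' seq1 <- trial_sequence(120, seed = 1)
#' table(seq1$effort_level, seq1$reward)
#' @export
trial_sequence <- function(n_trials = 120L, seed = 1L,
                           experiment = c("exp1", "exp2", "exp3")) {
  experiment <- match.arg(experiment)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || is.na(n_trials) ||
      n_trials <= 0 || n_trials != round(n_trials)) {
    stop("`n_trials` must be a positive integer", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  if (n_trials %% 12L != 0L) {
    stop("`n_trials` must be divisible by 12 (the number of effort x reward ",
         "combinations); got ", n_trials, call. = FALSE)
  }
  combos <- expand.grid(
    effort_level = effort_levels$effort_level,
    reward = reward_levels,
    KEEP.OUT.ATTRS = FALSE
  )
  n_blocks <- n_trials %/% 12L
  idx <- with_local_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(b) sample.int(12L)))
  })
  out <- combos[idx, , drop = FALSE]
  rownames(out) <- NULL
  out$effort_fraction <- effort_levels$effort_fraction[
    match(out$effort_level, effort_levels$effort_level)]
  out <- data.frame(
    trial = seq_len(n_trials),
    trial_type = ifelse(out$effort_level == 0L, "rest", "work"),
    effort_level = out$effort_level,
    effort_fraction = out$effort_fraction,
    reward = out$reward,
    reward_shown_before = experiment != "exp3",
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- as.integer(seed)
  attr(out, "experiment") <- experiment
  class(out) <- c("task_sequence", "data.frame")
  out
}

#' Read or write a task sequence as CSV
#'
#' @param x A `task_sequence` data frame.
#' @param file Path to a CSV file.
#' @return `read_task_sequence()` returns a `task_sequence` data frame;
#'   `write_task_sequence()` returns `file` invisibly.
#' @export
write_task_sequence <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_task_sequence
#' @export
read_task_sequence <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  needed <- c("trial", "trial_type", "effort_level", "effort_fraction",
              "reward", "reward_shown_before")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    stop("task sequence CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  class(out) <- c("task_sequence", "data.frame")
  out
}
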
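#' Quantize and censor a rating to the scale
#'
#' Ratings are entered in integer steps on a bounded visual analogue scale,
#' so simulated ratings are rounded to the nearest integer and censored to
#' `[0, scale_max]`. Both steps can be disabled for exact-recovery studies.
#'
#' @param x Numeric vector of latent rating values.
#' @param scale_max Scale maximum (20 for effort, 100 for fatigue).
#' @param quantize Round to integers (default `TRUE`).
#' @param censor Clamp to `[0, scale_max]` (default `TRUE`).
#' @export
quantize_rating <- function(x, scale_max, quantize = TRUE, censor = TRUE) {
  if (quantize) x <- round(x)
  if (censor) x <- pmin(pmax(x, 0), scale_max)
  x
}

#' Configuration for a synthetic grip-force experiment
#'
#' Bundles every knob of the synthetic cohort generator with defaults that
#' emulate the original task: 120 trials, effort levels 0/30/39/48% MVC,
#' rewards 6/8/10 credits, one shared counterbalanced sequence, bounded
#' integer rating scales, rating noise at 5% of the scale, and a small
#' trial-failure rate.
#'
#' @param n_participants Number of simulated participants.
#' @param model Generating model id (see [fatigue-models]).
#' @param readout `"fatigue"` (0-100 scale) or `"effort"` (0-20 scale).
#' @param combination Combination rule for the effort readout.
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`; `"exp3"` hides the
#'   reward before exertion, so reward cannot modulate simulated force.
#' @param n_trials Trials per participant (multiple of 12; default 120).
#' @param shared_sequence All participants receive the same trial order
#'   (default `TRUE`, as in the original design).
#' @param sequence_seed Seed of the shared canonical sequence (default 84).
#'   Like the counterbalancing of the original task, the default sequence
#'   is a fixed design choice, not part of the simulation randomness: it
#'   was certified at design time: for every recovery-to-exertion ratio
#'   in the default `delta_ratio` band, the (scale-free) recoverable
#'   fatigue process drains to its zero floor at least five times across
#'   the task, including late trials. Those floor visits are what make
#'   the recoverable and unrecoverable components separable in the data.
#'   Set to `NULL` to derive the sequence from the master seed instead.
#' @param param_range Named list of `c(lo, hi)` ranges from which each
#'   participant's ground-truth parameters are drawn uniformly. Defaults
#'   for the fatigue readout: alpha on `[0.3, 0.9]` (rest-trial dips of
#'   roughly 4-11 rating points), theta on `[0.01, 0.1]` (an unrecoverable
#'   rise of ~6-75 points over a 120-trial task), gamma on `[0.5, 2]`.
#'   For the effort readout the latent-fatigue ranges are ~50x smaller
#'   (alpha `[0.006, 0.018]`, theta `[2e-4, 2e-3]`, gamma `[0.5, 1.4]`)
#'   because fatigue enters the effort readout multiplied by exertion.
#'   By default delta is not drawn independently but as
#'   `delta = alpha * U(delta_ratio)`, keeping recovery during rest
#'   slightly ahead of work-run exertion gains so that the recoverable
#'   component is mean-reverting and regularly visits its zero floor — the
#'   regime the model intends, in which RF carries the fluctuation and UF
#'   the trend. (When exertion gains persistently outpace recovery, RF
#'   turns into a second linear trend and alpha/theta become structurally
#'   confounded along F = F_start + (alpha+theta) * cumulative exertion -
#'   delta * cumulative rest.) Supply an explicit `delta` range to draw it
#'   independently instead.
#' @param delta_ratio Range of the delta/alpha ratio used when no explicit
#'   `delta` range is given (default `c(1.55, 1.95)`). With mean work
#'   exertion around 7.5 units the drift balance point is near 1.53: above
#'   it, rests collectively outpace work-run gains, so RF mean-reverts and
#'   revisits its zero floor (separating it from the unrecoverable trend)
#'   while longer work runs still leave rests only partially depleting RF
#'   (pinning down the rest-rate delta separately from alpha).
#' @param baseline_range Integer range for the pre-task baseline fatigue
#'   rating (fatigue readout only; default 0-20: participants start the
#'   task fairly rested).
#' @param noise_sd Rating noise standard deviation in rating units;
#'   `NULL` (default) means 5% of the scale (5 for fatigue, 1 for effort).
#' @param scale_max Rating-scale maximum; `NULL` derives it from the
#'   readout (100 fatigue, 20 effort).
#' @param quantize,censor Apply integer rounding / bound censoring to the
#'   simulated ratings (defaults `TRUE`).
#' @param state_timing Passed to [fatigue_trajectory()].
#' @param sampling_interval Force-trace sampling interval in seconds
#'   (default 0.05).
#' @param ramp_time,hold_duration Force-template timing: linear ramps of
#'   `ramp_time` seconds up and down around a hold of `hold_duration`
#'   seconds (defaults 0.5 and 4).
#' @param overshoot Multiplicative margin by which simulated participants
#'   aim above the target line (default 1.05).
#' @param force_noise_sd Per-sample Gaussian force wobble during the hold,
#'   in MVC fractions (default 0.01).
#' @param reward_vigour_gain Extra hold force (MVC fraction) per credit
#'   above the 6-credit minimum when the reward is visible before exertion
#'   (default 0.005), reproducing reward-invigorated squeezing.
#' @param success_shortfall_prob Probability that a work trial's hold is cut
#'   short below the 3-s success criterion (default 0.03, matching the
#'   few-percent failure rates typical of the task).
#' @param seed Master seed; sequence, force and rating noise use separate
#'   streams derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 20,
                       model = "full",
                       readout = c("fatigue", "effort"),
                       combination = c("multiplicative", "additive"),
                       experiment = c("exp2", "exp1", "exp3"),
                       n_trials = 120,
                       shared_sequence = TRUE,
                       sequence_seed = 84L,
                       param_range = list(),
                       delta_ratio = c(1.55, 1.95),
                       baseline_range = c(0L, 20L),
                       noise_sd = NULL,
                       scale_max = NULL,
                       quantize = TRUE,
                       censor = TRUE,
                       state_timing = c("post", "pre"),
                       sampling_interval = 0.05,
                       ramp_time = 0.5,
                       hold_duration = 4,
                       overshoot = 1.05,
                       force_noise_sd = 0.01,
                       reward_vigour_gain = 0.005,
                       success_shortfall_prob = 0.03,
                       seed = 1) {
  readout <- match.arg(readout)
  combination <- match.arg(combination)
  experiment <- match.arg(experiment)
  state_timing <- match.arg(state_timing)
  model <- match_model(model, readout)
  scale_max <- scale_max %||% if (readout == "fatigue") 100L else 20L
  noise_sd <- noise_sd %||% (0.05 * scale_max)
  base_ranges <- if (readout == "fatigue") {
    list(alpha = c(0.3, 0.9), theta = c(0.01, 0.1), gamma = c(0.5, 2))
  } else {
    # effort readout: fatigue enters multiplied by exertion, so the same
    # rating-scale-relative dynamics need ~50x smaller latent parameters
    list(alpha = c(0.006, 0.018), theta = c(2e-4, 2e-3),
         gamma = c(0.5, 1.4))
  }
  ranges <- utils::modifyList(base_ranges, param_range)
  structure(list(
    n_participants = n_participants, model = model, readout = readout,
    combination = combination, experiment = experiment, n_trials = n_trials,
    shared_sequence = shared_sequence, sequence_seed = sequence_seed,
    param_range = ranges,
    delta_ratio = delta_ratio,
    baseline_range = baseline_range, noise_sd = noise_sd,
    scale_max = scale_max, quantize = quantize, censor = censor,
    state_timing = state_timing, sampling_interval = sampling_interval,
    ramp_time = ramp_time, hold_duration = hold_duration,
    overshoot = overshoot, force_noise_sd = force_noise_sd,
    reward_vigour_gain = reward_vigour_gain,
    success_shortfall_prob = success_shortfall_prob, seed = seed
  ), class = "sim_config")
}

#' Simulate one trial's force trace
#'
#' Generates a 5-s grip-force trace (fraction of MVC) for one planned
#' trial: zeros on rest trials; on work trials a ramp-hold-release template
#' aimed slightly above the target level, plus reward-invigorated extra
#' force when the reward is visible before exertion, plus Gaussian wobble.
#' With probability `success_shortfall_prob` (or when `shortfall = TRUE`)
#' the hold is cut short below the 3-s success criterion.
#'
#' Randomness is taken from the current RNG state; callers seed it (see
#' [simulate_cohort()]).
#'
#' @param spec One-row data frame from a [trial_sequence()] (columns
#'   `trial_type`, `effort_fraction`, `reward`, `reward_shown_before`).
#' @param config A [sim_config()].
#' @param shortfall Force a short hold (`NULL` = draw at random).
#' @return Data frame with columns `time_s` and `force_frac`.
#' @export
simulate_force_trace <- function(spec, config, shortfall = NULL) {
  dt <- config$sampling_interval
  time <- seq(0, 5, by = dt)
  if (spec$trial_type == "rest" || spec$effort_fraction == 0) {
    return(data.frame(time_s = time, force_frac = numeric(length(time))))
  }
  vig <- if (isTRUE(spec$reward_shown_before)) {
    config$reward_vigour_gain * (spec$reward - min(reward_levels))
  } else 0
  level <- spec$effort_fraction * config$overshoot + vig
  if (is.null(shortfall)) {
    shortfall <- stats::runif(1) < config$success_shortfall_prob
  }
  hold <- if (shortfall) stats::runif(1, 1.5, 2.7) else config$hold_duration
  t_up <- config$ramp_time
  t_rel <- min(5, t_up + hold)
  t_down <- min(5, t_rel + config$ramp_time)
  force <- ifelse(time < t_up, level * time / t_up,
           ifelse(time <= t_rel, level,
           ifelse(time < t_down, level * (t_down - time) / config$ramp_time,
                  0)))
  if (config$force_noise_sd > 0) {
    force <- force + ifelse(force > 0,
                            stats::rnorm(length(time), 0,
                                         config$force_noise_sd), 0)
  }
  data.frame(time_s = time, force_frac = pmax(0, force))
}

#' Simulate ratings from ground-truth parameters
#'
#' Computes the generating model's predicted trajectory on a set of
#' executed trials and adds Gaussian rating noise, then quantizes/censors
#' to the scale. With `noise_sd = 0` and quantization off, the ratings are
#' exactly the model predictions.
#'
#' Randomness is taken from the current RNG state; callers seed it.
#'
#' @param params Named ground-truth parameter vector.
#' @param observations Trial table with `trial_type` and `exertion_E`.
#' @param F_start Baseline fatigue (see [resolve_baseline()]).
#' @param config A [sim_config()] (model, readout, noise and scale
#'   settings).
#' @return `observations` with a `rating` column added.
#' @export
simulate_ratings <- function(params, observations, F_start, config) {
  traj <- fatigue_trajectory(params, observations, F_start,
                             model = config$model, readout = config$readout,
                             combination = config$combination,
                             state_timing = config$state_timing)
  lat <- traj$predicted
  if (config$noise_sd > 0) {
    lat <- lat + stats::rnorm(length(lat), 0, config$noise_sd)
  }
  observations$rating <- quantize_rating(lat, config$scale_max,
                                         quantize = config$quantize,
                                         censor = config$censor)
  observations
}

#' Simulate a cohort of synthetic participants
#'
#' Generates a complete synthetic experiment: a counterbalanced task
#' sequence (shared across participants by default), per-trial force traces
#' and success flags, per-participant normalized exertion, ground-truth
#' model parameters drawn from `config$param_range`, and noisy bounded
#' ratings. Fully reproducible from `config$seed`; sequence, force and
#' rating noise use separate derived streams so each can be varied
#' independently.
#'
#' @param config A [sim_config()].
#' @return An object of class `fatigue_cohort`: list with
#'   * `data` — long trial table (`participant`, `trial`, `trial_type`,
#'     `effort_level`, `reward`, `success`, `auc_norm`, `exertion_E`,
#'     `t_rest`, `rating`),
#'   * `participants` — per-participant table (`participant`, `baseline`,
#'     `mvc`),
#'   * `truth` — per-participant ground-truth parameters and noise level,
#'   * `sequence` — the shared [trial_sequence()] (or `NULL` when
#'     per-participant sequences are used),
#'   * `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 2, seed = 7))
#' head(cohort$data)
#' cohort$truth
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 4L)
  free <- free_params(config$model, config$readout)
  n <- config$n_participants

  truth <- with_local_seed(seeds[1], {
    out <- data.frame(participant = seq_len(n))
    for (p in setdiff(free, "delta")) {
      rg <- config$param_range[[p]]
      out[[p]] <- stats::runif(n, rg[1], rg[2])
    }
    if ("delta" %in% free) {
      rg <- config$param_range[["delta"]]
      out$delta <- if (!is.null(rg)) {
        stats::runif(n, rg[1], rg[2])
      } else {
        # recovery in balance with exertion: see ?sim_config
        out$alpha * stats::runif(n, config$delta_ratio[1],
                                 config$delta_ratio[2])
      }
    }
    out$noise_sd <- config$noise_sd
    out
  })
  participants <- with_local_seed(seeds[2], {
    data.frame(
      participant = seq_len(n),
      baseline = if (config$readout == "fatigue") {
        sample(seq(config$baseline_range[1], config$baseline_range[2]), n,
               replace = TRUE)
      } else NA_integer_,
      mvc = round(stats::runif(n, 200, 600), 1)
    )
  })

  shared_seq <- if (config$shared_sequence) {
    trial_sequence(config$n_trials,
                   seed = config$sequence_seed %||% seeds[3],
                   experiment = config$experiment)
  } else NULL

  data_list <- with_local_seed(seeds[4], {
    lapply(seq_len(n), function(i) {
      seq_i <- shared_seq %||%
        trial_sequence(config$n_trials,
                       seed = (as.numeric(seeds[3]) + i) %%
                         .Machine$integer.max,
                       experiment = config$experiment)
      traces <- lapply(seq_len(nrow(seq_i)), function(t) {
        simulate_force_trace(seq_i[t, ], config)
      })
      auc_raw <- vapply(traces, function(tr) {
        if (all(tr$force_frac == 0)) 0 else force_auc(tr$time_s, tr$force_frac)
      }, numeric(1))
      success <- vapply(seq_len(nrow(seq_i)), function(t) {
        judge_success(traces[[t]]$time_s, traces[[t]]$force_frac,
                      seq_i$effort_fraction[t])
      }, logical(1))
      obs <- build_observations(seq_i, auc_raw, success)
      F_start <- resolve_baseline(participants$baseline[i])
      pars <- unlist(truth[i, free, drop = FALSE])
      obs <- simulate_ratings(pars, obs, F_start, config)
      cbind(participant = i, obs)
    })
  })

  structure(list(
    data = do.call(rbind, data_list),
    participants = participants,
    truth = truth,
    sequence = shared_seq,
    config = config
  ), class = "fatigue_cohort")
}

#' @export
print.fatigue_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic fatigue cohort: ", cfg$n_participants, " participants x ",
      cfg$n_trials, " trials\n", sep = "")
  cat("  generating model: ", cfg$model, " (", cfg$readout, " readout), ",
      "noise sd ", cfg$noise_sd, ", scale 0-", cfg$scale_max, "\n", sep = "")
  cat("  seed: ", cfg$seed, "\n", sep = "")
  invisible(x)
}
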
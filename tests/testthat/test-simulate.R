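test_that("rest trials produce silent traces that trivially succeed", {
  cfg <- sim_config()
  spec <- data.frame(trial_type = "rest", effort_fraction = 0, reward = 8,
                     reward_shown_before = TRUE)
  tr <- simulate_force_trace(spec, cfg)
  expect_true(all(tr$force_frac == 0))
  expect_true(judge_success(tr$time_s, tr$force_frac, 0))
  expect_equal(force_auc(tr$time_s, tr$force_frac), 0)
})

test_that("noise-free work traces match the template's closed-form area", {
  cfg <- sim_config(force_noise_sd = 0, success_shortfall_prob = 0,
                    reward_vigour_gain = 0)
  for (frac in c(0.30, 0.39, 0.48)) {
    spec <- data.frame(trial_type = "work", effort_fraction = frac,
                       reward = 6, reward_shown_before = TRUE)
    tr <- simulate_force_trace(spec, cfg)
    expect_true(judge_success(tr$time_s, tr$force_frac, frac))
    # trapezoidal template: hold level x (hold + one ramp's worth)
    area <- frac * cfg$overshoot * (cfg$hold_duration + cfg$ramp_time)
    expect_equal(force_auc(tr$time_s, tr$force_frac), area,
                 tolerance = 0.02 * area)
  }
})

test_that("forced shortfalls fail the 3-s criterion", {
  cfg <- sim_config(force_noise_sd = 0)
  spec <- data.frame(trial_type = "work", effort_fraction = 0.39,
                     reward = 8, reward_shown_before = TRUE)
  set.seed(1)
  tr <- simulate_force_trace(spec, cfg, shortfall = TRUE)
  expect_false(judge_success(tr$time_s, tr$force_frac, 0.39))
})

test_that("visible rewards invigorate force; hidden rewards cannot", {
  cfg <- sim_config(success_shortfall_prob = 0)
  mean_auc <- function(reward, visible) {
    spec <- data.frame(trial_type = "work", effort_fraction = 0.39,
                       reward = reward, reward_shown_before = visible)
    mean(replicate(100, {
      tr <- simulate_force_trace(spec, cfg)
      force_auc(tr$time_s, tr$force_frac)
    }))
  }
  set.seed(21)
  expect_gt(mean_auc(10, TRUE), mean_auc(6, TRUE))
  # reward hidden before exertion: no vigour effect beyond noise
  set.seed(22)
  expect_equal(mean_auc(10, FALSE), mean_auc(6, FALSE), tolerance = 0.01)
})

test_that("simulated ratings quantize, censor, and honour the null case", {
  obs <- make_trials(rep(c("work", "rest"), 6))
  cfg0 <- sim_config(model = "full", noise_sd = 0)
  z <- simulate_ratings(c(alpha = 0, delta = 0, theta = 0), obs, 17.2, cfg0)
  expect_true(all(z$rating == 17)) # round(F_start)
  # rounding of a non-integer prediction
  cfg_eff <- sim_config(readout = "effort", model = "null", noise_sd = 0)
  w <- make_trials("work", E = 8)
  z2 <- simulate_ratings(c(gamma = 1.3), w, 0.01, cfg_eff)
  expect_equal(z2$rating, round((1.3 + 0.01) * 8))
  # ceiling censoring at the top of the scale
  cfg_hot <- sim_config(noise_sd = 0, param_range = list(theta = c(0.5, 0.5)))
  long <- make_trials(rep("work", 30), E = rep(10, 30))
  z3 <- simulate_ratings(c(alpha = 0, delta = 0, theta = 0.5), long, 50,
                         cfg_hot)
  expect_equal(max(z3$rating), 100)
  expect_true(any(50 + cumsum(rep(5, 30)) > 100)) # latent exceeds the scale
})

test_that("cohort simulation is reproducible and bookkeeps truth", {
  cfg <- sim_config(n_participants = 3, n_trials = 24, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$data), 3 * 24)
  expect_equal(nrow(a$truth), 3)
  expect_true(all(c("alpha", "delta", "theta") %in% names(a$truth)))
  expect_true(all(a$data$rating >= 0 & a$data$rating <= 100))
  expect_true(all(a$data$rating == round(a$data$rating)))
  # shared sequence: identical trial structure across participants
  s1 <- a$data[a$data$participant == 1, c("trial_type", "effort_level")]
  s2 <- a$data[a$data$participant == 2, c("trial_type", "effort_level")]
  expect_equal(s1, s2, ignore_attr = TRUE)
  cfg_i <- sim_config(n_participants = 2, n_trials = 24, seed = 99,
                      shared_sequence = FALSE)
  ind <- simulate_cohort(cfg_i)
  expect_false(identical(
    ind$data[ind$data$participant == 1, "effort_level"],
    ind$data[ind$data$participant == 2, "effort_level"]))
  expect_output(print(a), "Synthetic fatigue cohort")
})

test_that("rating noise monotonically degrades parameter recovery", {
  cors <- sapply(c(0.5, 5, 15), function(nsd) {
    cfg <- sim_config(n_participants = 12, noise_sd = nsd, seed = 31)
    ch <- simulate_cohort(cfg)
    fits <- fit_cohort(ch, models = "full")
    stats::median(recovery_report(ch, fits)$parameters$correlation)
  })
  expect_true(all(diff(cors) < 0))
  expect_gt(cors[1], 0.9)
})

test_that("the recovery report joins truth with estimates completely", {
  cfg <- sim_config(n_participants = 4, n_trials = 24, noise_sd = 2,
                    seed = 13)
  ch <- simulate_cohort(cfg)
  fits <- fit_cohort(ch, models = c("uf", "full"))
  cmp <- compare_fatigue_models(fits, ep_samples = 1e4, seed = 1)
  rep <- recovery_report(ch, fits, cmp)
  expect_s3_class(rep, "recovery_report")
  expect_setequal(rep$parameters$parameter, c("alpha", "delta", "theta"))
  expect_equal(nrow(rep$estimates), 4)
  expect_false(any(is.na(rep$estimates$alpha_hat)))
  expect_true(rep$model_recovery >= 0 && rep$model_recovery <= 1)
  expect_equal(rep$exceedance_probability,
               unname(cmp$exceedance_probability["full"]))
  expect_output(print(rep), "Recovery report")
  # mismatched ids are rejected
  ch2 <- ch; ch2$truth <- ch2$truth[-1, ]
  expect_error(recovery_report(ch2, fits), "match")
})
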
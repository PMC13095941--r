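test_that("AIC formula matches hand arithmetic", {
  expect_equal(aic_rss(120, 120, 3), 6)             # ln(1) = 0 leaves 2d
  expect_equal(aic_rss(240, 120, 3), 120 * log(2) + 6, tolerance = 1e-12)
  # linear in the parameter count
  expect_equal(aic_rss(240, 120, 6) - aic_rss(240, 120, 3), 6)
  expect_warning(v <- aic_rss(0, 10, 2), "floor")
  expect_equal(v, 10 * log(1e-12 / 10) + 4)
  expect_error(aic_rss(0, 10, 2, rss_floor = NULL), "undefined")
})

test_that("R^2 is the squared observed-predicted correlation", {
  obs <- c(1, 4, 2, 8, 5, 7)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, 3 * obs + 2), 1) # affine invariance
  # construct a pair with sample correlation exactly 0.5
  v1 <- scale(1:10)[, 1]
  z <- scale(resid(lm(rnorm(10) ~ v1)))[, 1]
  y <- 0.5 * v1 + sqrt(0.75) * z
  expect_equal(r_squared(v1, y), 0.25, tolerance = 1e-10)
  expect_warning(r2 <- r_squared(rep(3, 5), 1:5), "zero variance")
  expect_true(is.na(r2))
  expect_error(r_squared(1:2, 1:2), ">= 3")
})

test_that("initialisation grids are full factorials with endpoints", {
  expect_equal(nrow(initialisation_grid(c("alpha", "delta", "theta",
                                          "gamma"))), 1296) # 6^4
  g1 <- initialisation_grid("alpha")
  expect_equal(g1$alpha, seq(0, 1, by = 0.2))
  g2 <- initialisation_grid(c("a", "b"), n_per_param = 2)
  expect_equal(nrow(g2), 4)
  expect_setequal(do.call(paste, g2), c("0 0", "1 0", "0 1", "1 1"))
  expect_error(initialisation_grid("a", n_per_param = 1), ">= 2")
})

test_that("the RSS objective penalises infeasible parameters", {
  d <- make_trials(rep(c("work", "rest"), 6))
  d$rating <- 10
  obj <- fatiguedyn:::make_rss_objective(
    c("alpha", "delta", "theta"), d$exertion_E, rest_time(d$trial_type),
    d$trial_type == "work", d$rating, rep(TRUE, 12), 5, "full", "fatigue",
    "multiplicative", "post")
  feasible <- obj(c(0.1, 0.1, 0.05))
  expect_lt(feasible, 1e6)
  expect_gt(obj(c(-0.01, 0.1, 0.05)), 1e11)
  expect_gt(obj(c(-1, -1, -1)), feasible)
})

test_that("perfect predictions give zero RSS and R^2 of 1", {
  d <- make_trials(rep(c("work", "work", "rest"), 10),
                   E = rep(c(5, 8, 0), 10))
  truth <- c(alpha = 0.3, delta = 0.5, theta = 0.05)
  d$rating <- fatigue_trajectory(truth, d, 12)$predicted
  fit <- suppressWarnings(
    fit_fatigue(d, model = "full", readout = "fatigue", baseline = 12))
  expect_lt(fit$rss, 1e-8)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_obs, 30)
  expect_equal(fit$n_params, 3)
})

test_that("simplex optimum matches the closed-form null-model gamma", {
  s <- trial_sequence(48, seed = 4)
  auc <- ifelse(s$trial_type == "rest", 0,
                s$effort_fraction * 4.5 * runif(48, 0.97, 1.03))
  obs <- build_observations(s, auc)
  cfg <- sim_config(readout = "effort", model = "null", noise_sd = 0,
                    quantize = FALSE, censor = FALSE)
  obs <- simulate_ratings(c(gamma = 2), obs, resolve_baseline(NULL), cfg)
  fit <- suppressWarnings(fit_fatigue(obs, model = "null", readout = "effort"))
  gamma_cf <- null_gamma_closed_form(obs)
  expect_equal(unname(coef(fit)["gamma"]), gamma_cf, tolerance = 1e-4)
  expect_equal(gamma_cf, 2, tolerance = 1e-10)
})

test_that("multi-start best never loses to any raw grid start", {
  set.seed(8)
  d <- make_trials(rep(c("work", "work", "work", "rest"), 9))
  truth <- c(alpha = 0.4, delta = 0.6, theta = 0.06)
  d$rating <- round(fatigue_trajectory(truth, d, 15)$predicted +
                      rnorm(36, 0, 4))
  fit <- fit_fatigue(d, model = "full", readout = "fatigue", baseline = 15)
  grid <- initialisation_grid(c("alpha", "delta", "theta"))
  start_rss <- apply(grid, 1, function(p) {
    pred <- fatigue_trajectory(setNames(unname(p),
                                        c("alpha", "delta", "theta")),
                               d, 15)$predicted
    sum((d$rating - pred)^2)
  })
  expect_lte(fit$rss, min(start_rss) + 1e-9)
  expect_equal(fit$n_starts, 216)
  expect_gt(fit$converged_fraction, 0.5)
})

test_that("degenerate data still yield a finite fit", {
  d <- make_trials(rep("work", 12), E = rep(6, 12))
  d$rating <- rep(10, 12) # zero-variance ratings
  fit <- suppressWarnings(fit_fatigue(d, model = "null", readout = "effort"))
  expect_true(is.finite(fit$rss))
  expect_true(is.finite(coef(fit)["gamma"]))
  expect_true(is.na(fit$r_squared)) # constant predictions: R^2 undefined
})

test_that("failed trials can be excluded from the residuals", {
  d <- make_trials(rep("work", 12), E = rep(6, 12))
  d$rating <- 10
  d$success <- rep(c(TRUE, FALSE), 6)
  fit_all <- suppressWarnings(fit_fatigue(d, "null", "effort"))
  fit_ok <- suppressWarnings(fit_fatigue(d, "null", "effort",
                                         include_failed = FALSE))
  expect_equal(fit_all$n_obs, 12)
  expect_equal(fit_ok$n_obs, 6)
})

test_that("fit objects expose the standard modelling methods", {
  d <- make_trials(rep(c("work", "rest"), 18))
  truth <- c(alpha = 0.4, delta = 0.5, theta = 0.08)
  set.seed(2)
  d$rating <- round(fatigue_trajectory(truth, d, 20)$predicted + rnorm(36, 0, 3))
  fit <- fit_fatigue(d, model = "full", readout = "fatigue", baseline = 20)
  expect_s3_class(fit, "fatigue_fit")
  expect_named(coef(fit), c("alpha", "delta", "theta"))
  expect_length(fitted(fit), 36)
  expect_equal(sum(residuals(fit)^2, na.rm = TRUE), fit$rss)
  expect_equal(predict(fit), fitted(fit))
  longer <- make_trials(rep(c("work", "rest"), 24))
  expect_length(predict(fit, newdata = longer), 48)
  traj <- predict(fit, type = "trajectory")
  expect_named(traj, c("trial", "RF", "UF", "F", "predicted"))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(36, 3))
  expect_true(all(sims >= 0 & sims <= 100))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1)) # seeded
  expect_output(print(fit), "RSS")
  expect_output(print(summary(fit)), "multi-start")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("malformed trial tables produce clear schema errors", {
  expect_error(fit_fatigue(data.frame(trial_type = "work"), "full"),
               "exertion_E")
  d <- make_trials(c("work", "rest"))
  expect_error(fit_fatigue(d, "full"), "rating")
  d$rating <- c(NA, NA)
  expect_error(fit_fatigue(d, "full"), "no rated trials")
})
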
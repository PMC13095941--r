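test_that("single-step updates follow the latent dynamics", {
  # work trial: exertion rise and rest decline combine before the floor
  expect_equal(update_recoverable(1.0, 3, 2.5, alpha = 0.1, delta = 0.2), 0.8)
  # floor at zero: recoverable fatigue cannot go negative
  expect_equal(update_recoverable(0.1, 0, 7.5, alpha = 0.1, delta = 0.2), 0)
  expect_equal(update_recoverable(2, 5, 7.5, alpha = 0, delta = 0), 2)
  expect_equal(update_unrecoverable(0, 3, theta = 0.05), 0.15)
  expect_equal(update_unrecoverable(1.3, 0, theta = 0.05), 1.3) # rest
  expect_equal(update_unrecoverable(1.3, 9, theta = 0), 1.3)
})

test_that("perceived effort is zero at rest and combines per rule", {
  expect_equal(predict_effort(1.5, 2.0, 3, "rest"), 0)
  expect_equal(predict_effort(1.5, 2.0, 3, "work", "multiplicative"), 10.5)
  expect_equal(predict_effort(1.5, 2.0, 3, "work", "additive"), 6.5)
  expect_equal(predict_effort(1.5, 2.0, c(3, 0), c("work", "rest")), c(10.5, 0))
})

test_that("baseline resolution substitutes 0.01 for zero or missing", {
  expect_equal(resolve_baseline(37), 37)
  expect_equal(resolve_baseline(0), 0.01)
  expect_equal(resolve_baseline(NULL), 0.01)
  expect_equal(resolve_baseline(NA), 0.01)
})

test_that("three-trial trajectory matches hand-computed states exactly", {
  # alpha=0.1, delta=0.2, theta=0.05, F_start=10
  # t1 work E=3: UF=0.15; RF=max(0, 0.3-0.5)=0;       F=10.15
  # t2 work E=6: UF=0.45; RF=max(0, 0+0.6-0.5)=0.1;   F=10.55
  # t3 rest E=0: UF=0.45; RF=max(0, 0.1-1.5)=0;       F=10.45
  d <- make_trials(c("work", "work", "rest"), E = c(3, 6, 0))
  tr <- fatigue_trajectory(c(alpha = 0.1, delta = 0.2, theta = 0.05), d,
                           F_start = 10, model = "full", readout = "fatigue")
  expect_equal(tr$RF, c(0, 0.1, 0), tolerance = 1e-12)
  expect_equal(tr$UF, c(0.15, 0.45, 0.45), tolerance = 1e-12)
  expect_equal(tr$F, c(10.15, 10.55, 10.45), tolerance = 1e-12)
  expect_equal(tr$predicted, tr$F)
})

test_that("vectorized trajectory agrees with the scalar update loop", {
  set.seed(11)
  for (i in 1:20) {
    n <- 40
    types <- sample(c("work", "rest"), n, replace = TRUE, prob = c(.75, .25))
    E <- ifelse(types == "work", runif(n, 3, 10), 0)
    t_rest <- rest_time(types)
    a <- runif(1, 0, 1); dl <- runif(1, 0, 1); th <- runif(1, 0, 0.3)
    tr <- fatigue_trajectory(c(alpha = a, delta = dl, theta = th),
                             make_trials(types, E), F_start = 5)
    ref <- loop_trajectory(a, dl, th, E, t_rest, 5)
    expect_equal(tr$RF, ref$RF, tolerance = 1e-12)
    expect_equal(tr$UF, ref$UF, tolerance = 1e-12)
    expect_equal(tr$F, ref$F, tolerance = 1e-12)
  }
})

test_that("degenerate parameter settings give the expected limits", {
  d <- make_trials(rep(c("work", "rest"), 10))
  # all-zero parameters, fatigue readout: rating pinned at baseline
  tr <- fatigue_trajectory(c(alpha = 0, delta = 0, theta = 0), d, 42,
                           model = "full", readout = "fatigue")
  expect_true(all(tr$predicted == 42))
  # null effort model: prediction (gamma + F_start) * E on work, 0 on rest
  tr2 <- fatigue_trajectory(c(gamma = 2), d, F_start = 0.01,
                            model = "null", readout = "effort")
  expect_equal(tr2$predicted,
               ifelse(d$trial_type == "work", (2 + 0.01) * d$exertion_E, 0))
})

test_that("rest-only sequences freeze UF and drain RF to zero", {
  d <- make_trials(rep("rest", 15))
  tr <- fatigue_trajectory(c(alpha = 0.5, delta = 0.1, theta = 0.2), d, 1)
  expect_true(all(tr$UF == 0))
  expect_true(all(diff(tr$RF) <= 0))
  expect_equal(tr$RF[15], 0)
})

test_that("model nesting: full degenerates to uf; rf1 ties delta to alpha", {
  set.seed(3)
  types <- sample(c("work", "rest"), 36, replace = TRUE)
  d <- make_trials(types, ifelse(types == "work", runif(36, 4, 10), 0))
  full0 <- fatigue_trajectory(c(alpha = 0, delta = 0, theta = 0.07), d, 8,
                              model = "full")
  uf <- fatigue_trajectory(c(theta = 0.07), d, 8, model = "uf")
  expect_equal(full0, uf)
  rf1 <- fatigue_trajectory(c(alpha = 0.3), d, 8, model = "rf1")
  rf_tied <- fatigue_trajectory(c(alpha = 0.3, delta = 0.3), d, 8,
                                model = "rf")
  expect_equal(rf1, rf_tied)
  # uf_rf1 likewise equals full with delta tied to alpha
  uf_rf1 <- fatigue_trajectory(c(alpha = 0.3, theta = 0.05), d, 8,
                               model = "uf_rf1")
  full_tied <- fatigue_trajectory(c(alpha = 0.3, delta = 0.3, theta = 0.05),
                                  d, 8, model = "full")
  expect_equal(uf_rf1, full_tied)
})

test_that("pre-update readout predicts from the carried-in state", {
  d <- make_trials(c("work", "work", "work"), E = c(5, 5, 5))
  post <- fatigue_trajectory(c(alpha = 0.2, delta = 0.1, theta = 0.1), d, 10,
                             state_timing = "post")
  pre <- fatigue_trajectory(c(alpha = 0.2, delta = 0.1, theta = 0.1), d, 10,
                            state_timing = "pre")
  expect_equal(pre$predicted, c(10, post$F[-3]))
  expect_equal(pre$F, post$F) # latent states identical; only readout shifts
})

test_that("invalid inputs are rejected", {
  d <- make_trials(c("work", "rest"))
  expect_error(fatigue_trajectory(c(alpha = -0.1), d, 5), "non-negative")
  expect_error(fatigue_trajectory(c(alpha = 0.1), d, 0), "F_start")
  expect_error(fatigue_trajectory(c(beta = 0.1), d, 5), "named")
  expect_error(fatigue_trajectory(c(theta = 0.1), d, 5, model = "null",
                                  readout = "fatigue"), "null")
  expect_error(free_params("banana"), "must be one of")
})

test_that("model family frees the documented parameter subsets", {
  expect_equal(free_params("full", "effort"),
               c("alpha", "delta", "theta", "gamma"))
  expect_equal(free_params("full", "fatigue"), c("alpha", "delta", "theta"))
  expect_equal(free_params("null", "effort"), "gamma")
  expect_equal(free_params("uf", "fatigue"), "theta")
  expect_equal(free_params("rf", "fatigue"), c("alpha", "delta"))
  expect_equal(free_params("rf1", "fatigue"), "alpha")
  expect_equal(free_params("uf_rf1", "fatigue"), c("theta", "alpha"))
  expect_setequal(model_ids("effort"),
                  c("null", "uf", "rf", "rf1", "uf_rf1", "full"))
  expect_setequal(model_ids("fatigue"), c("uf", "rf", "rf1", "uf_rf1", "full"))
})
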
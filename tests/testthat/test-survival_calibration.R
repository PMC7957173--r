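test_that("rate_to_probability follows the exponential law", {
  expect_equal(rate_to_probability(0, 12), 0)
  expect_equal(rate_to_probability(log(2) / 10, 10), 0.5)
  # frozen high-precision value of 1 - exp(-0.3)
  expect_equal(rate_to_probability(0.1, 3), 0.2591817793182821, tolerance = 1e-15)
  expect_error(rate_to_probability(-0.1, 3), "non-negative")
  expect_error(rate_to_probability(0.1, -3), "non-negative")
})

test_that("per-cycle Weibull conditional probabilities are correct", {
  u <- 0.75
  # gamma = 1: memoryless, constant across cycles, equals the exponential
  p1 <- weibull_params(0.1, 1)
  probs <- weibull_transition_prob(p1, t = (1:20) * u, u = u)
  expect_equal(probs, rep(1 - exp(-0.1 * u), 20))
  expect_equal(probs[1], rate_to_probability(0.1, u))

  # first cycle conditions on time zero
  p2 <- weibull_params(0.05, 1.7)
  expect_equal(weibull_transition_prob(p2, t = u, u = u),
               1 - exp(-0.05 * u^1.7))

  # frozen oracle value for lambda=0.02, gamma=1.5, u=0.75, t=10
  expect_equal(weibull_transition_prob(weibull_params(0.02, 1.5), 10, 0.75),
               0.06741968079815571, tolerance = 1e-14)

  expect_error(weibull_transition_prob(p2, t = 0.5, u = 0.75), "at least one cycle")
  expect_error(weibull_params(-1, 1), "lambda")
  expect_error(weibull_params(1, 0), "gamma")
})

test_that("per-cycle probabilities telescope back to the survivor function", {
  grid <- expand.grid(lambda = c(0.005, 0.03, 0.1), gamma = c(0.8, 1, 1.3, 2))
  spec <- cycle_spec(21, 5)
  u <- cycle_months(spec)
  for (i in seq_len(nrow(grid))) {
    wp <- weibull_params(grid$lambda[i], grid$gamma[i])
    sched <- build_transition_schedule(wp, spec)
    surv_from_sched <- cumprod(1 - sched$p_event)
    surv_direct <- weibull_survivor(sched$time_months, wp$lambda, wp$gamma)
    expect_equal(surv_from_sched, surv_direct, tolerance = 1e-12)
  }
})

test_that("transition schedules have the right length and monotonicity", {
  sched <- build_transition_schedule(weibull_params(0.03, 1.3), cycle_spec(21, 5))
  expect_equal(nrow(sched), floor(5 * 365.25 / 21)) # 86
  expect_true(all(sched$p_event >= 0 & sched$p_event <= 1))

  # constant hazard: all entries equal
  flat <- build_transition_schedule(weibull_params(0.03, 1), cycle_spec(21, 5))
  expect_equal(length(unique(round(flat$p_event, 15))), 1)

  # increasing hazard (gamma > 1): nondecreasing entries, across a grid
  for (g in c(1.1, 1.5, 2, 3)) {
    s <- build_transition_schedule(weibull_params(0.01, g), cycle_spec(28, 10))
    expect_true(all(diff(s$p_event) >= -1e-15), info = paste("gamma", g))
  }
})

test_that("noiseless curves are recovered to high precision", {
  tt <- seq(2, 40, by = 2)
  for (par in list(c(0.03, 1.2), c(0.05, 1), c(0.008, 1.8))) {
    cv <- km_curve(c(0, tt), c(1, exp(-par[1] * tt^par[2])))
    ft <- fit_weibull(cv)
    expect_equal(ft$lambda, par[1], tolerance = 1e-6)
    expect_equal(ft$gamma, par[2], tolerance = 1e-6)
    expect_gt(ft$r_squared, 1 - 1e-10)
  }
})

test_that("fit refuses degenerate input and drops boundary points", {
  expect_error(fit_weibull(km_curve(c(0, 5, 10), c(1, 1, 1))), "interior")
  # survival exactly 0/1 and below 0.01 are excluded from the regression
  tt <- seq(2, 30, by = 2)
  sv <- exp(-0.03 * tt^1.2)
  cv <- km_curve(c(0, tt, 40, 50), c(1, sv, 0.005, 0))
  ft <- fit_weibull(cv)
  expect_equal(ft$n_points, length(tt))
  expect_equal(ft$lambda, 0.03, tolerance = 1e-6)
})

test_that("digitized-curve fits recover the survival function and median", {
  # The (lambda, gamma) coordinates are ill-conditioned on digitized data,
  # but the fitted survivor function and median are well identified.
  for (g in c(0.8, 1.2, 1.6, 2.0)) {
    for (seed in 1:3) {
      lam <- log(2) / 9.2^g
      cv <- simulate_km_curve(weibull_params(lam, g), n = 300,
                              censor_rate = 0.2, n_points = 30, seed = seed)
      ft <- fit_weibull(cv)
      med <- weibull_median(ft$lambda, ft$gamma)
      expect_lt(abs(med - 9.2) / 9.2, 0.10)
      expect_lt(abs(ft$gamma - g) / g, 0.25)
      tt <- cv$time[cv$time > 0]
      sup <- max(abs(weibull_survivor(tt, ft$lambda, ft$gamma) -
                       weibull_survivor(tt, lam, g)))
      expect_lt(sup, 0.06)
    }
  }
})

test_that("fitted median matches a curve generated at median 9.2 months", {
  truth <- weibull_params_from_median(9.2, gamma = 1.3)
  cv <- simulate_km_curve(truth, n = 300, censor_rate = 0.2, n_points = 30,
                          seed = 11)
  ft <- fit_weibull(cv)
  expect_equal(weibull_median(ft$lambda, ft$gamma), 9.2, tolerance = 0.1)
})

test_that("mle mode fits reconstructed pseudo-individual data", {
  tt <- seq(2, 40, by = 2)
  cv <- km_curve(c(0, tt), c(1, exp(-0.03 * tt^1.2)))
  ft <- fit_weibull(cv, method = "mle", n_pseudo = 2000)
  expect_equal(ft$gamma, 1.2, tolerance = 0.1)
  expect_equal(weibull_median(ft$lambda, ft$gamma),
               weibull_median(0.03, 1.2), tolerance = 0.5)
})

test_that("parameter tables round-trip and tidiers expose the fit", {
  cv1 <- simulate_km_curve(weibull_params(0.03, 1.2), seed = 1, arm = "a",
                           endpoint = "PFS")
  cv2 <- simulate_km_curve(weibull_params(0.01, 1.1), seed = 2, arm = "a",
                           endpoint = "OS")
  tab <- fit_parameter_table(list(cv1, cv2))
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("arm", "endpoint", "lambda", "gamma", "r_squared"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_parameter_table(tab, tmp)
  expect_equal(read_parameter_table(tmp), tab, tolerance = 1e-12)

  ft <- fit_weibull(cv1)
  td <- tidy(ft)
  expect_equal(td$term, c("lambda", "gamma"))
  gl <- glance(ft)
  expect_true(all(c("lambda", "gamma", "r.squared", "median") %in% names(gl)))
})
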
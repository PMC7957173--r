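test_that("single cohort steps are exact", {
  expect_equal(step_cohort(c(1, 0, 0), 0, 0), c(pfs = 1, pd = 0, death = 0))
  expect_equal(step_cohort(c(1, 0, 0), 0, 1), c(pfs = 0, pd = 0, death = 1))
  expect_equal(step_cohort(c(1, 0, 0), 0.3, 0.1),
               c(pfs = 0.7, pd = 0.2, death = 0.1))
  # PD is only exited through death
  expect_equal(step_cohort(c(0, 1, 0), 0.5, 0.2),
               c(pfs = 0, pd = 0.8, death = 0.2))
  expect_error(step_cohort(c(0.5, 0.2, 0.2), 0.1, 0.1), "sum to 1")
  expect_error(step_cohort(c(1, 0, 0), 1.2, 0.1), "\\[0, 1\\]")
})

test_that("discount factors follow the annual rate on the cycle grid", {
  spec <- cycle_spec(21, 5)
  expect_equal(discount_factor(0, spec), 1)
  # frozen: 1.03^-(17 * 21 / 365.25)
  expect_equal(discount_factor(17, spec), 0.9715222092689171, tolerance = 1e-14)
  expect_true(all(diff(discount_factor(0:86, spec)) < 0))
  expect_equal(discount_factor(10, cycle_spec(21, 5, 0)), 1)
})

test_that("a cohort with (near) zero transitions accrues utility for the whole horizon", {
  # 487-day cycles divide the 4-year horizon exactly (3 cycles), so the
  # undiscounted QALY equals u_pfs x horizon with no truncation remainder
  eps_law <- weibull_params(1e-30, 1)
  arm <- toy_arm("still", role = "treatment")
  arm$pfs_weibull <- eps_law
  arm$os_weibull <- eps_law
  spec <- cycle_spec(487, 4, 0)
  fc <- fixed_costs(0, 0, 0, 0, 0)
  tr <- run_cohort(arm, spec, fc, toy_prices())
  u_eff <- 0.8 + 0.3 * (-0.0731)
  expect_equal(attr(tr, "total_qaly"), u_eff * 4, tolerance = 1e-12)

  # general truncated closed form on a 21-day cycle
  spec21 <- cycle_spec(21, 5, 0)
  tr21 <- run_cohort(arm, spec21, fc, toy_prices())
  expect_equal(attr(tr21, "total_qaly"),
               u_eff * n_cycles(spec21) * 21 / 365.25, tolerance = 1e-12)
})

test_that("constant-hazard occupancy matches the geometric series", {
  p_exit <- 0.1
  u <- cycle_months(cycle_spec(21, 10))
  lam_pfs <- -log(1 - p_exit) / u
  arm <- toy_arm("geo", role = "treatment")
  arm$pfs_weibull <- weibull_params(lam_pfs, 1)
  arm$os_weibull <- weibull_params(1e-30, 1)
  spec <- cycle_spec(21, 10, 0)
  tr <- run_cohort(arm, spec, fixed_costs(0, 0, 0, 0, 0), toy_prices())
  # sum_k (1-p)^k = (1-p)/p up to the truncation tail
  expected_cycles <- (1 - p_exit) / p_exit
  truncation <- (1 - p_exit)^(n_cycles(spec) + 1) / p_exit
  expect_equal(sum(tr$pfs), expected_cycles, tolerance = truncation + 1e-10)
})

test_that("occupancy conserves mass and obeys monotonicity across random models", {
  set.seed(42)
  for (i in 1:20) {
    arm <- toy_arm("rnd",
                   lambda_pfs = runif(1, 0.005, 0.2), gamma_pfs = runif(1, 0.7, 2.5),
                   lambda_os = runif(1, 0.002, 0.05), gamma_os = runif(1, 0.7, 2),
                   role = "treatment")
    spec <- cycle_spec(sample(c(21, 28), 1), sample(c(5, 10), 1))
    tr <- run_cohort(arm, spec, fixed_costs(), toy_prices())
    expect_true(all(abs(tr$pfs + tr$pd + tr$death - 1) < 1e-12))
    expect_true(all(diff(tr$death) >= -1e-15))
    expect_true(all(diff(tr$pfs) <= 1e-15))
    expect_true(all(tr$pfs >= -1e-15 & tr$pd >= -1e-15))
  }
})

test_that("death occupancy tracks the OS survivor function exactly", {
  arm <- toy_arm("os", role = "treatment")
  spec <- cycle_spec(21, 10)
  tr <- run_cohort(arm, spec, fixed_costs(), toy_prices())
  s_os <- weibull_survivor(tr$time_months, arm$os_weibull$lambda,
                           arm$os_weibull$gamma)
  expect_equal(tr$death, 1 - s_os, tolerance = 1e-9)
  # and PFS occupancy tracks the PFS survivor while it dominates OS
  s_pfs <- weibull_survivor(tr$time_months, arm$pfs_weibull$lambda,
                            arm$pfs_weibull$gamma)
  expect_equal(tr$pfs, pmin(s_pfs, s_os), tolerance = 1e-9)
})

test_that("discounting reduces totals and longer horizons accrue more", {
  m <- load_trial("flaura")
  arm <- m$arms$osimertinib
  disc <- run_cohort(arm, m$cycle, m$costs, m$prices, m$patient)
  m0 <- m; m0$cycle$discount_annual <- 0
  undisc <- run_cohort(arm, m0$cycle, m0$costs, m0$prices, m0$patient)
  expect_lt(attr(disc, "total_cost"), attr(undisc, "total_cost"))
  expect_lt(attr(disc, "total_qaly"), attr(undisc, "total_qaly"))
  expect_equal(sum(undisc$cycle_cost), attr(undisc, "total_cost"))

  s5 <- run_model(m, horizon_years = 5)$summary
  s10 <- run_model(m, horizon_years = 10)$summary
  expect_true(all(s10$cost >= s5$cost))
  expect_true(all(s10$qaly >= s5$qaly))
})

test_that("cohort trace matches an individual-level microsimulation oracle", {
  m <- load_trial("archer1050")
  arm <- m$arms$dacomitinib
  tr <- run_cohort(arm, m$cycle, m$costs, m$prices, m$patient)
  ms <- microsimulate(arm, m$cycle, m$costs, m$prices, m$patient,
                      n_patients = 2e4, seed = 99)
  expect_lt(abs(ms$cost - attr(tr, "total_cost")), 3 * ms$se_cost)
  expect_lt(abs(ms$qaly - attr(tr, "total_qaly")), 3 * ms$se_qaly)
})

test_that("half-cycle correction shifts accrual without breaking occupancy", {
  m <- load_trial("flaura")
  arm <- m$arms$osimertinib
  full <- run_cohort(arm, m$cycle, m$costs, m$prices, m$patient)
  half <- run_cohort(arm, m$cycle, m$costs, m$prices, m$patient,
                     half_cycle = TRUE)
  # half-cycle accrual averages in the healthier cycle-start state
  expect_gt(attr(half, "total_qaly"), attr(full, "total_qaly"))
  expect_equal(half$death, full$death)
})

test_that("traces export to delimited text", {
  m <- load_trial("flaura")
  tr <- run_cohort(m$arms$egfr_tki, m$cycle, m$costs, m$prices, m$patient)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, tmp)
  back <- read.table(tmp, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(back), nrow(tr))
  expect_equal(back$cum_disc_cost[nrow(back)], attr(tr, "total_cost"),
               tolerance = 1e-6)
})
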
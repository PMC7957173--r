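test_that("all six packaged trial configs load and validate", {
  specs <- list(
    archer1050 = list(cycle = 28, arms = 2),
    flaura = list(cycle = 21, arms = 2),
    jo25567 = list(cycle = 21, arms = 2),
    nej026 = list(cycle = 21, arms = 2),
    nej009 = list(cycle = 21, arms = 2),
    nct02148380 = list(cycle = 28, arms = 3)
  )
  for (trial in names(specs)) {
    m <- load_trial(trial)
    expect_s3_class(m, "cea_model")
    expect_equal(m$cycle$cycle_days, specs[[trial]]$cycle, info = trial)
    expect_equal(m$cycle$horizon_years, 5L, info = trial)
    expect_length(m$arms, specs[[trial]]$arms)
    expect_equal(m$cycle$discount_annual, 0.03)
    expect_equal(m$cea$wtp, 30828)
    # every arm gets a provisional Weibull law from its published medians
    for (arm in m$arms) {
      expect_s3_class(arm$pfs_weibull, "weibull_params")
      expect_s3_class(arm$os_weibull, "weibull_params")
    }
  }
  expect_error(load_trial("nope"), "unknown trial")
})

test_that("fixtures carry the published prices, utilities, AE rates and medians", {
  # literal published parameter table: drug -> (pack USD, mg per pack)
  prices <- list(
    osimertinib = c(2171.48, 80 * 30), gefitinib = c(22.65, 250),
    erlotinib = c(10.08, 150), bevacizumab = c(212.89, 100),
    carboplatin = c(7.34, 100), pemetrexed = c(190.61, 200),
    dacomitinib = c(803.30, 15 * 30)
  )
  seen <- c()
  for (trial in trial_fixtures()) {
    m <- load_trial(trial)
    for (i in seq_len(nrow(m$prices))) {
      drug <- m$prices$name[i]
      expect_equal(m$prices$pack_price[i], prices[[drug]][1], info = drug)
      expect_equal(m$prices$pack_content_mg[i], prices[[drug]][2], info = drug)
      seen <- union(seen, drug)
    }
    expect_equal(m$costs$follow_up_per_cycle, 55.60)
    expect_equal(m$costs$supportive_care_per_cycle, 337.50)
    expect_equal(m$costs$ae_cost_per_cycle, 507.40)
    expect_equal(m$costs$pd_cost_per_week, 276.75)
    expect_equal(m$costs$terminal_care_per_week, 1412.92)
    for (arm in m$arms) {
      expect_equal(arm$utilities$pd, 0.70)
      expect_equal(arm$utilities$ae_disutility, -0.0731)
    }
  }
  expect_setequal(seen, names(prices))

  # per-arm utilities, AE rates and medians, spot-checked against the
  # published table
  fl <- load_trial("flaura")
  expect_equal(fl$arms$osimertinib$utilities$pfs_on_treatment, 0.84)
  expect_equal(fl$arms$osimertinib$utilities$ae_rate_grade3plus, 0.34)
  expect_equal(fl$arms$osimertinib$pfs_median_months, 18.9)
  expect_equal(fl$arms$osimertinib$os_median_months, 38.6)
  expect_equal(fl$arms$egfr_tki$utilities$pfs_on_treatment, 0.805)
  expect_equal(fl$arms$egfr_tki$pfs_median_months, 10.2)

  ar <- load_trial("archer1050")
  expect_equal(ar$arms$dacomitinib$utilities$pfs_on_treatment, 0.827)
  expect_equal(ar$arms$dacomitinib$utilities$ae_rate_grade3plus, 0.63)
  expect_equal(ar$arms$dacomitinib$pfs_median_months, 14.7)
  expect_equal(ar$arms$gefitinib$os_median_months, 26.8)

  jo <- load_trial("jo25567")
  expect_equal(jo$arms$bev_erlotinib$utilities$pfs_on_treatment, 0.76)
  expect_equal(jo$arms$bev_erlotinib$utilities$ae_rate_grade3plus, 0.91)
  expect_equal(jo$arms$erlotinib$utilities$pfs_on_treatment, 0.81)

  n9 <- load_trial("nej009")
  expect_equal(n9$arms$gef_carbo_pem$utilities$ae_rate_grade3plus, 0.653)
  expect_equal(n9$arms$gef_carbo_pem$pfs_median_months, 20.9)

  nct <- load_trial("nct02148380")
  expect_equal(nct$arms$pem_carbo$pfs_median_months, 5.7)
  expect_equal(nct$arms$gefitinib$utilities$ae_rate_grade3plus, 0.122)
  gef <- nct$arms$pem_carbo_gef$regimen[[3]]
  expect_equal(gef$days_on_per_cycle, 17)   # d5-21 of a 28-day cycle
  expect_equal(gef$max_cycles, 6)
  expect_true(gef$maintenance)
})

test_that("config validation catches missing fields and violated invariants", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  base <- yaml::read_yaml(system.file("extdata", "trials", "flaura.yaml",
                                      package = "egfrcea"))

  bad <- base; bad$cycle_days <- NULL
  yaml::write_yaml(bad, tmp)
  expect_error(load_model_config(tmp), "cycle_days")

  bad <- base; bad$arms[[1]]$utilities$pfs_on_treatment <- -0.1
  yaml::write_yaml(bad, tmp)
  expect_error(load_model_config(tmp), "pfs_on_treatment")

  bad <- base; bad$arms[[1]]$regimen[[1]]$drug <- "unpriced"
  yaml::write_yaml(bad, tmp)
  expect_error(load_model_config(tmp), "unpriced")

  bad <- base; bad$arms[[1]]$regimen[[1]]$days_on_per_cycle <- 40
  yaml::write_yaml(bad, tmp)
  expect_error(load_model_config(tmp), "days_on_per_cycle")

  # omitted discount falls back to 3%
  nodisc <- base; nodisc$discount_annual <- NULL
  yaml::write_yaml(nodisc, tmp)
  expect_equal(load_model_config(tmp)$cycle$discount_annual, 0.03)
})

test_that("configurations round-trip through serialization unchanged", {
  for (trial in c("flaura", "nct02148380")) {
    m <- load_trial(trial)
    tmp <- withr::local_tempfile(fileext = ".yaml")
    write_model_config(m, tmp)
    m2 <- load_model_config(tmp)
    expect_equal(m2$cycle, m$cycle)
    expect_equal(m2$patient, m$patient)
    expect_equal(m2$costs, m$costs)
    expect_equal(m2$cea, m$cea)
    expect_equal(m2$prices, m$prices)
    expect_equal(names(m2$arms), names(m$arms))
    for (nm in names(m$arms)) {
      expect_equal(m2$arms[[nm]]$regimen, m$arms[[nm]]$regimen, info = nm)
      expect_equal(m2$arms[[nm]]$utilities, m$arms[[nm]]$utilities)
      expect_equal(m2$arms[[nm]]$pfs_weibull$lambda, m$arms[[nm]]$pfs_weibull$lambda)
      expect_equal(m2$arms[[nm]]$route, m$arms[[nm]]$route)
    }
  }
})

test_that("KM curve validation enforces the invariants", {
  ok <- km_curve(c(0, 6, 12), c(1, 0.7, 0.4))
  expect_equal(nrow(ok), 3)

  # missing (0, 1) anchor is prepended
  fixed <- validate_km_curve(tibble::tibble(time = c(6, 12), survival = c(0.7, 0.4)))
  expect_equal(fixed$time[1], 0)
  expect_equal(fixed$survival[1], 1)

  expect_error(km_curve(c(0, 6, 12), c(1, 0.4, 0.7)), "index 3")
  expect_error(km_curve(c(0, 12, 6), c(1, 0.7, 0.4)), "increasing")
  expect_error(km_curve(c(0, 6, 12), c(1, 1.2, 0.4)), "\\[0, 1\\]")
})

test_that("KM curve files round-trip through the two-column dialect", {
  cv <- km_curve(c(0, 3, 6, 9), c(1, 0.8, 0.55, 0.4), endpoint = "OS",
                 arm = "test")
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_km_curve(cv, tmp)
  back <- read_km_curve(tmp, endpoint = "OS")
  expect_equal(back$time, cv$time)
  expect_equal(back$survival, cv$survival)
  expect_error(read_km_curve(tempfile(), "PFS"), "not found")
})
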
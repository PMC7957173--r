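# Builders for small fast models and the independent microsimulation oracle.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_prices <- function() {
  drug_prices(c("drugA", "drugB", "ivdrug"),
              pack_price = c(100, 10, 250),
              pack_content_mg = c(100, 50, 100))
}

toy_arm <- function(name = "treat", lambda_pfs = 0.05, gamma_pfs = 1.2,
                    lambda_os = 0.02, gamma_os = 1.1,
                    u_pfs = 0.8, ae_rate = 0.3, drug = "drugA",
                    dose = 100, role = "treatment") {
  arm_model(
    name = name,
    regimen = list(regimen_component(drug, "fixed_daily", dose)),
    utilities = utility_set(u_pfs, pd = 0.7, ae_disutility = -0.0731,
                            ae_rate_grade3plus = ae_rate),
    route = "oral_only",
    pfs_weibull = weibull_params(lambda_pfs, gamma_pfs),
    os_weibull = weibull_params(lambda_os, gamma_os),
    role = role
  )
}

toy_model <- function(cycle_days = 21, horizon_years = 5, discount = 0.03,
                      costs = fixed_costs(), arms = NULL) {
  arms <- arms %||% list(
    toy_arm("treat", role = "treatment"),
    toy_arm("ctrl", lambda_pfs = 0.08, lambda_os = 0.03, u_pfs = 0.78,
            ae_rate = 0.2, drug = "drugB", dose = 50, role = "control")
  )
  cea_model(
    trial = "toy", cycle = cycle_spec(cycle_days, horizon_years, discount),
    arms = arms, prices = toy_prices(), costs = costs,
    patient = patient_profile(), cea = cea_config()
  )
}

# Independent oracle: individual-level microsimulation stepped with the
# same per-cycle probabilities and unit costs as the cohort engine.
# Returns Monte Carlo means and standard errors of discounted cost/QALY.
microsimulate <- function(arm, spec, costs, prices,
                          patient = patient_profile(),
                          n_patients = 1e4, seed = 1) {
  set.seed(seed)
  sched <- transition_schedules(arm, spec)
  n_cyc <- nrow(sched$pfs)
  u_years <- cycle_years(spec)
  u_weeks <- cycle_weeks(spec)
  terminal_cost <- costs$terminal_care_per_week *
    (costs$terminal_care_weeks %||% u_weeks)
  pd_cycle_cost <- costs$pd_cost_per_week * u_weeks
  fixed <- costs$follow_up_per_cycle + costs$supportive_care_per_cycle +
    costs$examination_per_cycle
  ae_cost <- expected_ae_cost(arm$utilities, costs)
  u_pfs_eff <- arm$utilities$pfs_on_treatment +
    arm$utilities$ae_rate_grade3plus * arm$utilities$ae_disutility
  u_pd <- arm$utilities$pd

  state <- rep(1L, n_patients) # 1 PFS, 2 PD, 3 dead
  cost <- numeric(n_patients)
  qaly <- numeric(n_patients)
  for (k in seq_len(n_cyc)) {
    p_exit <- sched$pfs$p_event[k]
    p_death <- sched$os$p_event[k]
    to_pd <- max(0, p_exit - p_death)
    alive <- state != 3L
    u1 <- runif(n_patients)
    newstate <- state
    # death claims p_death from every alive state
    dies <- alive & (u1 < p_death)
    newstate[dies] <- 3L
    # PFS survivors of death move to PD with conditional prob to_pd/(1-p_death)
    in_pfs <- state == 1L & !dies
    if (p_death < 1) {
      u2 <- runif(n_patients)
      prog <- in_pfs & (u2 < to_pd / (1 - p_death))
      newstate[prog] <- 2L
    }
    df <- discount_factor(k, spec)
    drug <- drug_cost_per_cycle(arm$regimen, k, spec, prices, patient)
    pfs_cost <- drug + fixed + ae_cost
    cost <- cost + df * ((newstate == 1L) * pfs_cost +
                           (newstate == 2L) * pd_cycle_cost +
                           dies * terminal_cost)
    qaly <- qaly + df * u_years * ((newstate == 1L) * u_pfs_eff +
                                     (newstate == 2L) * u_pd)
    state <- newstate
  }
  list(cost = mean(cost), qaly = mean(qaly),
       se_cost = sd(cost) / sqrt(n_patients),
       se_qaly = sd(qaly) / sqrt(n_patients))
}

# Numerical oracle for synthetic end-to-end runs: cohort occupancy taken
# directly from the true survivor functions (no Markov stepping), costs
# and QALYs accrued with the same per-cycle accounting.
oracle_arm_values <- function(arm, spec, costs, prices,
                              patient = patient_profile()) {
  u <- cycle_months(spec)
  n <- n_cycles(spec)
  u_years <- cycle_years(spec)
  u_weeks <- cycle_weeks(spec)
  terminal_cost <- costs$terminal_care_per_week *
    (costs$terminal_care_weeks %||% u_weeks)
  pd_cycle_cost <- costs$pd_cost_per_week * u_weeks
  fixed <- costs$follow_up_per_cycle + costs$supportive_care_per_cycle +
    costs$examination_per_cycle
  ae_cost <- expected_ae_cost(arm$utilities, costs)
  u_pfs_eff <- arm$utilities$pfs_on_treatment +
    arm$utilities$ae_rate_grade3plus * arm$utilities$ae_disutility
  tk <- seq_len(n) * u
  s_pfs <- weibull_survivor(tk, arm$pfs_weibull$lambda, arm$pfs_weibull$gamma)
  s_os <- weibull_survivor(tk, arm$os_weibull$lambda, arm$os_weibull$gamma)
  pfs <- pmin(s_pfs, s_os)
  death <- 1 - s_os
  pd <- 1 - pfs - death
  new_deaths <- diff(c(0, death))
  df <- discount_factor(seq_len(n), spec)
  drug <- vapply(seq_len(n), function(k) {
    drug_cost_per_cycle(arm$regimen, k, spec, prices, patient)
  }, 0)
  cost <- sum(df * (pfs * (drug + fixed + ae_cost) + pd * pd_cycle_cost +
                      new_deaths * terminal_cost))
  qaly <- sum(df * u_years * (pfs * u_pfs_eff + pd * arm$utilities$pd))
  list(cost = cost, qaly = qaly)
}
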
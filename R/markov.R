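#' Discount factor at a cycle boundary
#'
#' `(1 + discount_annual)^-(cycle_index * cycle_years)`: costs and QALYs
#' accrued in cycle `k` are discounted to present value at the cycle's
#' end time.
#'
#' @param cycle_index cycle number (0 returns 1).
#' @param spec a [cycle_spec()].
#' @return factor in (0, 1\].
#' @export
#' @examples
#' discount_factor(17, cycle_spec(21, 5)) # 1.03^-(17 * 21 / 365.25)
discount_factor <- function(cycle_index, spec) {
  if (any(cycle_index < 0)) abort("`cycle_index` must be >= 0.")
  (1 + spec$discount_annual)^(-(cycle_index * cycle_years(spec)))
}

#' Advance the cohort one cycle
#'
#' Three states: progression-free (PFS), progressive disease (PD), death.
#' Death absorbs. Death claims `p_death` from both alive states (the
#' overall-survival law drives mortality regardless of progression
#' status); PFS additionally loses `max(0, p_exit_pfs - p_death)` to PD,
#' so that the marginal PFS and OS curves both track their fitted laws.
#'
#' @param state occupancy vector `c(pfs, pd, death)`, summing to 1.
#' @param p_exit_pfs per-cycle probability of leaving PFS (progression or
#'   death; the PFS-endpoint event).
#' @param p_death per-cycle death probability (the OS-endpoint event).
#' @return the next occupancy vector.
#' @export
#' @examples
#' step_cohort(c(1, 0, 0), p_exit_pfs = 0.3, p_death = 0.1)
step_cohort <- function(state, p_exit_pfs, p_death) {
  if (abs(sum(state) - 1) > 1e-9) {
    abort("occupancy vector must sum to 1 (within 1e-9).")
  }
  if (p_exit_pfs < 0 || p_exit_pfs > 1 || p_death < 0 || p_death > 1) {
    abort("transition probabilities must lie in [0, 1].")
  }
  pfs <- state[1]; pd <- state[2]; death <- state[3]
  to_pd <- max(0, p_exit_pfs - p_death)
  pfs_new <- pfs * (1 - p_death - to_pd)
  pd_new <- pd * (1 - p_death) + pfs * to_pd
  death_new <- death + (pfs + pd) * p_death
  c(pfs = unname(pfs_new), pd = unname(pd_new), death = unname(death_new))
}

#' Per-cycle transition schedules for an arm
#'
#' @param arm an [arm_model()] with both Weibull laws present.
#' @param spec a [cycle_spec()].
#' @return list with tibbles `pfs` (exit-PFS probabilities) and `os`
#'   (death probabilities), as from [build_transition_schedule()].
#' @export
transition_schedules <- function(arm, spec) {
  if (is.null(arm$pfs_weibull) || is.null(arm$os_weibull)) {
    abort(paste0("arm `", arm$name, "` lacks fitted Weibull laws; fit or ",
                 "supply them (or published medians) first."))
  }
  list(pfs = build_transition_schedule(arm$pfs_weibull, spec),
       os = build_transition_schedule(arm$os_weibull, spec))
}

#' Run the cohort model for one arm
#'
#' Propagates the whole cohort (everyone starts progression-free) through
#' `floor(horizon / u)` cycles and accrues discounted costs and QALYs at
#' each cycle end:
#' cost = PFS occupancy x (drug + follow-up/supportive + expected AE
#' cost) + PD occupancy x weekly PD cost x weeks per cycle + newly dead
#' fraction x one-time terminal-care cost; QALY = \[PFS x (utility +
#' AE rate x AE disutility) + PD x PD utility\] x cycle length in years.
#'
#' @param arm an [arm_model()] with Weibull laws.
#' @param spec a [cycle_spec()].
#' @param costs a [fixed_costs()].
#' @param prices a [drug_prices()] tibble.
#' @param patient a [patient_profile()].
#' @param half_cycle if `TRUE`, state occupancy for accrual is the mean of
#'   cycle-start and cycle-end occupancy (half-cycle correction); default
#'   `FALSE` (cycle-end evaluation).
#' @param drug_cost_multiplier scales drug acquisition costs only (used by
#'   the price-concession solver); default 1.
#' @return a tibble of class `cohort_trace` with one row per cycle:
#'   `cycle`, `time_months`, `pfs`, `pd`, `death`, `new_deaths`,
#'   `cycle_cost`, `cycle_qaly`, `disc_cost`, `disc_qaly`,
#'   `cum_disc_cost`, `cum_disc_qaly`. Totals via [glance()].
#' @export
run_cohort <- function(arm, spec, costs, prices, patient = patient_profile(),
                       half_cycle = FALSE, drug_cost_multiplier = 1) {
  spec <- validate_cycle_spec(spec)
  sched <- transition_schedules(arm, spec)
  n <- nrow(sched$pfs)
  u_years <- cycle_years(spec)
  u_weeks <- cycle_weeks(spec)
  terminal_weeks <- costs$terminal_care_weeks %||% u_weeks
  terminal_cost <- costs$terminal_care_per_week * terminal_weeks
  pd_cycle_cost <- costs$pd_cost_per_week * u_weeks
  fixed <- costs$follow_up_per_cycle + costs$supportive_care_per_cycle +
    costs$examination_per_cycle
  ae_cost <- expected_ae_cost(arm$utilities, costs)
  u_pfs_eff <- arm$utilities$pfs_on_treatment +
    arm$utilities$ae_rate_grade3plus * arm$utilities$ae_disutility
  u_pd <- arm$utilities$pd

  drug_sched <- drug_cost_schedule(arm$regimen, n, spec, prices, patient) *
    drug_cost_multiplier

  state <- c(pfs = 1, pd = 0, death = 0)
  out <- matrix(0, nrow = n, ncol = 10,
                dimnames = list(NULL, c("pfs", "pd", "death", "new_deaths",
                                        "cycle_cost", "cycle_qaly",
                                        "disc_cost", "disc_qaly",
                                        "cum_disc_cost", "cum_disc_qaly")))
  cum_cost <- 0; cum_qaly <- 0
  for (k in seq_len(n)) {
    prev <- state
    state <- step_cohort(state, sched$pfs$p_event[k], sched$os$p_event[k])
    new_deaths <- state[["death"]] - prev[["death"]]
    acc <- if (half_cycle) (prev + state) / 2 else state
    drug <- drug_sched[k]
    cost_k <- acc[["pfs"]] * (drug + fixed + ae_cost) +
      acc[["pd"]] * pd_cycle_cost +
      new_deaths * terminal_cost
    qaly_k <- (acc[["pfs"]] * u_pfs_eff + acc[["pd"]] * u_pd) * u_years
    df <- discount_factor(k, spec)
    cum_cost <- cum_cost + cost_k * df
    cum_qaly <- cum_qaly + qaly_k * df
    out[k, ] <- c(state, new_deaths, cost_k, qaly_k, cost_k * df,
                  qaly_k * df, cum_cost, cum_qaly)
  }
  trace <- tibble::as_tibble(as.data.frame(out))
  trace <- tibble::add_column(trace,
                              cycle = seq_len(n),
                              time_months = seq_len(n) * cycle_months(spec),
                              .before = 1)
  structure(trace, arm = arm$name,
            total_cost = cum_cost, total_qaly = cum_qaly,
            class = c("cohort_trace", class(trace)))
}

#' @export
glance.cohort_trace <- function(x, ...) {
  tibble::tibble(arm = attr(x, "arm"),
                 cost = attr(x, "total_cost"),
                 qaly = attr(x, "total_qaly"))
}

#' Run every arm of a model
#'
#' @param model a `cea_model`.
#' @param horizon_years optional horizon override.
#' @param half_cycle passed to [run_cohort()].
#' @param drug_cost_multipliers optional named vector scaling drug costs
#'   per arm (names are arm names; unnamed arms use 1).
#' @return list with `traces` (named list of `cohort_trace`) and `summary`
#'   (tibble `arm`, `cost`, `qaly`).
#' @export
run_model <- function(model, horizon_years = NULL, half_cycle = FALSE,
                      drug_cost_multipliers = NULL) {
  if (!is.null(horizon_years)) {
    model$cycle$horizon_years <- as.integer(horizon_years)
  }
  traces <- lapply(model$arms, function(arm) {
    mult <- 1
    if (!is.null(drug_cost_multipliers) &&
        arm$name %in% names(drug_cost_multipliers)) {
      mult <- drug_cost_multipliers[[arm$name]]
    }
    run_cohort(arm, model$cycle, model$costs, model$prices, model$patient,
               half_cycle = half_cycle, drug_cost_multiplier = mult)
  })
  summary <- purrr::map_dfr(traces, glance)
  list(traces = traces, summary = summary)
}

#' Export a cohort trace to delimited text
#'
#' @param trace a `cohort_trace`.
#' @param path output path (tab-delimited with a header comment).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cohort trace, arm: %s", attr(trace, "arm")), con)
  write.table(as.data.frame(trace), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
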
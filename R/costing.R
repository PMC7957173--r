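#' Dose delivered per administration
#'
#' Resolves a regimen component's dosing rule against the reference
#' patient: `fixed_daily` returns the daily mg dose; `per_kg` multiplies
#' by weight; `per_bsa` by body surface area; `auc_dose` returns the
#' configured fixed mg-equivalent (carboplatin AUC dosing, for which no
#' anthropometric formula is applied).
#'
#' @param component a [regimen_component()].
#' @param patient a [patient_profile()].
#' @return dose in mg per administration (per day for `fixed_daily`).
#' @export
#' @examples
#' bev <- regimen_component("bevacizumab", "per_kg", 15)
#' dose_per_administration(bev, patient_profile()) # 975 mg
dose_per_administration <- function(component, patient) {
  switch(component$dosing,
    fixed_daily = component$dose,
    per_kg = component$dose * patient$weight_kg,
    per_bsa = component$dose * patient$bsa_m2,
    auc_dose = component$dose,
    abort(paste0("unknown dosing kind `", component$dosing, "`."))
  )
}

component_active_days <- function(component, cycle_index, cycle_days) {
  if (cycle_index <= component$max_cycles) {
    component$days_on_per_cycle %||% cycle_days
  } else if (isTRUE(component$maintenance)) {
    component$maintenance_days_on %||% component$days_on_per_cycle %||% cycle_days
  } else {
    0
  }
}

component_cost <- function(component, cycle_index, spec, prices, patient) {
  row <- prices[prices$name == component$drug, ]
  if (nrow(row) == 0) abort(paste0("no price for drug `", component$drug, "`."))
  oral <- component$dosing == "fixed_daily"
  if (oral) {
    days <- component_active_days(component, cycle_index, spec$cycle_days)
    # tablets priced pro-rata per mg-day
    per_day <- component$dose / row$pack_content_mg * row$pack_price
    per_day * days
  } else {
    active <- cycle_index <= component$max_cycles ||
      (isTRUE(component$maintenance))
    if (!active) return(0)
    dose <- dose_per_administration(component, patient)
    # whole-vial billing: round up, no vial sharing
    ceiling(dose / row$pack_content_mg) * row$pack_price
  }
}

#' Drug acquisition cost for one model cycle
#'
#' Oral components (`fixed_daily`) are priced pro-rata per mg-day times
#' the days dosed that cycle; intravenous components are billed in whole
#' vials (`ceiling(dose / pack_content) * pack_price`) once per cycle.
#' Components past their `max_cycles` contribute only if flagged as
#' maintenance.
#'
#' @param regimen list of [regimen_component()]s.
#' @param cycle_index 1-based model cycle.
#' @param spec a [cycle_spec()].
#' @param prices a [drug_prices()] tibble.
#' @param patient a [patient_profile()].
#' @return USD for that cycle.
#' @export
#' @examples
#' gef <- regimen_component("gefitinib", "fixed_daily", 250)
#' pr <- drug_prices("gefitinib", 22.65, 250)
#' drug_cost_per_cycle(list(gef), 1, cycle_spec(28, 5), pr, patient_profile())
drug_cost_per_cycle <- function(regimen, cycle_index, spec, prices, patient) {
  sum(vapply(regimen, component_cost, 0,
             cycle_index = cycle_index, spec = spec, prices = prices,
             patient = patient))
}

#' Drug acquisition cost schedule over the whole horizon
#'
#' Vectorised equivalent of calling [drug_cost_per_cycle()] for cycles
#' `1..n_cycles`.
#'
#' @inheritParams drug_cost_per_cycle
#' @param n_cycles number of cycles.
#' @return numeric vector of USD, one entry per cycle.
#' @export
drug_cost_schedule <- function(regimen, n_cycles, spec, prices, patient) {
  total <- numeric(n_cycles)
  k <- seq_len(n_cycles)
  for (component in regimen) {
    idx <- match(component$drug, prices$name)
    if (is.na(idx)) abort(paste0("no price for drug `", component$drug, "`."))
    pack_price <- prices$pack_price[idx]
    pack_mg <- prices$pack_content_mg[idx]
    initial <- k <= component$max_cycles
    if (component$dosing == "fixed_daily") {
      d_init <- component$days_on_per_cycle %||% spec$cycle_days
      d_maint <- if (isTRUE(component$maintenance)) {
        component$maintenance_days_on %||% d_init
      } else 0
      days <- ifelse(initial, d_init, d_maint)
      total <- total + component$dose / pack_mg * pack_price * days
    } else {
      dose <- dose_per_administration(component, patient)
      per_admin <- ceiling(dose / pack_mg) * pack_price
      active <- initial | isTRUE(component$maintenance)
      total <- total + per_admin * active
    }
  }
  total
}

#' Expected adverse-event management cost per cycle in PFS
#'
#' Grade >= 3 events are treatment-emergent, so their expected management
#' cost (trial AE rate times the per-cycle AE cost) accrues only while
#' progression-free on treatment.
#'
#' @param utilities a [utility_set()] (carries the arm's AE rate).
#' @param costs a [fixed_costs()].
#' @return USD per cycle.
#' @export
expected_ae_cost <- function(utilities, costs) {
  utilities$ae_rate_grade3plus * costs$ae_cost_per_cycle
}

#' Per-cycle cost breakdown for an arm
#'
#' @param arm an [arm_model()].
#' @param spec a [cycle_spec()].
#' @param prices a [drug_prices()] tibble.
#' @param patient a [patient_profile()].
#' @param costs a [fixed_costs()].
#' @param n_cycles number of cycles (default: the spec's horizon).
#' @return a tibble (`arm`, `cycle`, `drug_cost`, `fixed_cost`, `ae_cost`,
#'   `total`), where `fixed_cost` is follow-up + supportive care +
#'   scheduled examinations and `total` is the PFS-state per-cycle cost.
#' @export
cost_breakdown <- function(arm, spec, prices, patient, costs,
                           n_cycles = NULL) {
  n <- n_cycles %||% n_cycles(spec)
  drug <- drug_cost_schedule(arm$regimen, n, spec, prices, patient)
  fixed <- costs$follow_up_per_cycle + costs$supportive_care_per_cycle +
    costs$examination_per_cycle
  ae <- expected_ae_cost(arm$utilities, costs)
  tibble::tibble(arm = arm$name, cycle = seq_len(n), drug_cost = drug,
                 fixed_cost = fixed, ae_cost = ae,
                 total = drug + fixed + ae)
}
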
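#' Cycle and horizon specification
#'
#' @param cycle_days model cycle length in days (trials here use 21 or 28).
#' @param horizon_years time horizon in whole years (5 or 10 in the shipped
#'   fixtures).
#' @param discount_annual annual discount rate applied to both costs and
#'   QALYs; default 0.03.
#' @return a list of class `cycle_spec`.
#' @export
#' @examples
#' cycle_spec(21, 5)
cycle_spec <- function(cycle_days, horizon_years, discount_annual = 0.03) {
  validate_cycle_spec(structure(
    list(cycle_days = as.integer(cycle_days),
         horizon_years = as.integer(horizon_years),
         discount_annual = discount_annual),
    class = "cycle_spec"
  ))
}

validate_cycle_spec <- function(spec) {
  if (is.null(spec$cycle_days) || spec$cycle_days <= 0) {
    abort("cycle_spec: `cycle_days` must be a positive integer.")
  }
  if (is.null(spec$horizon_years) || spec$horizon_years <= 0) {
    abort("cycle_spec: `horizon_years` must be a positive integer.")
  }
  d <- spec$discount_annual %||% 0.03
  if (d < 0 || d >= 1) abort("cycle_spec: `discount_annual` must lie in [0, 1).")
  spec$discount_annual <- d
  spec
}

#' Cycle length in months, years, weeks; number of whole cycles
#'
#' One month is 365.25/12 days. The horizon is truncated by floor
#' division: no partial final cycle.
#'
#' @param spec a `cycle_spec`.
#' @return a scalar.
#' @export
cycle_months <- function(spec) spec$cycle_days / DAYS_PER_MONTH

#' @rdname cycle_months
#' @export
cycle_years <- function(spec) spec$cycle_days / DAYS_PER_YEAR

#' @rdname cycle_months
#' @export
cycle_weeks <- function(spec) spec$cycle_days / 7

#' @rdname cycle_months
#' @export
n_cycles <- function(spec) {
  floor(spec$horizon_years * DAYS_PER_YEAR / spec$cycle_days)
}

#' Reference patient anthropometrics
#'
#' Used for per-kg and per-BSA intravenous dosing.
#'
#' @param height_m height in metres (default 1.64).
#' @param weight_kg weight in kg (default 65).
#' @param bsa_m2 body surface area in m^2 (default 1.72).
#' @return a list of class `patient_profile`.
#' @export
patient_profile <- function(height_m = 1.64, weight_kg = 65, bsa_m2 = 1.72) {
  if (any(c(height_m, weight_kg, bsa_m2) <= 0)) {
    abort("patient_profile: height, weight and BSA must all be positive.")
  }
  structure(list(height_m = height_m, weight_kg = weight_kg, bsa_m2 = bsa_m2),
            class = "patient_profile")
}

#' Health-state utilities and adverse-event parameters for one arm
#'
#' @param pfs_on_treatment utility while progression-free on treatment, in
#'   \[0, 1\] (drug-specific for oral monotherapy; a single intravenous-
#'   therapy utility for regimens containing an IV component).
#' @param pd utility in the progressive-disease state (default 0.70).
#' @param ae_disutility decrement for grade >= 3 adverse events, `<= 0`
#'   (default -0.0731); applied in PFS weighted by `ae_rate_grade3plus`.
#' @param ae_rate_grade3plus trial-reported grade >= 3 AE rate in \[0, 1\].
#' @return a list of class `utility_set`.
#' @export
utility_set <- function(pfs_on_treatment, pd = 0.70, ae_disutility = -0.0731,
                        ae_rate_grade3plus = 0) {
  u <- structure(list(pfs_on_treatment = pfs_on_treatment, pd = pd,
                      ae_disutility = ae_disutility,
                      ae_rate_grade3plus = ae_rate_grade3plus),
                 class = "utility_set")
  validate_utility_set(u)
}

validate_utility_set <- function(u) {
  for (fld in c("pfs_on_treatment", "pd")) {
    v <- u[[fld]]
    if (is.null(v) || v < 0 || v > 1) {
      abort(paste0("utility_set: `", fld, "` must lie in [0, 1]."))
    }
  }
  if (u$ae_disutility > 0) abort("utility_set: `ae_disutility` must be <= 0.")
  r <- u$ae_rate_grade3plus %||% 0
  if (r < 0 || r > 1) abort("utility_set: `ae_rate_grade3plus` must lie in [0, 1].")
  u
}

#' Non-drug cost parameters (USD)
#'
#' Per-cycle follow-up, supportive-care and adverse-event management costs
#' apply while progression-free; the progressive-disease state is costed
#' per week; terminal care is a one-time cost on entry to death, priced
#' per week over `terminal_care_weeks` (default: one cycle length).
#' Examination costs may be scheduled per cycle via
#' `examination_per_cycle`; the default folds them into the lumped
#' follow-up/supportive totals (i.e. zero extra).
#'
#' @param follow_up_per_cycle USD per cycle (default 55.60).
#' @param supportive_care_per_cycle USD per cycle (default 337.50).
#' @param ae_cost_per_cycle USD per cycle at AE rate 1 (default 507.40).
#' @param pd_cost_per_week USD per week in PD (default 276.75).
#' @param terminal_care_per_week USD per week (default 1412.92).
#' @param terminal_care_weeks weeks of terminal care billed on death entry;
#'   `NULL` means one cycle length.
#' @param examination_per_cycle additional scheduled examinations, USD per
#'   cycle (default 0).
#' @return a list of class `fixed_costs`.
#' @export
fixed_costs <- function(follow_up_per_cycle = 55.60,
                        supportive_care_per_cycle = 337.50,
                        ae_cost_per_cycle = 507.40,
                        pd_cost_per_week = 276.75,
                        terminal_care_per_week = 1412.92,
                        terminal_care_weeks = NULL,
                        examination_per_cycle = 0) {
  fc <- structure(list(
    follow_up_per_cycle = follow_up_per_cycle,
    supportive_care_per_cycle = supportive_care_per_cycle,
    ae_cost_per_cycle = ae_cost_per_cycle,
    pd_cost_per_week = pd_cost_per_week,
    terminal_care_per_week = terminal_care_per_week,
    terminal_care_weeks = terminal_care_weeks,
    examination_per_cycle = examination_per_cycle
  ), class = "fixed_costs")
  validate_fixed_costs(fc)
}

validate_fixed_costs <- function(fc) {
  for (fld in c("follow_up_per_cycle", "supportive_care_per_cycle",
                "ae_cost_per_cycle", "pd_cost_per_week",
                "terminal_care_per_week", "examination_per_cycle")) {
    v <- fc[[fld]]
    if (is.null(v) || v < 0) abort(paste0("fixed_costs: `", fld, "` must be >= 0."))
  }
  fc
}

#' Drug price table
#'
#' @param name drug names.
#' @param pack_price USD per pack (or vial).
#' @param pack_content_mg mg (or mg-equivalent billing units) per pack.
#' @return a tibble with one row per drug.
#' @export
#' @examples
#' drug_prices("gefitinib", 22.65, 250)
drug_prices <- function(name, pack_price, pack_content_mg) {
  if (any(pack_price < 0)) abort("drug_prices: `pack_price` must be >= 0.")
  if (any(pack_content_mg <= 0)) abort("drug_prices: `pack_content_mg` must be > 0.")
  tibble::tibble(name = unname(name), pack_price = unname(pack_price),
                 pack_content_mg = unname(pack_content_mg))
}

#' One component of a treatment regimen
#'
#' @param drug drug name (must be priced in the model's price table).
#' @param dosing dosing rule: `"fixed_daily"` (mg/day, oral),
#'   `"per_kg"` (mg/kg once per cycle, IV), `"per_bsa"` (mg/m^2 once per
#'   cycle, IV), or `"auc_dose"` (configured fixed mg-equivalent once per
#'   cycle, IV; used for carboplatin AUC dosing).
#' @param dose the dose in the unit implied by `dosing`.
#' @param days_on_per_cycle for oral drugs, days dosed per cycle (default:
#'   every day of the cycle).
#' @param max_cycles last cycle in which the component is given at its
#'   initial schedule; `Inf` when unbounded.
#' @param maintenance if `TRUE` the component continues past `max_cycles`
#'   (at `maintenance_days_on` days per cycle for oral drugs).
#' @param maintenance_days_on oral days-on per cycle during maintenance
#'   (default: `days_on_per_cycle`).
#' @return a list of class `regimen_component`.
#' @export
regimen_component <- function(drug,
                              dosing = c("fixed_daily", "per_kg", "per_bsa", "auc_dose"),
                              dose, days_on_per_cycle = NULL,
                              max_cycles = Inf, maintenance = FALSE,
                              maintenance_days_on = NULL) {
  dosing <- match.arg(dosing)
  if (dose < 0) abort("regimen_component: `dose` must be >= 0.")
  if (is.finite(max_cycles) && max_cycles < 1) {
    abort("regimen_component: `max_cycles` must be >= 1 when bounded.")
  }
  structure(list(drug = drug, dosing = dosing, dose = dose,
                 days_on_per_cycle = days_on_per_cycle,
                 max_cycles = max_cycles, maintenance = maintenance,
                 maintenance_days_on = maintenance_days_on),
            class = "regimen_component")
}

#' Treatment arm: transition laws, regimen, utilities
#'
#' @param name arm label.
#' @param regimen non-empty list of [regimen_component()]s.
#' @param utilities a [utility_set()].
#' @param route `"oral_only"` or `"contains_iv"`.
#' @param pfs_weibull,os_weibull `weibull_params` for the PFS and OS
#'   survivor laws (may be `NULL` at construction and attached after
#'   fitting or via [weibull_params_from_median()]).
#' @param pfs_median_months,os_median_months published medians, months
#'   (used by the synthetic generator and to derive provisional Weibull
#'   laws when none are supplied).
#' @param role `"treatment"`, `"control"` or `"other"`.
#' @return a list of class `arm_model`.
#' @export
arm_model <- function(name, regimen, utilities,
                      route = c("oral_only", "contains_iv"),
                      pfs_weibull = NULL, os_weibull = NULL,
                      pfs_median_months = NULL, os_median_months = NULL,
                      role = "other") {
  route <- match.arg(route)
  if (length(regimen) == 0) abort("arm_model: `regimen` must be non-empty.")
  if (inherits(regimen, "regimen_component")) regimen <- list(regimen)
  structure(list(name = name, regimen = regimen,
                 utilities = validate_utility_set(utilities), route = route,
                 pfs_weibull = pfs_weibull, os_weibull = os_weibull,
                 pfs_median_months = pfs_median_months,
                 os_median_months = os_median_months, role = role),
            class = "arm_model")
}

#' Analysis configuration: WTP threshold and sensitivity-analysis settings
#'
#' @param wtp willingness-to-pay threshold, USD/QALY (default 30828, three
#'   times China's per-capita GDP).
#' @param psa_iterations Monte Carlo iterations for the PSA (default 1000).
#' @param seed integer seed for the PSA generator.
#' @param dsa_cost_range one-way range for cost parameters (default 0.30).
#' @param dsa_other_range one-way range for utilities and probabilities
#'   (default 0.20).
#' @return a list of class `cea_config`.
#' @export
cea_config <- function(wtp = 30828, psa_iterations = 1000, seed = 1L,
                       dsa_cost_range = 0.30, dsa_other_range = 0.20) {
  if (wtp <= 0) abort("cea_config: `wtp` must be > 0.")
  if (psa_iterations < 1) abort("cea_config: `psa_iterations` must be >= 1.")
  if (dsa_cost_range <= 0 || dsa_cost_range >= 1 ||
      dsa_other_range <= 0 || dsa_other_range >= 1) {
    abort("cea_config: sensitivity ranges must lie in (0, 1).")
  }
  structure(list(wtp = wtp, psa_iterations = as.integer(psa_iterations),
                 seed = as.integer(seed), dsa_cost_range = dsa_cost_range,
                 dsa_other_range = dsa_other_range),
            class = "cea_config")
}
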
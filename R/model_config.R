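#' Assemble a full decision model
#'
#' @param trial trial label.
#' @param cycle a [cycle_spec()].
#' @param arms list of [arm_model()]s (first listed treatment/control roles
#'   drive the default comparison).
#' @param prices a [drug_prices()] tibble covering every drug in every
#'   regimen.
#' @param costs a [fixed_costs()].
#' @param patient a [patient_profile()].
#' @param cea a [cea_config()].
#' @param metadata free-form provenance list (e.g. exchange-rate note).
#' @return a list of class `cea_model`.
#' @export
cea_model <- function(trial, cycle, arms, prices, costs = fixed_costs(),
                      patient = patient_profile(), cea = cea_config(),
                      metadata = list()) {
  model <- structure(list(trial = trial, cycle = cycle, arms = arms,
                          prices = prices, costs = costs, patient = patient,
                          cea = cea, metadata = metadata),
                     class = "cea_model")
  validate_cea_model(model)
}

validate_cea_model <- function(model) {
  model$cycle <- validate_cycle_spec(model$cycle)
  model$costs <- validate_fixed_costs(model$costs)
  if (length(model$arms) == 0) abort("cea_model: at least one arm is required.")
  nm <- vapply(model$arms, `[[`, "", "name")
  if (anyDuplicated(nm)) abort("cea_model: arm names must be unique.")
  names(model$arms) <- nm
  for (arm in model$arms) {
    for (comp in arm$regimen) {
      if (!comp$drug %in% model$prices$name) {
        abort(paste0("cea_model: drug `", comp$drug, "` in arm `", arm$name,
                     "` has no price entry."))
      }
      days_on <- comp$days_on_per_cycle
      if (!is.null(days_on) && days_on > model$cycle$cycle_days) {
        abort(paste0("regimen_component: `days_on_per_cycle` (", days_on,
                     ") exceeds the cycle length for drug `", comp$drug, "`."))
      }
    }
  }
  # provisional Weibull laws from published medians when none supplied
  model$arms <- lapply(model$arms, function(arm) {
    if (is.null(arm$pfs_weibull) && !is.null(arm$pfs_median_months)) {
      arm$pfs_weibull <- weibull_params_from_median(arm$pfs_median_months)
    }
    if (is.null(arm$os_weibull) && !is.null(arm$os_median_months)) {
      arm$os_weibull <- weibull_params_from_median(arm$os_median_months)
    }
    arm
  })
  model
}

#' @export
print.cea_model <- function(x, ...) {
  cat(sprintf("<cea_model> %s: %d arms, %d-day cycles, %d-year horizon (%d cycles)\n",
              x$trial, length(x$arms), x$cycle$cycle_days,
              x$cycle$horizon_years, n_cycles(x$cycle)))
  for (arm in x$arms) {
    cat(sprintf("  - %s [%s, %s]: %s\n", arm$name, arm$role, arm$route,
                paste(vapply(arm$regimen, `[[`, "", "drug"), collapse = " + ")))
  }
  invisible(x)
}

#' Load a model configuration from YAML or JSON
#'
#' The configuration schema mirrors the constructor arguments: top-level
#' keys `trial`, `cycle_days`, `horizon_years`, `discount_annual`,
#' `patient`, `wtp`, `psa_iterations`, `seed`, `dsa_cost_range`,
#' `dsa_other_range`, `drug_prices` (name -> pack_price /
#' pack_content_mg), `fixed_costs`, and `arms` (each with `name`, `role`,
#' `route`, `utilities`, `regimen`, optional `pfs_weibull` / `os_weibull`
#' and `pfs_median_months` / `os_median_months`). Omitted optional fields
#' take the documented defaults (discount 3%, WTP 30828, reference
#' patient). Missing mandatory fields and invariant violations raise
#' errors naming the field.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config.
#' @return a validated `cea_model`.
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  model_from_config(cfg)
}

model_from_config <- function(cfg) {
  for (fld in c("trial", "cycle_days", "horizon_years", "arms", "drug_prices")) {
    if (is.null(cfg[[fld]])) abort(paste0("config: mandatory field `", fld, "` is missing."))
  }
  cyc <- cycle_spec(cfg$cycle_days, cfg$horizon_years,
                    cfg$discount_annual %||% 0.03)
  pat <- do.call(patient_profile, cfg$patient %||% list())
  prices <- {
    dp <- cfg$drug_prices
    drug_prices(names(dp),
                vapply(dp, function(x) as.numeric(x$pack_price), 0),
                vapply(dp, function(x) as.numeric(x$pack_content_mg), 0))
  }
  fc <- do.call(fixed_costs, cfg$fixed_costs %||% list())
  cea <- cea_config(wtp = cfg$wtp %||% 30828,
                    psa_iterations = cfg$psa_iterations %||% 1000,
                    seed = cfg$seed %||% 1L,
                    dsa_cost_range = cfg$dsa_cost_range %||% 0.30,
                    dsa_other_range = cfg$dsa_other_range %||% 0.20)
  arms <- lapply(cfg$arms, function(a) {
    if (is.null(a$name)) abort("config: every arm needs a `name`.")
    if (is.null(a$utilities$pfs_on_treatment)) {
      abort(paste0("config: arm `", a$name, "` is missing `utilities$pfs_on_treatment`."))
    }
    regimen <- lapply(a$regimen, function(rc) {
      regimen_component(
        drug = rc$drug, dosing = rc$dosing, dose = rc$dose,
        days_on_per_cycle = rc$days_on_per_cycle,
        max_cycles = rc$max_cycles %||% Inf,
        maintenance = isTRUE(rc$maintenance),
        maintenance_days_on = rc$maintenance_days_on
      )
    })
    wb <- function(x) if (is.null(x)) NULL else weibull_params(x$lambda, x$gamma)
    arm_model(
      name = a$name, regimen = regimen,
      utilities = utility_set(
        pfs_on_treatment = a$utilities$pfs_on_treatment,
        pd = a$utilities$pd %||% 0.70,
        ae_disutility = a$utilities$ae_disutility %||% -0.0731,
        ae_rate_grade3plus = a$utilities$ae_rate_grade3plus %||% 0
      ),
      route = a$route %||% "oral_only",
      pfs_weibull = wb(a$pfs_weibull), os_weibull = wb(a$os_weibull),
      pfs_median_months = a$pfs_median_months,
      os_median_months = a$os_median_months,
      role = a$role %||% "other"
    )
  })
  cea_model(trial = cfg$trial, cycle = cyc, arms = arms, prices = prices,
            costs = fc, patient = pat, cea = cea,
            metadata = cfg$metadata %||% list())
}

#' Serialize a model back to a YAML configuration
#'
#' Round-trips with [load_model_config()]: reloading the written file
#' yields a field-by-field identical model.
#'
#' @param model a `cea_model`.
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    trial = model$trial,
    cycle_days = model$cycle$cycle_days,
    horizon_years = model$cycle$horizon_years,
    discount_annual = model$cycle$discount_annual,
    patient = unclass(model$patient),
    wtp = model$cea$wtp,
    psa_iterations = model$cea$psa_iterations,
    seed = model$cea$seed,
    dsa_cost_range = model$cea$dsa_cost_range,
    dsa_other_range = model$cea$dsa_other_range,
    drug_prices = setNames(
      lapply(seq_len(nrow(model$prices)), function(i) {
        list(pack_price = model$prices$pack_price[i],
             pack_content_mg = model$prices$pack_content_mg[i])
      }),
      model$prices$name
    ),
    fixed_costs = drop_null(unclass(model$costs)),
    arms = lapply(model$arms, function(a) {
      drop_null(list(
        name = a$name, role = a$role, route = a$route,
        pfs_median_months = a$pfs_median_months,
        os_median_months = a$os_median_months,
        pfs_weibull = if (!is.null(a$pfs_weibull)) unclass(a$pfs_weibull),
        os_weibull = if (!is.null(a$os_weibull)) unclass(a$os_weibull),
        utilities = unclass(a$utilities),
        regimen = lapply(a$regimen, function(rc) {
          rc <- unclass(rc)
          if (is.infinite(rc$max_cycles)) rc$max_cycles <- NULL
          drop_null(rc)
        })
      ))
    }),
    metadata = if (length(model$metadata)) model$metadata
  )
  cfg$arms <- unname(cfg$arms)
  yaml::write_yaml(drop_null(cfg), path, precision = 12)
  invisible(path)
}

drop_null <- function(x) x[!vapply(x, is.null, TRUE)]

#' Packaged trial configuration fixtures
#'
#' Six first-line EGFR-mutant NSCLC trials ship as ready-made model
#' configurations with the published cycle lengths, regimens, unit prices,
#' utilities, grade >= 3 adverse-event rates and median PFS/OS:
#' ARCHER 1050 (dacomitinib vs gefitinib), FLAURA (osimertinib vs
#' first-generation EGFR-TKI), JO25567 and NEJ026 (bevacizumab + erlotinib
#' vs erlotinib), NEJ009 (gefitinib + carboplatin + pemetrexed vs
#' gefitinib) and NCT02148380 (pemetrexed + carboplatin + gefitinib vs
#' chemotherapy vs gefitinib).
#'
#' @return `trial_fixtures()`: character vector of fixture names.
#' @export
trial_fixtures <- function() {
  c("archer1050", "flaura", "jo25567", "nej026", "nej009", "nct02148380")
}

#' @rdname trial_fixtures
#' @param trial fixture name, one of `trial_fixtures()`.
#' @param horizon_years optionally override the config horizon (5 or 10).
#' @return `load_trial()`: a validated `cea_model`.
#' @export
load_trial <- function(trial, horizon_years = NULL) {
  trial <- tolower(trial)
  if (!trial %in% trial_fixtures()) {
    abort(paste0("unknown trial fixture `", trial, "`; available: ",
                 paste(trial_fixtures(), collapse = ", ")))
  }
  path <- system.file("extdata", "trials", paste0(trial, ".yaml"),
                      package = "egfrcea", mustWork = TRUE)
  model <- load_model_config(path)
  if (!is.null(horizon_years)) {
    model$cycle$horizon_years <- as.integer(horizon_years)
    model$cycle <- validate_cycle_spec(model$cycle)
  }
  model
}
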
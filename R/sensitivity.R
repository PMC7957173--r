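#' Registry of sensitivity-analysis parameters for a model
#'
#' Enumerates every varied parameter with its base value and one-way
#' bounds: unit drug prices and the fixed cost blocks (cost class, default
#' +/- 30%), per-arm progression-free utilities, the shared PD utility and
#' the AE disutility magnitude (utility class, +/- 20%, capped at 1), and
#' per-arm grade >= 3 AE rates and first-cycle PFS/OS event probabilities
#' (probability class, +/- 20%, capped at 1). Each parameter is varied
#' independently.
#'
#' @param model a `cea_model`.
#' @param cost_range,other_range one-way ranges; defaults from the model's
#'   [cea_config()].
#' @return a tibble (`parameter`, `type`, `base`, `low`, `high`).
#' @export
cea_parameters <- function(model, cost_range = model$cea$dsa_cost_range,
                           other_range = model$cea$dsa_other_range) {
  rows <- list()
  add <- function(parameter, type, base) {
    rng <- if (type == "cost") cost_range else other_range
    lo <- base * (1 - rng)
    hi <- base * (1 + rng)
    if (type != "cost") hi <- min(hi, 1)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      parameter = parameter, type = type, base = base, low = lo, high = hi)
  }
  for (i in seq_len(nrow(model$prices))) {
    add(paste0("price.", model$prices$name[i]), "cost", model$prices$pack_price[i])
  }
  for (fld in c("follow_up_per_cycle", "supportive_care_per_cycle",
                "ae_cost_per_cycle", "pd_cost_per_week",
                "terminal_care_per_week")) {
    add(paste0("fixed.", fld), "cost", model$costs[[fld]])
  }
  u <- cycle_months(model$cycle)
  for (arm in model$arms) {
    add(paste0("utility.", arm$name, ".pfs"), "utility",
        arm$utilities$pfs_on_treatment)
    add(paste0("ae_rate.", arm$name), "probability",
        arm$utilities$ae_rate_grade3plus)
    p1 <- function(w) 1 - exp(-w$lambda * u^w$gamma)
    add(paste0("prob.", arm$name, ".pfs"), "probability", p1(arm$pfs_weibull))
    add(paste0("prob.", arm$name, ".os"), "probability", p1(arm$os_weibull))
  }
  add("utility.pd", "utility", model$arms[[1]]$utilities$pd)
  add("utility.ae_disutility_magnitude", "utility",
      abs(model$arms[[1]]$utilities$ae_disutility))
  dplyr::bind_rows(rows)
}

#' Set one registered parameter to a new value
#'
#' @param model a `cea_model`.
#' @param parameter registry name (see [cea_parameters()]).
#' @param value the new value.
#' @return the modified model.
#' @export
set_cea_parameter <- function(model, parameter, value) {
  parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  kind <- parts[1]
  u <- cycle_months(model$cycle)
  lambda_from_p1 <- function(p1, gamma) -log(1 - min(p1, 1 - 1e-12)) / u^gamma
  if (kind == "price") {
    drug <- paste(parts[-1], collapse = ".")
    idx <- match(drug, model$prices$name)
    if (is.na(idx)) abort(paste0("unknown price parameter `", parameter, "`."))
    model$prices$pack_price[idx] <- value
  } else if (kind == "fixed") {
    fld <- parts[2]
    if (!fld %in% names(model$costs)) abort(paste0("unknown fixed-cost parameter `", parameter, "`."))
    model$costs[[fld]] <- value
  } else if (kind == "utility" && parts[2] == "pd") {
    model$arms <- lapply(model$arms, function(a) { a$utilities$pd <- value; a })
  } else if (kind == "utility" && parts[2] == "ae_disutility_magnitude") {
    model$arms <- lapply(model$arms, function(a) {
      a$utilities$ae_disutility <- -abs(value); a
    })
  } else if (kind == "utility") {
    arm <- parts[2]
    if (!arm %in% names(model$arms)) abort(paste0("unknown arm in `", parameter, "`."))
    model$arms[[arm]]$utilities$pfs_on_treatment <- min(value, 1)
  } else if (kind == "ae_rate") {
    arm <- parts[2]
    if (!arm %in% names(model$arms)) abort(paste0("unknown arm in `", parameter, "`."))
    model$arms[[arm]]$utilities$ae_rate_grade3plus <- min(value, 1)
  } else if (kind == "prob") {
    arm <- parts[2]; endpoint <- parts[3]
    if (!arm %in% names(model$arms) || !endpoint %in% c("pfs", "os")) {
      abort(paste0("unknown probability parameter `", parameter, "`."))
    }
    fld <- paste0(endpoint, "_weibull")
    wp <- model$arms[[arm]][[fld]]
    model$arms[[arm]][[fld]] <- weibull_params(
      lambda_from_p1(value, wp$gamma), wp$gamma)
  } else {
    abort(paste0("unknown parameter `", parameter, "`."))
  }
  model
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full model at each parameter's low and high bound, all
#' other parameters held at base, and records the outcome at both bounds.
#' The outcome is the treatment-vs-control ICER by default, or the
#' incremental net monetary benefit with `metric = "nb"` (also used
#' automatically when the base-case IE is zero).
#'
#' @param model a `cea_model`.
#' @param treat,ctrl arm names.
#' @param wtp threshold for the net-benefit metric.
#' @param parameters registry tibble; default [cea_parameters()].
#' @param metric `"icer"` or `"nb"` (incremental net benefit).
#' @param half_cycle passed to [run_cohort()].
#' @return a tibble of class `tornado` (`parameter`, `type`, `base`,
#'   `low`, `high`, `low_result`, `high_result`, `width`), sorted by
#'   descending bar width. Attribute `base_result` holds the base-case
#'   outcome.
#' @export
one_way_sensitivity <- function(model, treat, ctrl, wtp = model$cea$wtp,
                                parameters = cea_parameters(model),
                                metric = c("icer", "nb"),
                                half_cycle = FALSE) {
  metric <- match.arg(metric)
  outcome <- function(m) {
    s <- run_model(m, half_cycle = half_cycle)$summary
    tr <- s[s$arm == treat, ]; ct <- s[s$arm == ctrl, ]
    cmp <- compare_arms(list(arm = treat, cost = tr$cost, qaly = tr$qaly),
                        list(arm = ctrl, cost = ct$cost, qaly = ct$qaly), wtp)
    if (metric == "icer") cmp$icer else cmp$nb_treat - cmp$nb_ctrl
  }
  base_result <- outcome(model)
  res <- purrr::pmap_dfr(parameters, function(parameter, type, base, low, high) {
    lo <- outcome(set_cea_parameter(model, parameter, low))
    hi <- outcome(set_cea_parameter(model, parameter, high))
    tibble::tibble(parameter = parameter, type = type, base = base,
                   low = low, high = high,
                   low_result = lo, high_result = hi,
                   width = abs(hi - lo))
  })
  res <- dplyr::arrange(res, dplyr::desc(.data$width))
  structure(res, base_result = base_result, metric = metric,
            class = c("tornado", class(res)))
}

# gamma draws with mean m and central-95% half-width `range` * m
sample_gamma <- function(n, m, range) {
  s <- range * m / 1.96
  if (m <= 0 || s <= 0) return(rep(m, n))
  shape <- (m / s)^2
  rgamma(n, shape = shape, rate = shape / m)
}

# beta draws with mean m and sd `range` * m / 1.96, variance capped to the
# feasible region of the (0, 1) support
sample_beta <- function(n, m, range) {
  s <- range * m / 1.96
  if (m <= 0 || s <= 0) return(rep(m, n))
  if (m >= 1) return(rep(1, n))
  v <- min(s^2, 0.9 * m * (1 - m))
  a <- m * (m * (1 - m) / v - 1)
  b <- (1 - m) / m * a
  rbeta(n, a, b)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation over the registered parameters: every cost
#' parameter is drawn from a gamma distribution and every utility and
#' probability parameter from a beta distribution, each moment-matched so
#' its mean is the base value and its central 95% interval spans the
#' one-way range (costs +/- 30%, others +/- 20% by default). The full
#' model is evaluated for every draw.
#'
#' @param model a `cea_model`.
#' @param n iterations; default the model's `psa_iterations` (1000).
#' @param seed integer seed; default the model's configured seed.
#' @param parameters registry tibble; default [cea_parameters()].
#' @param cost_range,other_range distribution spreads (set to 0 to
#'   collapse the PSA onto the deterministic base case).
#' @param half_cycle passed to [run_cohort()].
#' @return a tibble of class `psa_draws`: one row per draw with the
#'   sampled parameter columns followed by `cost_<arm>` / `qaly_<arm>`
#'   for every arm. Attributes: `seed`, `base` (base-case summary).
#' @export
psa_run <- function(model, n = model$cea$psa_iterations,
                    seed = model$cea$seed,
                    parameters = cea_parameters(model),
                    cost_range = model$cea$dsa_cost_range,
                    other_range = model$cea$dsa_other_range,
                    half_cycle = FALSE) {
  set.seed(seed)
  draws <- purrr::pmap(parameters, function(parameter, type, base, low, high) {
    if (type == "cost") sample_gamma(n, base, cost_range)
    else sample_beta(n, base, other_range)
  })
  names(draws) <- parameters$parameter
  draw_tbl <- tibble::as_tibble(draws)

  base_summary <- run_model(model, half_cycle = half_cycle)$summary
  arm_names <- base_summary$arm
  res <- matrix(0, nrow = n, ncol = 2 * length(arm_names))
  colnames(res) <- c(paste0("cost_", arm_names), paste0("qaly_", arm_names))
  for (i in seq_len(n)) {
    m_i <- model
    for (p in parameters$parameter) {
      m_i <- set_cea_parameter(m_i, p, draw_tbl[[p]][i])
    }
    s <- run_model(m_i, half_cycle = half_cycle)$summary
    res[i, ] <- c(s$cost, s$qaly)
  }
  out <- dplyr::bind_cols(tibble::tibble(draw = seq_len(n)), draw_tbl,
                          tibble::as_tibble(res))
  structure(out, seed = seed, base = base_summary,
            class = c("psa_draws", class(out)))
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA draws in which
#' the treatment arm's net monetary benefit strictly exceeds the control
#' arm's (and vice versa; at ties neither side is counted, so the two
#' curves sum to 1 up to the tied fraction).
#'
#' @param draws a `psa_draws` tibble.
#' @param treat,ctrl arm names present in the draws.
#' @param wtp_grid nondecreasing WTP grid; default 0 to 2,000,000 USD/QALY
#'   in 201 points.
#' @return a tibble of class `ceac` (`wtp`, `prob_treat`, `prob_ctrl`).
#' @export
ceac <- function(draws, treat, ctrl,
                 wtp_grid = seq(0, 2e6, length.out = 201)) {
  if (nrow(draws) == 0) abort("`draws` must contain at least one draw.")
  if (is.unsorted(wtp_grid)) abort("`wtp_grid` must be nondecreasing.")
  ct <- draws[[paste0("cost_", treat)]]; qt <- draws[[paste0("qaly_", treat)]]
  cc <- draws[[paste0("cost_", ctrl)]]; qc <- draws[[paste0("qaly_", ctrl)]]
  if (is.null(ct) || is.null(cc)) abort("arm not found in PSA draws.")
  res <- vapply(wtp_grid, function(w) {
    nbt <- qt * w - ct
    nbc <- qc * w - cc
    c(mean(nbt > nbc), mean(nbc > nbt))
  }, c(0, 0))
  out <- tibble::tibble(wtp = wtp_grid, prob_treat = res[1, ],
                        prob_ctrl = res[2, ])
  structure(out, treat = treat, ctrl = ctrl,
            class = c("ceac", class(out)))
}

#' Incremental cost/effect scatter from PSA draws
#'
#' @param draws a `psa_draws` tibble.
#' @param treat,ctrl arm names.
#' @return tibble (`draw`, `ic`, `ie`).
#' @export
psa_increments <- function(draws, treat, ctrl) {
  tibble::tibble(
    draw = draws$draw,
    ic = draws[[paste0("cost_", treat)]] - draws[[paste0("cost_", ctrl)]],
    ie = draws[[paste0("qaly_", treat)]] - draws[[paste0("qaly_", ctrl)]]
  )
}
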
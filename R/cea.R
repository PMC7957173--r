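#' Pairwise cost-effectiveness comparison
#'
#' Computes the incremental cost `IC = cost_treat - cost_ctrl`,
#' incremental effect `IE = qaly_treat - qaly_ctrl`, the incremental
#' cost-effectiveness ratio `ICER = IC / IE`, per-arm average
#' cost-effectiveness ratios `ACER = cost / QALY` and net monetary
#' benefits `NB = QALY x WTP - cost`.
#'
#' A negative ICER is reported with its sign plus a `dominance` annotation
#' (`"treatment dominates"` when cheaper and more effective,
#' `"treatment dominated"` when dearer and less effective, otherwise
#' `"none"`), since the bare sign does not identify the quadrant. When
#' `IE == 0` the ICER is undefined (`NA`) and flagged.
#'
#' @param treat,ctrl arm results: lists or one-row data frames with
#'   fields/columns `cost` (USD) and `qaly` (> 0), optionally `arm`.
#' @param wtp willingness-to-pay threshold, USD/QALY.
#' @return an object of class `cea_result`; see [tidy.cea_result()].
#' @export
#' @examples
#' compare_arms(list(cost = 10000, qaly = 1), list(cost = 5000, qaly = 0.5))
compare_arms <- function(treat, ctrl, wtp = 30828) {
  treat <- as.list(treat); ctrl <- as.list(ctrl)
  for (side in list(treat, ctrl)) {
    if (is.null(side$cost) || is.null(side$qaly)) {
      abort("arm results need `cost` and `qaly` fields.")
    }
    if (side$qaly <= 0) abort("arm QALY must be positive.")
  }
  ic <- treat$cost - ctrl$cost
  ie <- treat$qaly - ctrl$qaly
  icer <- if (ie == 0) NA_real_ else ic / ie
  dominance <- if (ie > 0 && ic < 0) {
    "treatment dominates"
  } else if (ie < 0 && ic > 0) {
    "treatment dominated"
  } else {
    "none"
  }
  structure(list(
    treat_name = treat$arm %||% "treatment",
    ctrl_name = ctrl$arm %||% "control",
    cost_treat = treat$cost, cost_ctrl = ctrl$cost,
    qaly_treat = treat$qaly, qaly_ctrl = ctrl$qaly,
    ic = ic, ie = ie, icer = icer, icer_defined = ie != 0,
    dominance = dominance,
    acer_treat = treat$cost / treat$qaly,
    acer_ctrl = ctrl$cost / ctrl$qaly,
    nb_treat = treat$qaly * wtp - treat$cost,
    nb_ctrl = ctrl$qaly * wtp - ctrl$cost,
    wtp = wtp
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s vs %s (WTP %.0f/QALY)\n",
              x$treat_name, x$ctrl_name, x$wtp))
  cat(sprintf("  IC %.2f, IE %.4f, ICER %s\n", x$ic, x$ie,
              if (x$icer_defined) sprintf("%.2f", x$icer) else "undefined (IE = 0)"))
  if (x$dominance != "none") cat("  dominance:", x$dominance, "\n")
  cat(sprintf("  ACER %.2f vs %.2f; NB %.2f vs %.2f\n",
              x$acer_treat, x$acer_ctrl, x$nb_treat, x$nb_ctrl))
  invisible(x)
}

#' @describeIn compare_arms one-row tibble of every comparison statistic.
#' @param x a `cea_result`.
#' @param ... unused.
#' @export
tidy.cea_result <- function(x, ...) {
  tibble::tibble(
    treat = x$treat_name, ctrl = x$ctrl_name,
    cost_treat = x$cost_treat, cost_ctrl = x$cost_ctrl,
    qaly_treat = x$qaly_treat, qaly_ctrl = x$qaly_ctrl,
    ic = x$ic, ie = x$ie, icer = x$icer,
    acer_treat = x$acer_treat, acer_ctrl = x$acer_ctrl,
    nb_treat = x$nb_treat, nb_ctrl = x$nb_ctrl,
    dominance = x$dominance, wtp = x$wtp
  )
}

#' Rank arms by net monetary benefit
#'
#' @param results tibble with columns `arm`, `cost`, `qaly` (as from
#'   [run_model()]'s `summary`).
#' @param wtp willingness-to-pay threshold.
#' @return the tibble with an `nb` column, sorted by descending net
#'   benefit; ties broken by lower cost, then arm name.
#' @export
rank_by_net_benefit <- function(results, wtp = 30828) {
  if (nrow(results) == 0) abort("`results` must be non-empty.")
  results |>
    dplyr::mutate(nb = .data$qaly * wtp - .data$cost) |>
    dplyr::arrange(dplyr::desc(.data$nb), .data$cost, .data$arm)
}

#' Drug-cost reduction needed to reach the WTP threshold
#'
#' For a comparison with a positive ICER above the threshold, finds the
#' smallest fraction `f` in \[0, 1\] such that scaling the treatment
#' arm's drug acquisition costs by `(1 - f)` — all other costs unchanged —
#' brings the ICER down to the willingness-to-pay threshold. Solved by
#' bisection to `|ICER(f) - wtp| <= tol` (default 0.01 USD/QALY).
#'
#' @param model a `cea_model`.
#' @param treat,ctrl arm names in `model`.
#' @param wtp threshold; default the model's configured WTP.
#' @param tol ICER tolerance at the solution, USD/QALY.
#' @param half_cycle passed to [run_cohort()].
#' @return the fraction `f`; 0 when the base-case ICER is already at or
#'   below the threshold. If even `f = 1` leaves the ICER above the
#'   threshold the result carries attribute `unattainable = TRUE`.
#' @export
cost_reduction_to_threshold <- function(model, treat, ctrl,
                                        wtp = model$cea$wtp, tol = 0.01,
                                        half_cycle = FALSE) {
  icer_at <- function(f) {
    res <- run_model(model, half_cycle = half_cycle,
                     drug_cost_multipliers = setNames(1 - f, treat))
    s <- res$summary
    tr <- s[s$arm == treat, ]; ct <- s[s$arm == ctrl, ]
    cmp <- compare_arms(list(arm = treat, cost = tr$cost, qaly = tr$qaly),
                        list(arm = ctrl, cost = ct$cost, qaly = ct$qaly),
                        wtp = wtp)
    if (!cmp$icer_defined) abort("incremental effect is zero; ICER undefined.")
    cmp
  }
  base <- icer_at(0)
  if (base$ie <= 0) abort("cost_reduction_to_threshold requires a positive incremental effect.")
  if (base$icer <= wtp) return(0)
  full <- icer_at(1)
  if (full$icer > wtp + tol) {
    warn("even a 100% drug-cost reduction does not reach the threshold.")
    return(structure(1, unattainable = TRUE))
  }
  lo <- 0; hi <- 1
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    ic_mid <- icer_at(mid)$icer
    if (abs(ic_mid - wtp) <= tol) return(mid)
    if (ic_mid > wtp) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Results table across horizons, mirroring the per-trial layout
#'
#' Runs the model at each horizon and assembles rows `cost`, `QALY`,
#' `ACER`, `net benefit` per arm plus `IC`, `IE`, `ICER` for each
#' treatment-vs-control pair.
#'
#' @param model a `cea_model`.
#' @param treat,ctrl arm names; default: the arms with roles `treatment`
#'   and `control`.
#' @param horizons integer vector of horizons in years.
#' @param half_cycle passed to [run_cohort()].
#' @return a tibble with columns `horizon_years`, `arm`, `cost`, `qaly`,
#'   `acer`, `nb`, plus comparison columns `ic`, `ie`, `icer` attached to
#'   the treatment row.
#' @export
cea_table <- function(model, treat = NULL, ctrl = NULL, horizons = c(5, 10),
                      half_cycle = FALSE) {
  roles <- vapply(model$arms, `[[`, "", "role")
  treat <- treat %||% names(model$arms)[match("treatment", roles)]
  ctrl <- ctrl %||% names(model$arms)[match("control", roles)]
  if (is.na(treat) || is.na(ctrl)) {
    abort("specify `treat` and `ctrl` (no arms carry treatment/control roles).")
  }
  purrr::map_dfr(horizons, function(h) {
    res <- run_model(model, horizon_years = h, half_cycle = half_cycle)
    s <- res$summary |>
      dplyr::mutate(horizon_years = h,
                    acer = .data$cost / .data$qaly,
                    nb = .data$qaly * model$cea$wtp - .data$cost,
                    ic = NA_real_, ie = NA_real_, icer = NA_real_)
    tr <- s$arm == treat; ct <- s$arm == ctrl
    s$ic[tr] <- s$cost[tr] - s$cost[ct]
    s$ie[tr] <- s$qaly[tr] - s$qaly[ct]
    s$icer[tr] <- if (s$ie[tr] == 0) NA_real_ else s$ic[tr] / s$ie[tr]
    dplyr::relocate(s, "horizon_years")
  })
}
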
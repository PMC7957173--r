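#' Simulate a digitized Kaplan-Meier curve from a known Weibull law
#'
#' Emulates the digitization of a published survival figure: individual
#' event times are drawn from `S(t) = exp(-lambda t^gamma)`, subjected to
#' independent uniform right-censoring, summarised by the product-limit
#' estimator, and read off at an evenly spaced time grid — the synthetic
#' analogue of clicking points off a printed curve.
#'
#' @param params a `weibull_params` (true law).
#' @param n number of patients (>= 10; default 300).
#' @param censor_rate fraction of patients subject to uniform
#'   administrative censoring on \[0, `horizon_months`\] (default 0.20).
#' @param n_points number of digitized grid points (>= 5; default 30).
#' @param horizon_months follow-up window (default 60).
#' @param seed integer seed; same seed, same curve.
#' @param endpoint,arm labels attached to the curve.
#' @return a validated `km_curve`.
#' @export
#' @examples
#' simulate_km_curve(weibull_params(0.03, 1.2), n = 100, seed = 1)
simulate_km_curve <- function(params, n = 300, censor_rate = 0.2,
                              n_points = 30, horizon_months = 60,
                              seed = 1L, endpoint = "PFS", arm = NULL) {
  if (n < 10) abort("`n` must be at least 10.")
  if (n_points < 5) abort("`n_points` must be at least 5.")
  if (censor_rate < 0 || censor_rate >= 1) abort("`censor_rate` must lie in [0, 1).")
  set.seed(seed)
  event <- rweibull(n, shape = params$gamma,
                    scale = params$lambda^(-1 / params$gamma))
  km_from_times(event, n, censor_rate, n_points, horizon_months,
                endpoint = endpoint, arm = arm)
}

# shared digitization path: censor, product-limit estimate, grid read-off
km_from_times <- function(event, n, censor_rate, n_points, horizon_months,
                          endpoint, arm, censor_time = NULL) {
  if (is.null(censor_time)) {
    censor_time <- ifelse(runif(n) < censor_rate,
                          runif(n, 0, horizon_months), Inf)
  }
  obs <- pmin(event, censor_time, horizon_months)
  status <- as.integer(event <= pmin(censor_time, horizon_months))
  fit <- survival::survfit(survival::Surv(obs, status) ~ 1)
  grid <- seq(0, min(max(obs), horizon_months), length.out = n_points + 1)[-1]
  sv <- summary(fit, times = grid, extend = TRUE)$surv
  km_curve(c(0, grid), c(1, sv), endpoint = endpoint, arm = arm)
}

#' Simulate paired PFS and OS curves from one synthetic cohort
#'
#' Progression-free survival events (progression or death) and deaths are
#' generated for the same patients with a comonotone coupling, so each
#' patient's PFS event time never exceeds their death time provided the
#' marginal survivor functions are ordered (`S_OS >= S_PFS` everywhere);
#' the ordering is checked over the follow-up window and violated
#' parameters raise an error. Both curves share one censoring time per
#' patient.
#'
#' @param truth_pfs,truth_os true `weibull_params` for the PFS and OS
#'   marginals.
#' @inheritParams simulate_km_curve
#' @return list with `pfs` and `os` `km_curve`s.
#' @export
make_paired_arm <- function(truth_pfs, truth_os, n = 300, censor_rate = 0.2,
                            n_points = 30, horizon_months = 60, seed = 1L,
                            arm = NULL) {
  if (n < 10) abort("`n` must be at least 10.")
  tchk <- seq(1e-6, horizon_months * 2, length.out = 400)
  if (any(weibull_survivor(tchk, truth_os$lambda, truth_os$gamma) <
          weibull_survivor(tchk, truth_pfs$lambda, truth_pfs$gamma) - 1e-12)) {
    abort("OS survivor must dominate PFS survivor at every time; the supplied parameters violate the ordering.")
  }
  set.seed(seed)
  uu <- runif(n)
  inv <- function(w) (-log(uu) / w$lambda)^(1 / w$gamma)
  t_pfs <- inv(truth_pfs)
  t_os <- pmax(inv(truth_os), t_pfs)  # death never precedes the PFS event
  censor_time <- ifelse(runif(n) < censor_rate,
                        runif(n, 0, horizon_months), Inf)
  list(
    pfs = km_from_times(t_pfs, n, censor_rate, n_points, horizon_months,
                        endpoint = "PFS", arm = arm,
                        censor_time = censor_time),
    os = km_from_times(t_os, n, censor_rate, n_points, horizon_months,
                       endpoint = "OS", arm = arm,
                       censor_time = censor_time)
  )
}

#' Build a full synthetic reference fixture for a packaged trial
#'
#' Loads the packaged trial configuration (published cycle length,
#' regimens, prices, utilities) and generates synthetic digitized KM
#' curves for every arm whose Weibull laws have the trial's published
#' median PFS/OS by construction (shape 1.3 by default — a mild
#' increasing hazard typical of advanced-NSCLC survival — with the scale
#' solved from the median).
#'
#' @param trial one of [trial_fixtures()].
#' @param seed integer seed.
#' @inheritParams simulate_km_curve
#' @param horizon_months follow-up window for the simulated curves;
#'   default 1.5x the longest published OS median.
#' @return list with `model` (the `cea_model`, arms carrying the *true*
#'   median-derived laws), `curves` (per arm: `pfs`, `os`), and `truth`
#'   (tibble `arm`, `endpoint`, `lambda`, `gamma`, `median`).
#' @export
make_reference_fixture <- function(trial, seed = 1L, n = 300,
                                   censor_rate = 0.2, n_points = 30,
                                   horizon_months = NULL) {
  model <- load_trial(trial)
  os_meds <- vapply(model$arms, function(a) a$os_median_months %||% NA_real_, 0)
  horizon_months <- horizon_months %||% (1.5 * max(os_meds, na.rm = TRUE))
  curves <- list()
  truth <- list()
  for (i in seq_along(model$arms)) {
    arm <- model$arms[[i]]
    pr <- make_paired_arm(arm$pfs_weibull, arm$os_weibull, n = n,
                          censor_rate = censor_rate, n_points = n_points,
                          horizon_months = horizon_months,
                          seed = seed + i, arm = arm$name)
    curves[[arm$name]] <- pr
    arm_name <- arm$name
    wp <- arm$pfs_weibull; wo <- arm$os_weibull
    truth[[arm$name]] <- tibble::tibble(
      arm = arm_name, endpoint = c("PFS", "OS"),
      lambda = c(wp$lambda, wo$lambda),
      gamma = c(wp$gamma, wo$gamma),
      median = c(weibull_median(wp$lambda, wp$gamma),
                 weibull_median(wo$lambda, wo$gamma))
    )
  }
  list(model = model, curves = curves, truth = dplyr::bind_rows(truth))
}

#' Calibrate a model's transition laws from KM curves
#'
#' Fits both endpoints of every arm and attaches the fitted Weibull laws,
#' replacing any median-derived provisional parameters.
#'
#' @param model a `cea_model`.
#' @param curves named list (per arm name) of lists with `pfs` and `os`
#'   `km_curve`s, as produced by [make_reference_fixture()].
#' @param method passed to [fit_weibull()].
#' @return the model with fitted laws, plus attribute `fits` (tibble as
#'   from [fit_parameter_table()]).
#' @export
calibrate_model <- function(model, curves, method = "ols") {
  fits <- list()
  for (arm_name in names(curves)) {
    if (!arm_name %in% names(model$arms)) {
      abort(paste0("curves provided for unknown arm `", arm_name, "`."))
    }
    fp <- fit_weibull(curves[[arm_name]]$pfs, method = method)
    fo <- fit_weibull(curves[[arm_name]]$os, method = method)
    model$arms[[arm_name]]$pfs_weibull <- weibull_params(fp$lambda, fp$gamma)
    model$arms[[arm_name]]$os_weibull <- weibull_params(fo$lambda, fo$gamma)
    fits[[arm_name]] <- tibble::tibble(
      arm = arm_name, endpoint = c("PFS", "OS"),
      lambda = c(fp$lambda, fo$lambda), gamma = c(fp$gamma, fo$gamma),
      r_squared = c(fp$r_squared, fo$r_squared))
  }
  attr(model, "fits") <- dplyr::bind_rows(fits)
  model
}
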
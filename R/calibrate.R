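#' Fit a Weibull survivor function to a digitized KM curve
#'
#' The default estimator is ordinary least squares on the linearisation
#' `ln(-ln S(t)) = ln(lambda) + gamma * ln(t)`, the standard approach for
#' curves digitized from published figures. Only interior points are used:
#' `t > 0` and `0 < S(t) < 1`, with points at `S <= 0.01` dropped because
#' the double-log transform is unstable there.
#'
#' An alternative `method = "mle"` reconstructs pseudo-individual event
#' times from the survival drops (assuming `n_pseudo` patients at risk at
#' time zero) and fits a parametric Weibull by maximum likelihood through
#' [survival::survreg()]. OLS is the default and the reference path.
#'
#' @param curve a validated `km_curve` (or data frame with `time`,
#'   `survival`).
#' @param method `"ols"` (default) or `"mle"`.
#' @param n_pseudo pseudo-cohort size for `method = "mle"`.
#' @return an object of class `weibull_fit`: a list with `lambda`, `gamma`,
#'   `r_squared` (of the linearised fit), `n_points`, `method`, `endpoint`,
#'   `arm`. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' tt <- seq(2, 40, by = 2)
#' cv <- km_curve(c(0, tt), c(1, exp(-0.03 * tt^1.2)))
#' fit_weibull(cv)
fit_weibull <- function(curve, method = c("ols", "mle"), n_pseudo = 200) {
  method <- match.arg(method)
  curve <- validate_km_curve(curve)
  usable <- curve$time > 0 & curve$survival > 0.01 & curve$survival < 1
  if (sum(usable) < 2) {
    abort("need at least 2 interior KM points with survival in (0.01, 1) to fit.")
  }
  tt <- curve$time[usable]
  ss <- curve$survival[usable]
  x <- log(tt)
  y <- log(-log(ss))
  ls <- stats::lm.fit(cbind(1, x), y)
  gamma_hat <- ls$coefficients[2]
  lambda_hat <- exp(ls$coefficients[1])
  ssr <- sum(ls$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1

  if (method == "mle") {
    ipd <- reconstruct_pseudo_ipd(curve, n_pseudo)
    sr <- survival::survreg(survival::Surv(ipd$time, ipd$status) ~ 1,
                            dist = "weibull")
    # survreg: S(t) = exp(-(t / exp(intercept))^(1/scale))
    gamma_hat <- 1 / sr$scale
    lambda_hat <- exp(-gamma_hat * unname(stats::coef(sr)[1]))
  }

  structure(
    list(lambda = unname(lambda_hat), gamma = unname(gamma_hat),
         r_squared = r2, n_points = sum(usable), method = method,
         endpoint = attr(curve, "endpoint"), arm = attr(curve, "arm")),
    class = c("weibull_fit", "weibull_params")
  )
}

# Spread the survival drop across each digitized interval as pseudo event
# times at the interval midpoint; remaining survivors censored at the last
# digitized time.
reconstruct_pseudo_ipd <- function(curve, n_pseudo) {
  drops <- -diff(curve$survival)
  mids <- (curve$time[-1] + curve$time[-nrow(curve)]) / 2
  n_events <- round(drops * n_pseudo)
  times <- rep(mids, n_events)
  n_cens <- n_pseudo - sum(n_events)
  data.frame(
    time = c(times, rep(max(curve$time), max(0, n_cens))),
    status = c(rep(1, length(times)), rep(0, max(0, n_cens)))
  )
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit (%s): lambda = %.6g, gamma = %.4f, R^2 = %.4f (%d points)\n",
              x$method, x$lambda, x$gamma, x$r_squared, x$n_points))
  cat(sprintf("  implied median: %.2f months\n", weibull_median(x$lambda, x$gamma)))
  invisible(x)
}

#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(term = c("lambda", "gamma"),
                 estimate = c(x$lambda, x$gamma))
}

#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, gamma = x$gamma,
                 r.squared = x$r_squared, n.points = x$n_points,
                 median = weibull_median(x$lambda, x$gamma),
                 method = x$method)
}

#' Per-cycle transition schedule from a Weibull law
#'
#' Evaluates the conditional per-cycle event probability
#' [weibull_transition_prob()] at the end of every model cycle from 1 to
#' `floor(horizon / u)`.
#'
#' @param params a `weibull_params` (or `weibull_fit`).
#' @param spec a `cycle_spec` (see [cycle_spec()]).
#' @return a tibble with columns `cycle`, `time_months`, `p_event`.
#' @export
build_transition_schedule <- function(params, spec) {
  spec <- validate_cycle_spec(spec)
  u <- cycle_months(spec)
  n <- n_cycles(spec)
  k <- seq_len(n)
  tibble::tibble(
    cycle = k,
    time_months = k * u,
    p_event = weibull_transition_prob(params, t = k * u, u = u)
  )
}

#' Fit both endpoints of several arms and tabulate the parameters
#'
#' Convenience wrapper producing the transition-parameter table layout
#' (`arm`, `endpoint`, `lambda`, `gamma`, `r_squared`), one row per fitted
#' curve, so a published parameter table can be swapped in for fitting.
#'
#' @param curves a list of `km_curve` objects (arm/endpoint attributes set).
#' @param method passed to [fit_weibull()].
#' @return a tibble, one row per curve.
#' @export
fit_parameter_table <- function(curves, method = "ols") {
  purrr::map_dfr(curves, function(cv) {
    ft <- fit_weibull(cv, method = method)
    tibble::tibble(arm = ft$arm %||% NA_character_, endpoint = ft$endpoint,
                   lambda = ft$lambda, gamma = ft$gamma,
                   r_squared = ft$r_squared)
  })
}

#' Write / read a fitted transition-parameter table
#'
#' Tab-delimited with a header line; columns
#' `arm endpoint lambda gamma r_squared`.
#'
#' @param params_table a tibble as returned by [fit_parameter_table()].
#' @param path file path.
#' @return `path` (write) or the tibble (read).
#' @export
write_parameter_table <- function(params_table, path) {
  write.table(params_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  tibble::as_tibble(read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE))
}
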
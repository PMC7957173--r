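#' Weibull survivor function S(t) = exp(-lambda * t^gamma)
#'
#' The two-parameter Weibull survivor law in the rate parameterisation used
#' throughout the package: `lambda` is the scale (per month^gamma) and
#' `gamma` the shape. `gamma = 1` reduces to the exponential.
#'
#' @param t time in months (vectorised, `t >= 0`).
#' @param lambda scale parameter, `> 0`.
#' @param gamma shape parameter, `> 0`.
#' @return survival fractions in (0, 1].
#' @export
#' @examples
#' weibull_survivor(c(0, 6, 12), lambda = 0.03, gamma = 1.2)
weibull_survivor <- function(t, lambda, gamma) {
  check_weibull_params(lambda, gamma)
  stopifnot(all(t >= 0))
  exp(-lambda * t^gamma)
}

#' Median survival time of a Weibull law
#'
#' `(ln 2 / lambda)^(1/gamma)`, in months.
#'
#' @inheritParams weibull_survivor
#' @return median time in months.
#' @export
weibull_median <- function(lambda, gamma) {
  check_weibull_params(lambda, gamma)
  (log(2) / lambda)^(1 / gamma)
}

#' Solve the Weibull scale from a median survival time
#'
#' Given a published median (months) and an assumed shape, returns the
#' scale `lambda = ln 2 / median^gamma` so that `S(median) = 1/2`.
#'
#' @param median_months median survival in months, `> 0`.
#' @param gamma assumed shape parameter, `> 0`.
#' @return a `weibull_params` list with elements `lambda` and `gamma`.
#' @export
#' @examples
#' weibull_params_from_median(18.9, gamma = 1.3)
weibull_params_from_median <- function(median_months, gamma = 1.3) {
  stopifnot(is.numeric(median_months), median_months > 0)
  weibull_params(lambda = log(2) / median_months^gamma, gamma = gamma)
}

#' Construct and validate Weibull parameters
#'
#' @param lambda scale, strictly positive and finite.
#' @param gamma shape, strictly positive and finite.
#' @return a list of class `weibull_params`.
#' @export
weibull_params <- function(lambda, gamma) {
  check_weibull_params(lambda, gamma)
  structure(list(lambda = lambda, gamma = gamma), class = "weibull_params")
}

check_weibull_params <- function(lambda, gamma) {
  if (!is.numeric(lambda) || !is.finite(lambda) || lambda <= 0) {
    abort("`lambda` (Weibull scale) must be a finite positive number.")
  }
  if (!is.numeric(gamma) || !is.finite(gamma) || gamma <= 0) {
    abort("`gamma` (Weibull shape) must be a finite positive number.")
  }
  invisible(TRUE)
}

#' Convert a constant event rate to a probability over an interval
#'
#' `P = 1 - exp(-r * t)`: the probability that an event with constant
#' hazard `r` per month occurs within `t` months.
#'
#' @param r event rate per month, `>= 0`.
#' @param t interval length in months, `>= 0`.
#' @return probability in \[0, 1).
#' @export
#' @examples
#' rate_to_probability(log(2) / 10, 10) # 0.5 at the median
rate_to_probability <- function(r, t) {
  if (any(r < 0)) abort("`r` must be non-negative.")
  if (any(t < 0)) abort("`t` must be non-negative.")
  1 - exp(-r * t)
}

#' Per-cycle conditional transition probability under a Weibull law
#'
#' Probability that the event occurs in the cycle ending at time `t`
#' (i.e. in `(t - u, t]`) given that it has not occurred by `t - u`:
#' `Pt = 1 - exp(lambda * ((t - u)^gamma - t^gamma))`.
#'
#' With `gamma = 1` this is constant across cycles (memorylessness); for
#' `gamma > 1` it increases with `t`.
#'
#' @param params a `weibull_params` object (or list with `lambda`, `gamma`).
#' @param t cycle-end time in months, vectorised, `t >= u`.
#' @param u cycle length in months, `> 0`.
#' @return conditional probabilities in \[0, 1).
#' @export
#' @examples
#' p <- weibull_params(0.02, 1.5)
#' weibull_transition_prob(p, t = 10, u = 0.75)
weibull_transition_prob <- function(params, t, u) {
  check_weibull_params(params$lambda, params$gamma)
  if (u <= 0) abort("cycle length `u` must be positive.")
  if (any(t < u)) abort("`t` must be at least one cycle length `u`.")
  1 - exp(params$lambda * ((t - u)^params$gamma - t^params$gamma))
}
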
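#' Plot a cohort trace
#'
#' State occupancy (PFS, PD, death) over time in months.
#'
#' @param object a `cohort_trace`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "time_months", "pfs", "pd", "death"),
    cols = c("pfs", "pd", "death"),
    names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = c("pfs", "pd", "death"),
                       labels = c("Progression-free", "Progressive disease",
                                  "Death"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_months,
                                     y = .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Time (months)", y = "State occupancy",
                  colour = NULL,
                  title = paste0("Cohort trace: ", attr(object, "arm"))) +
    ggplot2::theme_minimal()
}

#' Tornado diagram for a one-way sensitivity analysis
#'
#' @param object a `tornado` tibble from [one_way_sensitivity()].
#' @param top show only the `top` widest bars (default 15).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tornado <- function(object, top = 15, ...) {
  d <- head(object, top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  base <- attr(object, "base_result")
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$low_result,
                                       xend = .data$high_result,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = if (attr(object, "metric") == "icer")
                    "ICER (USD/QALY)" else "Incremental net benefit (USD)",
                  y = NULL, title = "One-way sensitivity") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param object a `ceac` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ceac <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("prob_treat", "prob_ctrl"),
                              names_to = "arm", values_to = "prob")
  long$arm <- ifelse(long$arm == "prob_treat",
                     attr(object, "treat"), attr(object, "ctrl"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wtp, y = .data$prob,
                                     colour = .data$arm)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Incremental cost-effect scatter of PSA draws
#'
#' @param object a `psa_draws` tibble.
#' @param treat,ctrl arm names.
#' @param wtp threshold line to draw (USD/QALY).
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_psa_scatter <- function(object, treat, ctrl, wtp = 30828, ...) {
  inc <- psa_increments(object, treat, ctrl)
  ggplot2::ggplot(inc, ggplot2::aes(x = .data$ie, y = .data$ic)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALY", y = "Incremental cost (USD)") +
    ggplot2::theme_minimal()
}

#' Plot a digitized KM curve and an optional fitted Weibull survivor
#'
#' @param object a `km_curve`.
#' @param fit optional `weibull_fit` / `weibull_params` overlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.km_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                            y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival fraction",
                  title = paste0(attr(object, "endpoint"),
                                 if (!is.null(attr(object, "arm")))
                                   paste0(" - ", attr(object, "arm")))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tt <- seq(0, max(object$time), length.out = 200)
    overlay <- tibble::tibble(time = tt,
                              survival = weibull_survivor(tt, fit$lambda,
                                                          fit$gamma))
    p <- p + ggplot2::geom_line(data = overlay, colour = "firebrick")
  }
  p
}
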
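# ggplot2 views of the three result types: tornado diagram, CE-plane
# scatter, acceptability curve.

#' Tornado diagram of one-way sensitivity results
#'
#' Horizontal bars from the ICER at each parameter's low bound to the ICER
#' at its high bound, ranked by spread, with a reference line at the
#' base-case ICER. Only the `top` widest bars are drawn (a full manifest is
#' unreadable).
#'
#' @param object A `tornado` tibble from [run_owsa()].
#' @param top Number of parameters to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tornado <- function(object, top = 12, ...) {
  d <- object[!object$failed & object$spread > 0, ]
  d <- utils::head(d, top)
  d$param <- factor(d$param, levels = rev(d$param))
  base <- attr(object, "base_icer")
  ggplot2::ggplot(d, ggplot2::aes(y = .data$param)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_at_low, xend = .data$icer_at_high,
                   yend = .data$param),
      linewidth = 4, colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(
      x = "ICER (CNY per QALY)", y = NULL,
      title = "One-way sensitivity of the long-term ICER",
      subtitle = sprintf("Dashed line: base case, %s CNY/QALY",
                         format(round(base), big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane scatter of a PSA
#'
#' One point per simulation draw (incremental QALYs against incremental
#' cost), the deterministic base case marked, and the willingness-to-pay
#' thresholds drawn as lines through the origin.
#'
#' @param object A `psa_result` from [run_psa()].
#' @param wtp Threshold lines to draw (CNY per QALY).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psa_result <- function(object, wtp = c(35100, 105000), ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "grey30") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = wtp, intercept = 0,
                         linetype = c(1, 2)[seq_along(wtp)]) +
    ggplot2::annotate("point", x = object$base$delta_qaly,
                      y = object$base$delta_cost, colour = "red", size = 2) +
    ggplot2::labs(
      x = "Incremental QALYs (tPA - control)",
      y = "Incremental cost (CNY)",
      title = "Cost-effectiveness plane",
      subtitle = sprintf("%d draws; red point: deterministic base case",
                         object$n_draws)
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A `psa_result` from [run_psa()] (or a CEAC tibble with
#'   columns `wtp` and `probability`).
#' @param wtp_marks Thresholds to mark with vertical lines.
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa, wtp_marks = c(35100, 105000)) {
  curve <- if (inherits(psa, "psa_result")) psa$ceac else psa
  ggplot2::ggplot(curve, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = wtp_marks, linetype = 2,
                        colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (CNY per QALY)",
      y = "Probability tPA is cost-effective",
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}

#' State-occupancy trace plot
#'
#' Stacked area chart of the cohort's occupancy of the four health states
#' across model cycles for one arm.
#'
#' @param object A `cohort_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("cycle", "mrs01", "mrs23", "mrs45", "death")],
    -"cycle", names_to = "state", values_to = "occupancy"
  )
  long$state <- factor(long$state, levels = rev(.states))
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(
      x = "Model cycle (0 = first 90 days, then years)",
      y = "State occupancy",
      title = paste("Cohort trace,", object$arm[1], "arm"),
      fill = "mRS state"
    ) +
    ggplot2::theme_minimal()
}
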
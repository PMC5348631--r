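#' Plot a discounting fit against its choice data
#'
#' Shows every trial in delay-by-amount space, coloured by the observed
#' choice, with the fitted indifference curve `A* = ref * (1 + k * D)`
#' overlaid; choices above the curve should mostly be "delayed" and choices
#' below it "immediate", with the mixing zone's width set by `beta`.
#'
#' @param object A `"discount_fit"` from [fit_mle()] with `keep_data = TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.discount_fit <- function(object, ...) {
  if (is.null(object$data)) {
    stop("fit was created with `keep_data = FALSE`; nothing to plot",
         call. = FALSE)
  }
  d <- object$data
  curve <- tibble::tibble(
    delay_days = seq(0, max(d$delay_days), length.out = 200)
  )
  curve$amount_eur <- indifference_amount(object$k, curve$delay_days,
                                          object$ref)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delay_days,
                                  y = .data$amount_eur)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$choice), alpha = 0.7) +
    ggplot2::geom_line(data = curve, linewidth = 0.8) +
    ggplot2::labs(
      x = "delay (days)", y = "delayed amount (EUR)",
      colour = "choice",
      title = sprintf("k = %.3f /day, beta = %.2f EUR", object$k, object$beta),
      subtitle = "line: fitted indifference amounts"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of the tag effect against attentional control
#'
#' One point per subject: singleton score (x) against the tag effect on
#' `sqrt(k)` (y), with a least-squares line.  A negative slope means
#' subjects with better flexible attentional control (lower singleton
#' scores) show a larger episodic reduction of discounting.
#'
#' @param tag_effects Output of [tag_effect()].
#' @param scores Per-subject tibble with `subject_id` and `singleton_score`.
#' @return A ggplot object.
#' @export
plot_tag_effect <- function(tag_effects, scores) {
  d <- dplyr::inner_join(tag_effects, scores, by = "subject_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$singleton_score,
                                  y = .data$delta_sqrt_k)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = "singleton score (ms; higher = poorer flexible control)",
      y = expression(Delta * sqrt(k) ~ "(tag - control)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a generated trial schedule
#'
#' Amounts by delay for each block, with the construction indifference
#' curve; a quick visual check that the ladders bracket the indifference
#' point and respect the 20.5-79.5 EUR range.
#'
#' @param schedule Output of [build_session()].
#' @return A ggplot object.
#' @export
plot_schedule <- function(schedule) {
  k <- attr(schedule, "k")
  ref <- attr(schedule, "ref") %||% 20
  p <- ggplot2::ggplot(schedule, ggplot2::aes(x = .data$delay_days,
                                              y = .data$amount_eur)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$condition),
                        alpha = 0.6, position = ggplot2::position_jitter(
                          width = 0.02, height = 0, seed = 1)) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = c(20.5, 79.5), linetype = 3) +
    ggplot2::labs(x = "delay (days, log scale)", y = "amount (EUR)") +
    ggplot2::theme_minimal()
  if (!is.null(k)) {
    curve <- tibble::tibble(delay_days = exp(seq(0, log(190), length.out = 200)))
    curve$amount_eur <- indifference_amount(k, curve$delay_days, ref)
    p <- p + ggplot2::geom_line(data = curve)
  }
  p
}
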
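#' Coefficient interval plot
#'
#' Posterior means and 95% credible intervals for the outcome regression
#' and structural coefficients.
#'
#' @param object A `sem_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sem_fit <- function(object, ...) {
  td <- tidy(object)
  td <- dplyr::filter(td, grepl("^(gamma_|beta_)|^rho$", .data$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)
    ) +
    ggplot2::labs(
      x = "posterior mean and 95% credible interval", y = NULL,
      title = "Outcome and structural coefficients"
    ) +
    ggplot2::theme_minimal()
}

#' Factor score versus admission risk plot
#'
#' Scatter of posterior mean factor scores against posterior mean relative
#' risks, with the locally weighted smooth from [factor_risk_curve()].
#'
#' @param fit A `sem_fit` object.
#' @param factor `"quality"` or `"poor_access"`.
#' @param span Smoother span.
#' @return A ggplot.
#' @export
plot_factor_risk <- function(fit, factor = c("quality", "poor_access"),
                             span = 2 / 3) {
  factor <- match.arg(factor)
  curve <- factor_risk_curve(fit, factor, span)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$score, y = .data$relative_risk)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), colour = "firebrick") +
    ggplot2::labs(
      x = paste("posterior mean", gsub("_", " ", factor), "score"),
      y = "posterior mean relative risk of admission"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
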
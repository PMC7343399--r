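# ggplot2 display methods.

#' @describeIn fit_univariate Coefficient interval plot (posterior mean and
#'   95 percent interval for every fixed effect).
#' @param object,x A `fid_fit`.
#' @param ... Unused.
#' @method autoplot fid_fit
#' @export
autoplot.fid_fit <- function(object, ...) {
  td <- tidy(object, effects = "fixed")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Posterior estimate (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot conditional-effect curves
#'
#' Observer-by-trial-number conditional predictions (the habituation /
#' sensitization display): posterior-mean response-scale curves per observer
#' with 2.5/97.5 percent bands.
#'
#' @param fit A `fid_fit`.
#' @param term,response Passed to [conditional_effects()].
#' @return A ggplot.
#' @export
plot_conditional_effects <- function(fit,
                                     term = "observer_unfamiliar:trial_number",
                                     response = NULL) {
  ce <- conditional_effects(fit, term, response)
  xvar <- setdiff(names(ce), c("estimate", "lower", "upper", "observer"))[1]
  p <- ggplot2::ggplot(ce, ggplot2::aes(x = .data[[xvar]], y = .data$estimate))
  if ("observer" %in% names(ce)) {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                        fill = .data$observer), alpha = 0.25) +
      ggplot2::geom_line(ggplot2::aes(colour = .data$observer))
  } else {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           alpha = 0.25) +
      ggplot2::geom_line()
  }
  p + ggplot2::labs(y = paste0("Predicted ",
                               toupper(response %||% names(fit$specs)[1]),
                               " (m)")) +
    ggplot2::theme_minimal()
}

#' Convergent-validity scatter of conditional modes
#'
#' Per-individual visual-tolerance (VOD) versus displacement-tolerance (FID)
#' estimates from a bivariate fit; lower values mean greater tolerance.
#'
#' @param fit A bivariate `fid_fit` (or a wide tibble from
#'   [conditional_modes()]).
#' @return A ggplot.
#' @export
plot_conditional_modes <- function(fit) {
  cm <- if (inherits(fit, "fid_fit")) conditional_modes(fit) else fit
  stopifnot(all(c("vod", "fid") %in% names(cm)))
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$vod, y = .data$fid)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = "Visual tolerance (VOD intercept deviation)",
                  y = "Displacement tolerance (FID intercept deviation)") +
    ggplot2::theme_minimal()
}

#' @describeIn enhanced_icc Interval plot of the per-response ICC posterior.
#' @param object A `fid_icc`.
#' @param ... Unused.
#' @method autoplot fid_icc
#' @export
autoplot.fid_icc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$response, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$hdi_low,
                                          ymax = .data$hdi_high)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "Repeatability (ICC), 95% HDI", x = NULL) +
    ggplot2::theme_minimal()
}
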
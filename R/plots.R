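#' Plot psychometric curves
#'
#' Points with binomial error bars per signed contrast, optionally coloured
#' by a condition column.
#'
#' @param trials Trial table with choices.
#' @param colour Optional unquoted column to colour/group by (e.g. a block
#'   side).
#' @return A ggplot object.
#' @export
plot_psychometric <- function(trials, colour = NULL) {
  colour <- rlang::enquo(colour)
  if (rlang::quo_is_null(colour)) {
    dat <- psychometric(trials)
    p <- ggplot2::ggplot(dat, ggplot2::aes(.data$signed_contrast,
                                           .data$p_right))
  } else {
    dat <- psychometric(trials, !!colour)
    p <- ggplot2::ggplot(dat, ggplot2::aes(.data$signed_contrast,
                                           .data$p_right,
                                           colour = !!colour,
                                           group = !!colour))
  }
  p +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p_right - .data$se,
                                        ymax = .data$p_right + .data$se),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Signed contrast", y = "Rightward (proportion)") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot block-switch learning curves
#'
#' @param curve Output of [learning_curve()].
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$rel_trial, .data$p_right,
                                      colour = .data$new_large_side)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Trials from block switch",
                  y = "P(rightward) running average",
                  colour = "New large side") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_grid NLL landscape over `alpha` and `sigma2` at the best
#'   `x` (log colour scale).
#' @param object,x An `rl_fit`.
#' @param ... Unused.
#' @export
autoplot.rl_fit <- function(object, ...) {
  best_x <- object$best_params$x
  dat <- dplyr::filter(object$grid, .data$x == best_x)
  ggplot2::ggplot(dat, ggplot2::aes(factor(.data$alpha), factor(.data$sigma2),
                                    fill = .data$nll)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "alpha", y = "sigma2",
                  title = sprintf("NLL at x = %g", best_x), fill = "NLL") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_event_kernels Fitted kernels by event.
#' @param object,x A `kernel_fit`.
#' @param ... Unused.
#' @export
autoplot.kernel_fit <- function(object, ...) {
  ggplot2::ggplot(object$kernels, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~event, scales = "free_x") +
    ggplot2::labs(x = "Time from event (s)", y = "Kernel (unit norm)") +
    ggplot2::theme_minimal()
}

#' @describeIn correlate_gains_with_latents Binned gain means against the
#'   latent with the fitted regression line.
#' @param object,x A `latent_cor`.
#' @param ... Unused.
#' @export
autoplot.latent_cor <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(.data$latent_mean,
                                            .data$gain_mean)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gain_mean - .data$se,
                                          ymax = .data$gain_mean + .data$se)) +
    ggplot2::labs(x = "Latent (bin mean)", y = "Trial gain (bin mean)") +
    ggplot2::theme_minimal()
}
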
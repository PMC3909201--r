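#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an apparent free-energy profile
#' @param object A `cg_free_energy`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cg_free_energy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q_frac, y = .data$f)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Q (fraction of native contacts)",
                  y = expression(-k[B] * T[avg] * ln * P(Q)),
                  title = "Apparent free-energy profile") +
    ggplot2::theme_minimal()
}

#' Plot a residue phi-profile
#' @param object A `cg_phi_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cg_phi_profile <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$phi), ],
                  ggplot2::aes(x = .data$residue, y = .data$phi)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "residue", y = expression(phi),
                  title = "Transition-state phi-values") +
    ggplot2::theme_minimal()
}

#' Plot a phi-profile comparison
#' @param object A `cg_phi_comparison`.
#' @param ... Ignored.
#' @return A ggplot of the two profiles and their increments.
#' @export
autoplot.cg_phi_comparison <- function(object, ...) {
  tab <- object$table
  long <- tidyr::pivot_longer(tab, c("phi_a", "phi_b"),
                              names_to = "model", values_to = "phi")
  ggplot2::ggplot(long[!is.na(long$phi), ],
                  ggplot2::aes(x = .data$residue, y = .data$phi,
                               colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue", y = expression(phi),
                  subtitle = sprintf("Pearson r = %.2f, mean increment %.2f",
                                     object$r, object$mean_increment)) +
    ggplot2::theme_minimal()
}

#' Plot a variable-temperature trace
#' @param object A `cg_temperature_trace`.
#' @param ... Ignored.
#' @return A ggplot of temperature vs adjustment window.
#' @export
autoplot.cg_temperature_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window,
                                       y = .data$temperature)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "adjustment window", y = "temperature (reduced)",
                  title = "Adaptive temperature trace") +
    ggplot2::theme_minimal()
}
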
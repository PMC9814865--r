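utils::globalVariables(c("t", "S", "ci_lo", "ci_hi", "theta", "y", "curve"))

#' Plot a survival curve
#'
#' Log-log survival probability with its confidence band (when the curve
#' came from Monte Carlo).
#'
#' @param object an `rxn_survival` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rxn_survival <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$S > 0 & df$t > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = t, y = S))
  if (any(df$halfwidth > 0)) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_lo, ymax = ci_hi),
                                  alpha = 0.25, fill = "steelblue")
  }
  p + ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "survival probability S(t)")
}

#' Plot rescaled survival curves against their universal limit
#'
#' @param curves named list of rescaled curves (see [rescale_survival()]).
#' @param theory optional function of `theta` for the limit curve.
#' @param window plotted `theta` range.
#' @return a ggplot object.
#' @export
plot_collapse <- function(curves, theory = NULL, window = c(0.05, 5)) {
  if (is.null(names(curves))) names(curves) <- paste0("curve", seq_along(curves))
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    tibble(curve = nm, theta = cv$theta, y = cv$y)
  }))
  df <- df[df$theta >= window[1] & df$theta <= window[2] & df$y > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = theta, y = y, colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(theta == t / scale),
                  y = "rescaled survival")
  if (!is.null(theory)) {
    th <- exp(seq(log(window[1]), log(window[2]), length.out = 200))
    p <- p + ggplot2::geom_line(
      data = tibble(theta = th, y = theory(th), curve = "theory"),
      colour = "black", linetype = 2)
  }
  p
}
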
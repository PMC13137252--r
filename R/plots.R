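# ggplot2 displays for ensembles, scans and kernels.

#' Plot ensemble population dynamics
#'
#' Donor/acceptor populations (and coherence magnitude) against time, with
#' a Monte-Carlo error ribbon on the acceptor population.
#'
#' @param object An `nmsse_ensemble`.
#' @param show_coherence Add the electronic coherence magnitude.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nmsse_ensemble
#' @export
autoplot.nmsse_ensemble <- function(object, show_coherence = FALSE, ...) {
  df <- object$data
  long <- tidyr::pivot_longer(
    df[, c("t", "p_donor", "p_acceptor", "coherence_abs")],
    -"t", names_to = "series", values_to = "value")
  if (!show_coherence) long <- dplyr::filter(long, .data$series != "coherence_abs")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                          colour = .data$series)) +
    ggplot2::geom_ribbon(
      data = df, inherit.aes = FALSE,
      ggplot2::aes(x = .data$t,
                   ymin = .data$p_acceptor - 2 * .data$se_p_a,
                   ymax = .data$p_acceptor + 2 * .data$se_p_a),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (1/eV)", y = "population",
                  colour = NULL,
                  title = sprintf("NMSSE ensemble (%s bath, %d trajectories)",
                                  object$bath_kind, object$n_traj)) +
    ggplot2::theme_minimal()
  p
}

#' Plot a Delta-P scan as a heat map
#'
#' @param object An `nmsse_scan`.
#' @param y Which cell variable spans the vertical axis: `"coupling"` or
#'   `"lam"`.
#' @param ... Unused.
#' @return A ggplot object (tiles of Delta-P over log10(delta) and `y`,
#'   faceted by bath kind).
#' @method autoplot nmsse_scan
#' @export
autoplot.nmsse_scan <- function(object, y = c("coupling", "lam"), ...) {
  y <- match.arg(y)
  df <- dplyr::filter(object$data, !is.na(.data$delta_p))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$delta),
                                   y = factor(.data[[y]]),
                                   fill = .data$delta_p)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~bath) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "electronic coupling Delta (eV)", y = y,
                  fill = "Delta P") +
    ggplot2::theme_minimal()
}

#' Plot a correlation kernel
#'
#' @param object A `correlation_kernel`.
#' @param ... Unused.
#' @return A ggplot object with the real and imaginary parts over lag.
#' @method autoplot correlation_kernel
#' @export
autoplot.correlation_kernel <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"tau",
                            names_to = "part", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$value,
                                   colour = .data$part)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (1/eV)", y = "alpha(tau)",
                  title = sprintf("%s bath kernel", object$kind)) +
    ggplot2::theme_minimal()
}
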
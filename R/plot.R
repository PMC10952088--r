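# ggplot2 autoplot methods for the result objects.

#' @export
autoplot.aq_rdf <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "r (Å)",
                  y = bquote(g[.(object$pair)](r)),
                  title = paste0("Radial distribution function g_",
                                 object$pair)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aq_msd <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag time (ps)", y = expression(MSD~(ring(A)^2)),
                  title = "Mean-squared displacement") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aq_acf <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$C)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag time (ps)",
                  y = bquote(C[.(object$order)](t)),
                  title = paste0("Orientational ACF, ", object$axis,
                                 " axis, order ", object$order)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aq_angledist <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$angle, y = .data$beta_density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(beta~(degrees)),
                  y = expression(P(beta)~(degree^-1)),
                  title = "H-bond angle distribution") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aq_volscan <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$volume, y = .data$energy)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$v_eq, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression(V~(ring(A)^3)), y = "E(V) (backend units)",
                  title = "Energy-volume scan") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
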
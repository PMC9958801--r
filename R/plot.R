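#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a transfer or output sweep
#'
#' Drain current against the swept terminal voltage. If the sweep carries a
#' grouping column (`pH`, `Nm`, `i0` or `Nt` from [run_study()]-style
#' sweeps), one curve per group is drawn.
#'
#' @param object A `biofet_iv` tibble.
#' @param scale `"log"` (default) or `"linear"` current axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot biofet_iv
#' @export
autoplot.biofet_iv <- function(object, scale = c("log", "linear"), ...) {
  scale <- match.arg(scale)
  xvar <- if (length(unique(object$Vlg)) > 1 || nrow(object) == 1) "Vlg" else "Vd"
  group <- intersect(c("pH", "Nm", "i0", "Nt"), names(object))
  p <- if (length(group) > 0) {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data[[xvar]], y = .data$Ids,
                                 colour = factor(.data[[group[1]]]))) +
      ggplot2::labs(colour = group[1])
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]], y = .data$Ids))
  }
  p <- p + ggplot2::geom_line() +
    ggplot2::labs(x = paste0(if (xvar == "Vlg") "Liquid-gate voltage" else "Drain voltage", " (V)"),
                  y = "Drain current (A)") +
    ggplot2::theme_minimal()
  if (scale == "log") p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot the electrolyte potential drop against pH
#'
#' Surface potential `psi0` (and the outer-Helmholtz-plane potential
#' `psi_m`) versus bulk pH, the ion-sensing calibration curve of the
#' interface.
#'
#' @param object A `biofet_ph` tibble from [electrolyte_drop_vs_ph()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot biofet_ph
#' @export
autoplot.biofet_ph <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("psi0", "psi_m"),
                              names_to = "potential", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pH, y = .data$value,
                                     colour = .data$potential)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "bulk pH", y = "potential (V)") +
    ggplot2::theme_minimal()
}

#' Plot per-region sensitivities of a sensing report
#'
#' @param object A `biofet_sensing` object.
#' @param ... Unused.
#' @return A ggplot object (bar chart of S per operating region).
#' @method autoplot biofet_sensing
#' @export
autoplot.biofet_sensing <- function(object, ...) {
  rep <- object$report
  rep$region <- factor(rep$region, levels = c("subthreshold", "saturation", "linear"))
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$region, y = .data$S)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "current sensitivity S") +
    ggplot2::theme_minimal()
}
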
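#' Raster plot of a simulation
#'
#' Spike times per neuron, colored by cell class (pyramidal cells black,
#' PV red, Sst cyan -- the conventional palette for this model).
#'
#' @param sim An `snn_sim` (or a raster tibble).
#' @return A ggplot object.
#' @export
plot_raster <- function(sim) {
  raster <- if (inherits(sim, "snn_sim")) sim$raster else sim
  ggplot2::ggplot(raster,
                  ggplot2::aes(x = .data$time_ms, y = .data$neuron,
                               colour = .data$cell_type)) +
    ggplot2::geom_point(shape = ".", alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(Pyr = "black", PV = "red",
                                            Sst = "cyan3")) +
    ggplot2::labs(x = "time (ms)", y = "neuron", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.snn_density <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "spike density") +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "grey40")
  p
}

#' @export
autoplot.snn_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f (%d stimulated neurons)",
                                  object$auc, object$n_stim)) +
    ggplot2::theme_minimal()
}

#' Joint degree scatter of an excitatory graph
#'
#' @param g An `exc_graph` or a degree tibble (`d_in`, `d_out`).
#' @return A ggplot object.
#' @export
plot_degrees <- function(g) {
  deg <- if (inherits(g, "exc_graph")) g$degrees else g
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$d_in, y = .data$d_out)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = "in-degree", y = "out-degree") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
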
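#' Tidy an ROC experiment
#'
#' @param x An `snn_roc` from [roc_experiment()].
#' @param ... Unused.
#' @return The ROC curve as a tibble (`threshold`, `fpr`, `tpr`).
#' @export
tidy.snn_roc <- function(x, ...) x$curve

#' One-row summary of an ROC experiment
#'
#' @param x An `snn_roc`.
#' @param ... Unused.
#' @return Tibble with `auc`, `n_stim`, `n_windows`, `bg_rate`.
#' @export
glance.snn_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_stim = x$n_stim,
                 n_windows = x$n_windows, bg_rate = x$bg_rate)
}

#' Tidy a development experiment
#'
#' @param x An `snn_development` from [development_experiment()].
#' @param ... Unused.
#' @return The pruned degree table (`neuron`, `d_in`, `d_out`).
#' @export
tidy.snn_development <- function(x, ...) x$degrees

#' One-row summary of a development experiment
#'
#' @param x An `snn_development`.
#' @param ... Unused.
#' @return Tibble with `mean_rate`, `lsr_slope`, `lsr_p`, `quadrant_stat`,
#'   `frac_low`, `frac_high` (pre-pruning weight distribution mass near the
#'   bounds), `runaway`.
#' @export
glance.snn_development <- function(x, ...) {
  bm <- weight_bimodality(x$weights_pre)
  tibble::tibble(mean_rate = x$mean_rate, lsr_slope = x$lsr$slope,
                 lsr_p = x$lsr$p_value, quadrant_stat = x$quadrant$statistic,
                 frac_low = bm$frac_low, frac_high = bm$frac_high,
                 runaway = x$runaway)
}
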
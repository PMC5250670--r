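#' Prune the weakest excitatory synapses to a target connectivity
#'
#' Keeps exactly `round(p_final * n_exc * (n_exc - 1))` strongest
#' excitatory-to-excitatory synapses (ties broken by synapse index, i.e.
#' first-come), removing the globally weakest ones, and leaves all other
#' connections untouched.
#'
#' @param network An `snn_network` (typically after a plasticity run).
#' @param p_final Target excitatory connection probability (default 0.05).
#' @return The pruned network.
#' @export
prune_to_connectivity <- function(network, p_final = 0.05) {
  ne <- network$n_exc
  is_ee <- network$edges$pre <= ne & network$edges$post <= ne
  n_keep <- round(p_final * ne * (ne - 1))
  ee_idx <- which(is_ee)
  if (n_keep > length(ee_idx))
    stop("target connectivity exceeds the available synapse count")
  o <- order(-network$edges$weight[ee_idx], ee_idx)
  drop <- ee_idx[o[-seq_len(n_keep)]]
  network$edges <- network$edges[-drop, ]
  attr(network, "compiled") <- NULL
  network
}

#' Excitatory degree table of a network
#'
#' Realized in- and out-degrees of the excitatory subnetwork.
#'
#' @param network An `snn_network`.
#' @return Tibble: `neuron`, `d_in`, `d_out`.
#' @export
exc_degrees <- function(network) {
  ne <- network$n_exc
  ee <- network$edges[network$edges$pre <= ne & network$edges$post <= ne, ]
  tibble::tibble(neuron = seq_len(ne),
                 d_in = tabulate(ee$post, nbins = ne),
                 d_out = tabulate(ee$pre, nbins = ne))
}

#' Development experiment: plasticity prunes a dense random network
#'
#' Mimics circuit maturation: a dense uncorrelated (UCOR) network at
#' excitatory connection probability `p0` (10 %) is driven by background
#' noise while STDP reshapes the excitatory weights and global homeostatic
#' scaling holds the population rate near the 1.5 Hz target; afterwards the
#' weakest synapses are pruned until exactly `p_final` (5 %) connectivity
#' remains. The additive rule produces a bimodal weight distribution, the
#' weight-dependent rule a unimodal one; in both cases the surviving
#' synapses carry an anti-correlated joint degree distribution.
#'
#' @param seed Experiment seed (construction and dynamics).
#' @param duration_s Plasticity simulation length in seconds (default 20,
#'   using the sped-up STDP/homeostasis constants).
#' @param p0 Initial excitatory connectivity (default 0.10).
#' @param p_final Post-pruning connectivity (default 0.05).
#' @param bg_rate Background rate per neuron, Hz (default 0.1).
#' @param rule `"additive"` or `"weight_dependent"`.
#' @param n_exc Excitatory population size (default 480).
#' @param cfg A [plasticity_config()]; default uses `rule` and the standard
#'   constants with initial weights at `w_max / 2`.
#' @param w_init Initial excitatory weight (default `w_max / 2`).
#' @param ... Passed to [build_network()].
#' @return List of class `snn_development`: `network` (pruned), `weights_pre`
#'   (exc weights before pruning), `degrees` (pruned degree table), `lsr`,
#'   `quadrant` (correlation statistics of the pruned graph), `mean_rate`
#'   (Hz over the run), `runaway` (TRUE if the rate left the homeostatic
#'   operating range).
#' @export
development_experiment <- function(seed, duration_s = 20, p0 = 0.10,
                                   p_final = 0.05, bg_rate = 0.1,
                                   rule = "additive", n_exc = 480,
                                   cfg = plasticity_config(rule = rule),
                                   w_init = cfg$w_max / 2, ...) {
  set.seed(seed)
  net <- build_network(degree_spec(n_exc, p0, "UCOR"), w_ee = w_init, ...)
  sim <- simulate_network(net, duration_s * 1000, bg_rate = bg_rate,
                          seed = sample.int(2^31 - 2, 1), plasticity = cfg)
  net <- sim$network
  ne <- net$n_exc
  w_pre <- net$edges$weight[net$edges$pre <= ne & net$edges$post <= ne]
  mean_rate <- firing_rate(sim, ne, neurons = seq_len(ne))
  pruned <- prune_to_connectivity(net, p_final)
  deg <- exc_degrees(pruned)
  structure(list(
    network = pruned,
    weights_pre = w_pre,
    degrees = deg,
    lsr = lsr_correlation(deg$d_in, deg$d_out),
    quadrant = quadrant_statistic(deg$d_in, deg$d_out),
    mean_rate = mean_rate,
    runaway = mean_rate > 10 * cfg$r_target),
    class = "snn_development")
}

#' @export
print.snn_development <- function(x, ...) {
  cat(sprintf(
    "snn_development: mean rate %.2f Hz, LSR slope %.2f, quadrant stat %.2f\n",
    x$mean_rate, x$lsr$slope, x$quadrant$statistic))
  invisible(x)
}

#' Bimodality of a weight distribution
#'
#' Fraction of weights within `edge_frac * w_max` of either bound, a simple
#' summary of how bimodal an additive-STDP weight distribution is.
#'
#' @param w Weights.
#' @param w_max Upper bound.
#' @param edge_frac Width of the boundary bins (default 0.1).
#' @return Named list: `frac_low`, `frac_high`, `frac_middle`.
#' @export
weight_bimodality <- function(w, w_max = 0.013, edge_frac = 0.1) {
  lo <- mean(w <= edge_frac * w_max)
  hi <- mean(w >= (1 - edge_frac) * w_max)
  list(frac_low = lo, frac_high = hi, frac_middle = 1 - lo - hi)
}
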
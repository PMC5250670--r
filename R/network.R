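#' Izhikevich cell-class parameters
#'
#' The three model cell classes: regular-spiking pyramidal cells (Pyr),
#' fast-spiking parvalbumin interneurons (PV) and low-threshold-spiking
#' somatostatin interneurons (Sst). `c_var` and `i_fluc_var` are the
#' variances of the across-neuron normal distributions from which the spike
#' reset value `c` and the mean of the white-noise drive are drawn once per
#' neuron at network construction (the per-step standard deviation of the
#' white-noise current itself is set in [wire_network()]).
#'
#' @return Tibble with one row per cell class.
#' @export
cell_params <- function() {
  tibble::tibble(
    type = c("Pyr", "PV", "Sst"),
    a = c(0.02, 0.1, 0.02),
    b = c(0.2, 0.2, 0.25),
    c = c(-65, -65, -65),
    c_var = c(5, 5, 5),
    d = c(8, 2, 2),
    i_fluc = c(3, 0, 0),
    i_fluc_var = c(0.5, 0.5, 0.5))
}

#' Wire the full three-population network
#'
#' Embeds an excitatory graph (Pyr to Pyr connectivity from
#' [generate_exc_graph()]) into the full network: pyramidal cells project to
#' both interneuron classes with probability `p_ei`; PV cells project to all
#' Pyr and PV cells and Sst cells to all Pyr and PV cells with probability
#' `p_ie`; Sst cells receive no inhibition (no Sst to Sst, no PV to Sst).
#' Inhibitory weights are `w_inh` scaled by the relative-strength table
#' `inh_ratios` (PV outputs as reference, Sst outputs weaker, following the
#' experimentally measured ratios of interneuron synaptic drive). Per-neuron
#' heterogeneity (reset value `c`, white-noise mean) is sampled here, once,
#' from the variances in [cell_params()]. Uses the R random number generator.
#'
#' All weights are non-negative; the sign of a synapse's effect is carried by
#' its reversal potential (0 for excitatory, -80 for inhibitory presynaptic
#' cells), not by the weight.
#'
#' @param exc One of: an `exc_graph`, or a plain edge tibble (`pre`, `post`)
#'   over `1..n_exc`.
#' @param n_exc,n_pv,n_sst Population sizes (defaults 480 / 60 / 60).
#' @param w_ee Recurrent excitatory (Pyr to Pyr) weight, default 0.013 (the
#'   plasticity hard bound, at which neurons fire near the homeostatic target
#'   rate for 0.1 Hz background noise).
#' @param w_ei Pyr to interneuron weight (default 0.013).
#' @param w_inh Base inhibitory weight (default 0.6; calibrated, together
#'   with `excitability_margin` and `fluc_sd`, so the default network is
#'   silent without input, quiescent-to-intermittent at 0.07 Hz background
#'   noise, and continuously bursting near 0.1 Hz with a mean excitatory
#'   rate close to 1.5 Hz).
#' @param p_ei Pyr to interneuron connection probability (default 0.5).
#' @param p_ie Interneuron to {Pyr, PV} connection probability (default 0.6).
#' @param inh_ratios Named relative strengths
#'   (`pv_pyr`, `pv_pv`, `sst_pyr`, `sst_pv`).
#' @param fluc_sd Per-step standard deviation of the white-noise current
#'   (default 0.3; the table's printed variance is read as across-neuron
#'   variability of the mean drive, while intrinsic fluctuations contribute
#'   only a small part of the input variability).
#' @param excitability_margin How far below the resting-state stability
#'   boundary the per-neuron drive is truncated (default 0.15 current units);
#'   controls how hard it is for background activity to ignite a network
#'   burst.
#' @return An object of class `snn_network`: list with `neurons` (tibble:
#'   `id`, `type`, `a`, `b`, `c`, `d`, `i_fluc_mean`, `i_fluc_sd`), `edges`
#'   (tibble: `pre`, `post`, `weight`), counts and the wiring parameters.
#' @export
wire_network <- function(exc, n_exc = 480, n_pv = 60, n_sst = 60,
                         w_ee = 0.013, w_ei = 0.013, w_inh = 0.6,
                         p_ei = 0.5, p_ie = 0.6,
                         inh_ratios = c(pv_pyr = 1, pv_pv = 1,
                                        sst_pyr = 0.54, sst_pv = 0.33),
                         fluc_sd = 0.3, excitability_margin = 0.15) {
  if (inherits(exc, "exc_graph")) {
    n_exc <- exc$spec$n_exc
    exc_edges <- exc$edges
  } else {
    exc_edges <- exc
  }
  stopifnot(p_ei >= 0, p_ei <= 1, p_ie >= 0, p_ie <= 1,
            w_ee >= 0, w_ei >= 0, w_inh >= 0, all(inh_ratios >= 0))
  if (any(exc_edges$pre == exc_edges$post))
    stop("excitatory graph contains self connections")

  n <- n_exc + n_pv + n_sst
  pars <- cell_params()
  type <- rep(pars$type, c(n_exc, n_pv, n_sst))
  row <- match(type, pars$type)
  # largest constant current for which the resting state exists AND is
  # linearly stable (below both the saddle-node and the Hopf point
  # 0.08 v* + 5 = a): cortical neurons are not intrinsic pacemakers, so the
  # frozen per-neuron drive is truncated excitability_margin below the
  # stability boundary
  i_saddle <- ((5 - pars$b[row])^2 - 0.16 * 140) / 0.16
  v_h <- (pars$a[row] - 5) / 0.08
  i_hopf <- -(0.04 * v_h^2 + (5 - pars$b[row]) * v_h + 140)
  i_max <- pmin(i_saddle, i_hopf) - excitability_margin
  i_mean <- pars$i_fluc[row] + sqrt(pars$i_fluc_var[row]) * stats::rnorm(n)
  while (any(bad <- i_mean >= i_max))
    i_mean[bad] <- pars$i_fluc[row][bad] +
      sqrt(pars$i_fluc_var[row][bad]) * stats::rnorm(sum(bad))
  neurons <- tibble::tibble(
    id = seq_len(n),
    type = type,
    a = pars$a[row],
    b = pars$b[row],
    c = pars$c[row] + sqrt(pars$c_var[row]) * stats::rnorm(n),
    d = pars$d[row],
    i_fluc_mean = i_mean,
    i_fluc_sd = fluc_sd)

  pv_ids <- n_exc + seq_len(n_pv)
  sst_ids <- n_exc + n_pv + seq_len(n_sst)

  bernoulli_block <- function(pre_ids, post_ids, prob, weight, no_self = TRUE) {
    pre <- rep(pre_ids, each = length(post_ids))
    post <- rep(post_ids, times = length(pre_ids))
    if (no_self) {
      keep <- pre != post
      pre <- pre[keep]; post <- post[keep]
    }
    keep <- stats::runif(length(pre)) < prob
    tibble::tibble(pre = pre[keep], post = post[keep], weight = weight)
  }

  edges <- dplyr::bind_rows(
    tibble::tibble(pre = exc_edges$pre, post = exc_edges$post, weight = w_ee),
    bernoulli_block(seq_len(n_exc), c(pv_ids, sst_ids), p_ei, w_ei),
    bernoulli_block(pv_ids, seq_len(n_exc), p_ie, w_inh * inh_ratios[["pv_pyr"]]),
    bernoulli_block(pv_ids, pv_ids, p_ie, w_inh * inh_ratios[["pv_pv"]]),
    bernoulli_block(sst_ids, seq_len(n_exc), p_ie, w_inh * inh_ratios[["sst_pyr"]]),
    bernoulli_block(sst_ids, pv_ids, p_ie, w_inh * inh_ratios[["sst_pv"]]))

  structure(
    list(neurons = neurons, edges = edges,
         n = n, n_exc = n_exc, n_pv = n_pv, n_sst = n_sst,
         params = list(w_ee = w_ee, w_ei = w_ei, w_inh = w_inh,
                       p_ei = p_ei, p_ie = p_ie, inh_ratios = inh_ratios)),
    class = "snn_network")
}

#' Build a default network from a degree specification
#'
#' Convenience pipeline: [generate_exc_graph()] then [wire_network()].
#'
#' @param spec A [degree_spec()]; its `n_exc` sets the pyramidal count.
#' @param n_pv,n_sst Interneuron counts; default 1/8 of the excitatory count
#'   each (60 for the standard 480-cell excitatory population).
#' @param ... Passed to [wire_network()].
#' @return An `snn_network` with the generating `exc_graph` attached as
#'   `$exc_graph`.
#' @export
build_network <- function(spec, n_pv = round(spec$n_exc / 8),
                          n_sst = round(spec$n_exc / 8), ...) {
  g <- generate_exc_graph(spec)
  net <- wire_network(g, n_pv = n_pv, n_sst = n_sst, ...)
  net$exc_graph <- g
  net
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("snn_network: %d neurons (%d Pyr, %d PV, %d Sst), %d connections\n",
              x$n, x$n_exc, x$n_pv, x$n_sst, nrow(x$edges)))
  invisible(x)
}

#' Set the recurrent excitatory strength of a network
#'
#' Rescales only the Pyr to Pyr weights, as used in the sensitivity sweep
#' over recurrent strength.
#'
#' @param network An `snn_network`.
#' @param w_ee New Pyr to Pyr weight.
#' @return The modified network.
#' @export
set_w_ee <- function(network, w_ee) {
  ee <- network$edges$pre <= network$n_exc & network$edges$post <= network$n_exc
  network$edges$weight[ee] <- w_ee
  network$params$w_ee <- w_ee
  network
}

#' Excitatory out-degrees and the stimulation candidate pool
#'
#' The stimulation protocol targets pyramidal neurons whose out-degree
#' (within the excitatory subnetwork) is closest to the mean out-degree; the
#' candidate pool holds the 10 closest, ties broken by neuron index.
#'
#' @param network An `snn_network`.
#' @param pool_size Number of candidates (default 10).
#' @return Integer vector of neuron ids.
#' @export
stim_candidates <- function(network, pool_size = 10) {
  ee <- network$edges[network$edges$pre <= network$n_exc &
                        network$edges$post <= network$n_exc, ]
  d_out <- tabulate(ee$pre, nbins = network$n_exc)
  ord <- order(abs(d_out - mean(d_out)), seq_len(network$n_exc))
  ord[seq_len(pool_size)]
}

#' Write / read a network as plain-text tables
#'
#' The network is stored as two tab-separated files: `<stem>_edges.tsv`
#' (`pre`, `post`, `weight`) and `<stem>_neurons.tsv` (`id`, `type`, `a`,
#' `b`, `c`, `d`, `i_fluc_mean`, `i_fluc_sd`).
#'
#' @param network An `snn_network`.
#' @param stem Path stem for the two files.
#' @return `write_network()` returns the stem invisibly; `read_network()`
#'   returns the reconstructed `snn_network`.
#' @export
write_network <- function(network, stem) {
  utils::write.table(network$edges, paste0(stem, "_edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(network$neurons, paste0(stem, "_neurons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' @rdname write_network
#' @export
read_network <- function(stem) {
  edges <- tibble::as_tibble(utils::read.delim(paste0(stem, "_edges.tsv")))
  neurons <- tibble::as_tibble(utils::read.delim(paste0(stem, "_neurons.tsv")))
  counts <- table(factor(neurons$type, levels = c("Pyr", "PV", "Sst")))
  structure(
    list(neurons = neurons, edges = edges, n = nrow(neurons),
         n_exc = unname(counts[["Pyr"]]), n_pv = unname(counts[["PV"]]),
         n_sst = unname(counts[["Sst"]]), params = list()),
    class = "snn_network")
}
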
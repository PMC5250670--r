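#' Stimulation protocol
#'
#' Current injection used for the sensitivity and detection experiments: a
#' square pulse of amplitude 8 (current units) for 25 ms into a small set of
#' pyramidal cells sampled from the near-mean-out-degree candidate pool
#' (see [stim_candidates()]).
#'
#' @param neurons Integer vector of stimulated neuron ids (may be empty).
#' @param amplitude Injected current (default 8).
#' @param onset_ms Stimulus onset relative to the start of the simulation.
#' @param duration_ms Pulse duration (default 25 ms).
#' @return A list of class `stim_protocol`.
#' @export
stim_protocol <- function(neurons, amplitude = 8, onset_ms = 0,
                          duration_ms = 25) {
  stopifnot(amplitude >= 0, duration_ms >= 0)
  structure(list(neurons = as.integer(neurons), amplitude = amplitude,
                 onset_ms = onset_ms, duration_ms = duration_ms),
            class = "stim_protocol")
}

#' STDP and homeostasis configuration
#'
#' Parameters of the plasticity experiment. The additive rule changes an
#' excitatory-to-excitatory weight by `A+ * exp(-|dt|/tau+)` when the
#' presynaptic spike leads the postsynaptic spike by `|dt|`, and by
#' `-A- * exp(-|dt|/tau-)` when it lags; `A- = 1.05 * A+` gives net
#' depression for uncorrelated spike pairs. Implemented as the all-pairs
#' trace scheme. The weight-dependent variant scales potentiation by
#' `(w/w_max)^mu` and makes depression proportional to `w/w_max`
#' (Morrison-style multiplicative form), yielding a unimodal weight
#' distribution. Global homeostasis multiplies every plastic weight by
#' `1 + dt * (R_target - Rbar) / tau_h` each step, where `Rbar` is the mean
#' excitatory firing rate over the trailing `rate_window`. Weights are
#' clipped to `[0, w_max]` after every update.
#'
#' @param rule `"additive"` or `"weight_dependent"`.
#' @param a_plus Potentiation amplitude (default 0.005).
#' @param a_minus Depression amplitude (default `1.05 * a_plus`).
#' @param tau_plus,tau_minus STDP time constants, ms (default 20).
#' @param w_max Hard weight bound (default 0.013).
#' @param tau_h Homeostatic time constant, ms (default 2000, the sped-up
#'   developmental value).
#' @param r_target Homeostatic target mean rate, Hz (default 1.5).
#' @param rate_window Trailing window for the rate estimate, ms (default 500).
#' @param mu Weight exponent of the weight-dependent rule (default 0.4).
#' @param alpha Depression scale of the weight-dependent rule (default 1,
#'   the plain multiplicative form); its fixed point is
#'   `w_max (A+ / (alpha A-))^(1/(1-mu))`.
#' @param homeostasis Apply the homeostatic scaling (default TRUE).
#' @return A list of class `plasticity_config`.
#' @export
plasticity_config <- function(rule = c("additive", "weight_dependent"),
                              a_plus = 0.005, a_minus = 1.05 * a_plus,
                              tau_plus = 20, tau_minus = 20, w_max = 0.013,
                              tau_h = 2000, r_target = 1.5, rate_window = 500,
                              mu = 0.4, alpha = 1, homeostasis = TRUE) {
  rule <- match.arg(rule)
  stopifnot(a_minus > a_plus, tau_plus > 0, tau_minus > 0, w_max > 0,
            tau_h > 0, rate_window > 0)
  structure(list(rule = rule,
                 rule_code = if (rule == "additive") 1L else 2L,
                 a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, w_max = w_max, tau_h = tau_h,
                 r_target = r_target, rate_window = rate_window, mu = mu,
                 alpha = alpha, homeostasis = homeostasis),
            class = "plasticity_config")
}

# CSR representation handed to the C++ core (0-based)
compile_network <- function(network) {
  ord <- order(network$edges$pre, network$edges$post)
  pre <- network$edges$pre[ord]
  list(n = network$n, n_exc = network$n_exc,
       out_ptr = c(0L, cumsum(tabulate(pre, nbins = network$n))),
       out_post = network$edges$post[ord] - 1L,
       w = network$edges$weight[ord],
       edge_order = ord,
       a = network$neurons$a, b = network$neurons$b,
       c = network$neurons$c, d = network$neurons$d,
       i_fluc_mean = network$neurons$i_fluc_mean,
       i_fluc_sd = network$neurons$i_fluc_sd)
}

#' Simulate an Izhikevich network
#'
#' Euler integration of the membrane potential at `dt_v` (two substeps per
#' slow step by default) and of the recovery variable and conductances at
#' `dt`. Each neuron receives the sum of a white-noise current (per-neuron
#' mean frozen at construction, per-step spread set by [wire_network()]),
#' Poisson background current pulses (amplitude 15 for one slow step,
#' excitatory neurons only), the stimulation current and conductance-based
#' synaptic input `sum_i w_ij g_i (E_rev,i - v_j)`. Spikes are detected at
#' `v >= 30` at slow-step boundaries, after which `v <- c` and `u <- u + d`.
#'
#' The simulation is deterministic given `seed` (an internal generator is
#' used, independent of R's RNG stream) and its full state -- including the
#' generator -- can be snapshotted and restored: continuing from
#' `$state` reproduces the uninterrupted trajectory bit-exactly.
#'
#' @param network An `snn_network`.
#' @param duration_ms Simulated time in ms.
#' @param bg_rate Background Poisson event rate per excitatory neuron, Hz.
#' @param seed Integer seed for the simulator's generator (required unless
#'   `state` is given; ignored when resuming from a snapshot).
#' @param stim A [stim_protocol()] or NULL.
#' @param plasticity A [plasticity_config()] or NULL (weights frozen).
#' @param state A snapshot from a previous run's `$state` to resume from.
#' @param dt,dt_v Slow and membrane time steps in ms (defaults 0.1 / 0.05).
#' @param fluc Apply the white-noise current (default TRUE; FALSE gives the
#'   fully noise-free condition).
#' @param fluc_scale Multiplier on the white-noise standard deviation
#'   (`0` keeps only the frozen per-neuron mean; default 1).
#' @param bg_amp Background event amplitude (default 15).
#' @param bg_size Number of pyramidal cells hit simultaneously by one
#'   background event (default 1: independent single spikes; larger values
#'   model correlated input volleys). The network-wide event rate is scaled
#'   so each neuron still receives `bg_rate` pulses per second on average.
#' @param bg_mode `"kick"` (default): each background event depolarizes its
#'   target by `bg_amp`, making a single event suprathreshold for a resting
#'   pyramidal cell (the 15 exceeds its 10 mV distance to threshold);
#'   `"current"`: `bg_amp` is injected as a current for one slow step
#'   (depositing only `bg_amp * dt`, dynamically negligible).
#' @return An object of class `snn_sim`: list with `raster` (tibble:
#'   `time_ms`, `neuron`, `cell_type`), `state` (snapshot), `network` (with
#'   updated weights when plasticity was on), `duration_ms`, `dt`.
#' @examples
#' set.seed(1)
#' net <- build_network(degree_spec(80, 0.05, "UCOR"), n_pv = 10, n_sst = 10)
#' sim <- simulate_network(net, 200, bg_rate = 0.1, seed = 7)
#' nrow(sim$raster)
#' @export
simulate_network <- function(network, duration_ms, bg_rate = 0, seed = NULL,
                             stim = NULL, plasticity = NULL, state = NULL,
                             dt = 0.1, dt_v = 0.05, fluc = TRUE,
                             fluc_scale = 1, bg_amp = 15, bg_size = 1,
                             bg_mode = c("kick", "current")) {
  bg_mode <- match.arg(bg_mode)
  stopifnot(inherits(network, "snn_network"), duration_ms > 0, bg_rate >= 0)
  if (is.null(state) && is.null(seed))
    stop("either a seed or a state snapshot must be supplied")
  if (abs(dt / dt_v - round(dt / dt_v)) > 1e-9)
    stop("dt_v must divide dt")
  comp <- attr(network, "compiled")
  if (is.null(comp)) comp <- compile_network(network)

  stim_neurons <- integer(0)
  stim_amp <- 0; stim_start <- 0; stim_dur <- 0
  if (!is.null(stim)) {
    stopifnot(inherits(stim, "stim_protocol"))
    stim_neurons <- stim$neurons - 1L
    stim_amp <- stim$amplitude
    stim_start <- stim$onset_ms
    stim_dur <- stim$duration_ms
  }

  res <- cpp_simulate(comp, duration_ms, dt_v, dt, bg_rate, bg_amp, bg_size,
                      stim_neurons, stim_amp, stim_start, stim_dur,
                      bg_mode == "kick", fluc, fluc_scale,
                      plasticity, state, if (is.null(seed)) 0 else seed)

  neuron <- res$spike_neuron + 1L
  raster <- tibble::tibble(
    time_ms = (res$spike_step + 1L) * dt,
    neuron = neuron,
    cell_type = network$neurons$type[neuron])

  if (!is.null(plasticity)) {
    w_new <- res$w
    network$edges$weight[comp$edge_order] <- w_new
    comp$w <- w_new
  }
  attr(network, "compiled") <- comp
  structure(list(raster = raster, state = res$state, network = network,
                 duration_ms = duration_ms, dt = dt),
            class = "snn_sim")
}

#' @export
print.snn_sim <- function(x, ...) {
  cat(sprintf("snn_sim: %g ms, %d spikes (%.3g Hz per neuron overall)\n",
              x$duration_ms, nrow(x$raster),
              nrow(x$raster) / x$network$n / (x$duration_ms / 1000)))
  invisible(x)
}

#' Trace-based STDP on a single synapse with prescribed spike trains
#'
#' Runs the exact per-step trace update used inside the network simulator on
#' one synapse, given explicit pre- and postsynaptic spike times. Intended
#' for validating the rule against the explicit all-pairs pair sum and for
#' exploring the pairing function.
#'
#' @param pre_ms,post_ms Spike times in ms.
#' @param w0 Initial weight.
#' @param cfg A [plasticity_config()].
#' @param duration_ms Train length (default: past the last spike).
#' @param dt Slow step, ms.
#' @return Final weight (scalar).
#' @export
stdp_train <- function(pre_ms, post_ms, w0, cfg = plasticity_config(),
                       duration_ms = NULL, dt = 0.1) {
  if (is.null(duration_ms)) duration_ms <- max(pre_ms, post_ms, 0) + dt
  n_steps <- as.integer(round(duration_ms / dt))
  res <- cpp_stdp_train(as.integer(round(pre_ms / dt)) ,
                        as.integer(round(post_ms / dt)),
                        w0, dt, cfg$rule_code, cfg$a_plus, cfg$a_minus,
                        cfg$tau_plus, cfg$tau_minus, cfg$w_max, cfg$mu,
                        cfg$alpha, n_steps)
  res$w
}

#' Conductance-based synaptic current
#'
#' The instantaneous current each postsynaptic neuron receives,
#' `I_j = sum_i w_ij g_i (E_rev,i - v_j)`: presynaptic conductances are
#' weighted by the synaptic strength and driven by the distance of the
#' postsynaptic membrane potential from the presynaptic cell's reversal
#' potential. This is the same quantity the simulator core computes every
#' slow step.
#'
#' @param w Weight matrix (`n x n`, `w[i, j]` from presynaptic `i` to
#'   postsynaptic `j`).
#' @param g Presynaptic conductances (length `n`).
#' @param e_rev Presynaptic reversal potentials (length `n`; 0 excitatory,
#'   -80 inhibitory).
#' @param v Postsynaptic membrane potentials (length `n`).
#' @return Numeric vector of per-neuron synaptic currents.
#' @examples
#' synaptic_current(matrix(1), g = 1, e_rev = 0, v = -70)  # +70
#' @export
synaptic_current <- function(w, g, e_rev, v) {
  w <- as.matrix(w)
  stopifnot(nrow(w) == length(g), nrow(w) == length(e_rev),
            ncol(w) == length(v))
  drop(crossprod(w, g * e_rev)) - drop(crossprod(w, g)) * v
}

#' Mean firing rate of a raster
#'
#' Spike count divided by (number of neurons x window length).
#'
#' @param raster Raster tibble (`time_ms`, `neuron`) or an `snn_sim`.
#' @param n_neurons Number of neurons the rate is normalized by.
#' @param window Length-2 numeric `c(t0, t1)` in ms; spikes with
#'   `t0 < time_ms <= t1` are counted. Default: the full raster extent.
#' @param neurons Optional subset of neuron ids to count.
#' @return Rate in Hz.
#' @export
firing_rate <- function(raster, n_neurons, window = NULL, neurons = NULL) {
  if (inherits(raster, "snn_sim")) {
    if (is.null(window)) window <- c(0, raster$duration_ms)
    raster <- raster$raster
  }
  if (is.null(window)) window <- c(0, max(raster$time_ms, 1))
  if (diff(window) <= 0) stop("window must have positive length")
  t <- raster$time_ms
  keep <- t > window[1] & t <= window[2]
  if (!is.null(neurons)) keep <- keep & raster$neuron %in% neurons
  sum(keep) / n_neurons / (diff(window) / 1000)
}
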
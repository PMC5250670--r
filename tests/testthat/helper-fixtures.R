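# small fixtures shared across test files

tiny_spec <- function(corr_type = "UCOR", n_exc = 120, p = 0.1) {
  degree_spec(n_exc, p, corr_type)
}

# small but dynamically faithful network (same per-type proportions)
tiny_network <- function(corr_type = "UCOR", n_exc = 120, p = 0.1, ...) {
  build_network(degree_spec(n_exc, p, corr_type), n_pv = 15, n_sst = 15, ...)
}

# a two-neuron "network" holding isolated cells with prescribed drive;
# useful for single-neuron dynamics tests
isolated_neurons <- function(i_mean, a = 0.02, b = 0.2, c = -65, d = 8,
                             i_sd = 0) {
  n <- length(i_mean)
  structure(list(
    neurons = tibble::tibble(id = seq_len(n), type = "Pyr", a = a, b = b,
                             c = c, d = d, i_fluc_mean = i_mean,
                             i_fluc_sd = i_sd),
    edges = tibble::tibble(pre = integer(0), post = integer(0),
                           weight = numeric(0)),
    n = as.integer(n), n_exc = as.integer(n), n_pv = 0L, n_sst = 0L,
    params = list()), class = "snn_network")
}

# reference Euler integration of a single Izhikevich neuron at a fine step,
# independent of the package's C++ core
reference_izhikevich <- function(I, duration_ms, dt = 0.001,
                                 a = 0.02, b = 0.2, c = -65, d = 8,
                                 v0 = NULL, u0 = NULL) {
  disc <- (5 - b)^2 - 0.16 * (140 + 0)
  if (is.null(v0)) v0 <- (-(5 - b) - sqrt(disc)) / 0.08
  if (is.null(u0)) u0 <- b * v0
  v <- v0; u <- u0
  spikes <- numeric(0)
  steps <- round(duration_ms / dt)
  for (k in seq_len(steps)) {
    v <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
    u <- u + dt * a * (b * v - u)
    if (v >= 30) {
      spikes <- c(spikes, k * dt)
      v <- c; u <- u + d
    }
  }
  spikes
}

# explicit all-pairs STDP sum (the independent oracle for the trace scheme):
# every pre/post spike pair contributes A+ e^{-|dt|/tau+} when the pre spike
# leads, and -A- e^{-|dt|/tau-} when it lags; simultaneous spikes contribute
# nothing. Pair times are quantized to the slow step like the simulator's.
allpairs_stdp <- function(pre_ms, post_ms, cfg, dt = 0.1) {
  pre <- round(pre_ms / dt) * dt
  post <- round(post_ms / dt) * dt
  dw <- 0
  for (tp in pre) for (tq in post) {
    if (tp < tq) dw <- dw + cfg$a_plus * exp(-(tq - tp) / cfg$tau_plus)
    if (tp > tq) dw <- dw - cfg$a_minus * exp(-(tp - tq) / cfg$tau_minus)
  }
  dw
}
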
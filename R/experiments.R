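#' Group means, SEM and a two-sided t-test
#'
#' Per-group mean and standard error; when exactly two groups are present a
#' two-sided pooled-variance t-test between them is attached (the classical
#' two-sample test used throughout the study).
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the values and grouping.
#' @return Tibble with `group`, `n`, `mean`, `sem`; for two groups, the
#'   t-test p-value is in `attr(, "p_value")`.
#' @export
aggregate_stats <- function(data, value, group) {
  v <- data[[value]]
  g <- data[[group]]
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(g = g, v = v), g),
    n = dplyr::n(),
    mean = mean(v),
    sem = stats::sd(v) / sqrt(dplyr::n()),
    .groups = "drop")
  names(out)[1] <- group
  if (dplyr::n_distinct(g) == 2) {
    gs <- unique(g)
    if (all(out$n >= 2)) {
      attr(out, "p_value") <-
        stats::t.test(v[g == gs[1]], v[g == gs[2]], var.equal = TRUE)$p.value
    }
  }
  out
}

#' Stability sweep: burst rate and firing rate versus background noise
#'
#' For each correlation type and background rate, networks are built from a
#' shared degree specification, simulated, and the network burst rate (from
#' the excitatory spike-density trace) and mean excitatory firing rate are
#' recorded.
#'
#' @param corr_types Character vector of correlation types.
#' @param bg_rates Background rates per neuron, Hz.
#' @param n_networks Network realizations per type.
#' @param duration_ms Simulated time per (network, rate) cell.
#' @param seed Seed for the whole sweep (network construction and dynamics).
#' @param n_exc,p Degree specification shared by all types.
#' @param skip_ms Transient discarded before analysis (default 200 ms).
#' @param ... Passed to [build_network()] (e.g. `w_ee`, `w_inh`).
#' @return Tibble: `corr_type`, `network`, `bg_rate`, `burst_rate` (1/s),
#'   `mean_rate` (Hz).
#' @export
stability_sweep <- function(corr_types = c("ACOR", "UCOR", "XCOR", "PCOR"),
                            bg_rates = seq(0.07, 0.11, by = 0.01),
                            n_networks = 10, duration_ms = 10000, seed = 1,
                            n_exc = 480, p = 0.05, skip_ms = 200, ...) {
  set.seed(seed)
  grid <- tidyr::expand_grid(corr_type = corr_types, network = seq_len(n_networks))
  sim_seeds <- matrix(sample.int(2^31 - 2, nrow(grid) * length(bg_rates)),
                      nrow = nrow(grid))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    net <- build_network(degree_spec(n_exc, p, grid$corr_type[i]), ...)
    purrr::map_dfr(seq_along(bg_rates), function(j) {
      sim <- simulate_network(net, duration_ms, bg_rate = bg_rates[j],
                              seed = sim_seeds[i, j])
      br <- burst_rate(sim, skip_ms = skip_ms)
      tibble::tibble(
        corr_type = grid$corr_type[i], network = grid$network[i],
        bg_rate = bg_rates[j], burst_rate = br$rate,
        mean_rate = firing_rate(sim, net$n_exc, c(skip_ms, duration_ms),
                                neurons = seq_len(net$n_exc)))
    })
  })
}

#' Sensitivity sweep over recurrent excitatory strength
#'
#' Each network is stimulated once per recurrent-strength value: a 25 ms,
#' amplitude-8 pulse into `n_stim` pyramidal cells sampled from the
#' near-mean-out-degree pool, at a background rate low enough that no
#' spontaneous bursts occur. Burst detection excludes the stimulated neurons.
#'
#' @param w_ee_grid Recurrent strengths (default 25 values, 0.015 to 0.04).
#' @param corr_types Correlation types to compare.
#' @param n_networks Realizations per type.
#' @param bg_rate Background rate, Hz (default 0.07).
#' @param n_stim Stimulated neuron count (default 6).
#' @param settle_ms Pre-stimulus simulation time (default 200 ms).
#' @param observe_ms Post-onset window searched for a burst (default 150 ms).
#' @param seed Sweep seed.
#' @param n_exc,p Degree specification.
#' @param ... Passed to [build_network()].
#' @return Tibble: `corr_type`, `network`, `w_ee`, `burst` (logical),
#'   `peak_rate`, `latency_ms` (onset to density peak; NA without a burst).
#' @export
sensitivity_sweep <- function(w_ee_grid = seq(0.015, 0.04, length.out = 25),
                              corr_types = "UCOR", n_networks = 15,
                              bg_rate = 0.07, n_stim = 6, settle_ms = 200,
                              observe_ms = 150, seed = 1,
                              n_exc = 480, p = 0.05, ...) {
  set.seed(seed)
  grid <- tidyr::expand_grid(corr_type = corr_types, network = seq_len(n_networks))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    net0 <- build_network(degree_spec(n_exc, p, grid$corr_type[i]), ...)
    pool <- stim_candidates(net0)
    sim_seeds <- sample.int(2^31 - 2, length(w_ee_grid))
    purrr::map_dfr(seq_along(w_ee_grid), function(j) {
      net <- set_w_ee(net0, w_ee_grid[j])
      targets <- sample(pool, n_stim)
      sim <- simulate_network(
        net, settle_ms + observe_ms, bg_rate = bg_rate, seed = sim_seeds[j],
        stim = stim_protocol(targets, amplitude = 8, onset_ms = settle_ms,
                             duration_ms = 25))
      dens <- spike_density(sim$raster, t_range = c(settle_ms - 10, settle_ms + observe_ms),
                            neurons = seq_len(net$n_exc), exclude = targets)
      bursts <- detect_bursts(dens)
      bursts <- bursts[bursts$t_end >= settle_ms, , drop = FALSE]
      hit <- nrow(bursts) > 0
      tibble::tibble(
        corr_type = grid$corr_type[i], network = grid$network[i],
        w_ee = w_ee_grid[j], burst = hit,
        peak_rate = max(dens$density[dens$t >= settle_ms]),
        latency_ms = if (hit) bursts$peak_time[which.max(bursts$peak_rate)] - settle_ms
                     else NA_real_)
    })
  })
}

#' Burst-probability threshold of a sensitivity sweep
#'
#' Smallest recurrent strength at and above which every stimulation evoked a
#' detected burst (burst probability 1 for that grid point and all larger
#' ones).
#'
#' @param sweep Result of [sensitivity_sweep()].
#' @return The threshold `w_ee` (NA when never consistently bursting).
#' @export
consistent_burst_threshold <- function(sweep) {
  prob <- dplyr::summarise(dplyr::group_by(sweep, .data$w_ee),
                           p = mean(.data$burst), .groups = "drop")
  prob <- prob[order(prob$w_ee), ]
  all_one <- rev(cumprod(rev(prob$p == 1))) == 1
  if (!any(all_one)) return(NA_real_)
  prob$w_ee[which(all_one)[1]]
}

#' Paired state-reset ROC stimulus-detection experiment
#'
#' Stimulation is applied every `window_ms` (70 ms): at the start of each
#' window the full network state and random generator are snapshotted, the
#' window is simulated once without and once with stimulation (identical
#' noise by construction), and the baseline end-state seeds the next window.
#' The per-window statistic is the maximum of the excitatory spike-density
#' trace inside the 60 ms detection window (the 5 ms before stimulus onset
#' and the final 5 ms are discarded to avoid smoothing leakage), with
#' stimulated neurons excluded. Sweeping a threshold over all observed
#' statistics yields the empirical ROC; with 0 stimulated neurons the paired
#' trajectories are identical and the AUC is exactly 0.5.
#'
#' @param network An `snn_network`.
#' @param bg_rate Background rate per neuron, Hz.
#' @param n_stim Number of stimulated neurons per window (0 to 6), freshly
#'   sampled each window from the near-mean-out-degree pool.
#' @param n_windows Number of 70 ms windows (fewer than 20 is flagged as
#'   under-powered).
#' @param seed Experiment seed (dynamics and per-window target sampling).
#' @param window_ms,detect_ms,pre_ms Window geometry (defaults 70/60/5 ms).
#' @param stim_amp,stim_dur_ms Stimulus parameters (defaults 8, 25 ms).
#' @param settle_ms Warm-up before the first window (default 200 ms).
#' @return An object of class `snn_roc`: list with `stats` (tibble: `window`,
#'   `baseline`, `stimulated`), `curve` (tibble: `threshold`, `fpr`, `tpr`),
#'   `auc`, `n_stim`, `n_windows`.
#' @export
roc_experiment <- function(network, bg_rate = 0.098, n_stim = 4,
                           n_windows = 120, seed = 1, window_ms = 70,
                           detect_ms = 60, pre_ms = 5, stim_amp = 8,
                           stim_dur_ms = 25, settle_ms = 200) {
  stopifnot(n_stim >= 0, n_stim <= 10)
  if (n_windows < 20)
    warning("fewer than 20 windows: ROC estimate is under-powered")
  set.seed(seed)
  pool <- stim_candidates(network)
  exc_ids <- seq_len(network$n_exc)

  warm <- simulate_network(network, settle_ms, bg_rate = bg_rate,
                           seed = sample.int(2^31 - 2, 1))
  state <- warm$state
  network <- warm$network  # carries the compiled representation

  stat_of <- function(sim, targets) {
    dens <- spike_density(sim$raster, t_range = c(pre_ms, pre_ms + detect_ms),
                          neurons = exc_ids, exclude = targets)
    max(dens$density)
  }

  res <- purrr::map_dfr(seq_len(n_windows), function(wi) {
    targets <- if (n_stim > 0) sample(pool, n_stim) else integer(0)
    base <- simulate_network(network, window_ms, bg_rate = bg_rate, state = state)
    stim <- simulate_network(network, window_ms, bg_rate = bg_rate, state = state,
                             stim = stim_protocol(targets, amplitude = stim_amp,
                                                  onset_ms = pre_ms,
                                                  duration_ms = stim_dur_ms))
    state <<- base$state
    tibble::tibble(window = wi,
                   baseline = stat_of(base, targets),
                   stimulated = stat_of(stim, targets))
  })

  curve <- roc_curve(res$baseline, res$stimulated)
  structure(list(stats = res, curve = curve, auc = roc_auc(curve),
                 n_stim = n_stim, n_windows = n_windows, bg_rate = bg_rate),
            class = "snn_roc")
}

# empirical ROC over all observed statistic values (plus infinite endpoints)
roc_curve <- function(baseline, stimulated) {
  thr <- c(-Inf, sort(unique(c(baseline, stimulated))), Inf)
  tibble::tibble(
    threshold = thr,
    fpr = vapply(thr, function(th) mean(baseline >= th), 0),
    tpr = vapply(thr, function(th) mean(stimulated >= th), 0))
}

# trapezoidal area under the empirical ROC
roc_auc <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  x <- curve$fpr[o]; y <- curve$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.snn_roc <- function(x, ...) {
  cat(sprintf("snn_roc: %d windows, %d stimulated neurons, AUC = %.4f\n",
              x$n_windows, x$n_stim, x$auc))
  invisible(x)
}

#' Detectability across conditions
#'
#' Runs the ROC experiment over a grid of correlation types crossed with one
#' varying condition (background rate, connection probability or excitatory
#' network size) and returns one AUC per network realization.
#'
#' @param corr_types Correlation types.
#' @param condition Name of the varied condition: `"bg_rate"`, `"p"` or
#'   `"n_exc"`.
#' @param values Values of the varied condition.
#' @param n_networks Realizations per cell.
#' @param n_stim Stimulated neurons (default 4).
#' @param n_windows Windows per ROC (default 40).
#' @param seed Sweep seed.
#' @param bg_rate,p,n_exc Fixed values for the conditions not varied.
#' @param ... Passed to [build_network()].
#' @return Tibble: `corr_type`, `<condition>`, `network`, `auc`.
#' @export
detection_vs_condition <- function(corr_types = c("ACOR", "PCOR"),
                                   condition = c("bg_rate", "p", "n_exc"),
                                   values, n_networks = 10, n_stim = 4,
                                   n_windows = 40, seed = 1,
                                   bg_rate = 0.098, p = 0.05, n_exc = 480, ...) {
  condition <- match.arg(condition)
  set.seed(seed)
  grid <- tidyr::expand_grid(corr_type = corr_types, value = values,
                             network = seq_len(n_networks))
  grid$seed <- sample.int(2^31 - 2, nrow(grid))
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cfg <- list(bg_rate = bg_rate, p = p, n_exc = n_exc)
    cfg[[condition]] <- grid$value[i]
    net <- build_network(degree_spec(cfg$n_exc, cfg$p, grid$corr_type[i]), ...)
    roc <- roc_experiment(net, bg_rate = cfg$bg_rate, n_stim = n_stim,
                          n_windows = n_windows, seed = grid$seed[i])
    tibble::tibble(corr_type = grid$corr_type[i], value = grid$value[i],
                   network = grid$network[i], auc = roc$auc)
  })
  names(out)[names(out) == "value"] <- condition
  out
}
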
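test_that("group aggregation returns means, SEM and a pooled t-test", {
  df <- tibble::tibble(g = rep(c("a", "b"), each = 3), v = c(1, 2, 3, 1, 2, 3))
  out <- aggregate_stats(df, "v", "g")
  expect_equal(out$mean, c(2, 2))
  expect_equal(out$sem, rep(stats::sd(1:3) / sqrt(3), 2))
  expect_equal(attr(out, "p_value"), 1)

  df2 <- tibble::tibble(g = rep(c("a", "b"), each = 3), v = c(0, 0, 0.01, 1, 1, 0.99))
  expect_lt(attr(aggregate_stats(df2, "v", "g"), "p_value"), 0.01)
})

test_that("the empirical ROC handles separation, ties and monotone transforms", {
  # perfectly separated statistics give AUC 1
  curve <- snncorr:::roc_curve(1:10, 11:20)
  expect_equal(snncorr:::roc_auc(curve), 1)
  # identical paired statistics give AUC exactly 0.5
  x <- c(0.3, 1.7, 2.2, 5)
  expect_identical(snncorr:::roc_auc(snncorr:::roc_curve(x, x)), 0.5)
  # AUC is invariant under strictly monotone transforms of the statistic
  set.seed(3)
  b <- rnorm(50); s <- rnorm(50, 0.8)
  a1 <- snncorr:::roc_auc(snncorr:::roc_curve(b, s))
  a2 <- snncorr:::roc_auc(snncorr:::roc_curve(exp(b), exp(s)))
  expect_equal(a1, a2)
  # ROC curve is monotone
  expect_true(all(diff(curve$fpr) <= 0))
  expect_true(all(diff(curve$tpr) <= 0))
})

test_that("the state-reset protocol gives AUC exactly 0.5 with no stimulated neurons", {
  set.seed(4)
  net <- tiny_network()
  roc <- roc_experiment(net, bg_rate = 0.2, n_stim = 0, n_windows = 24,
                        seed = 11)
  expect_identical(roc$auc, 0.5)
  # paired trajectories are bit-identical window by window
  expect_identical(roc$stats$baseline, roc$stats$stimulated)
})

test_that("zero-amplitude stimulation is equivalent to no stimulation", {
  set.seed(5)
  net <- tiny_network()
  roc <- roc_experiment(net, bg_rate = 0.2, n_stim = 4, n_windows = 20,
                        seed = 13, stim_amp = 0)
  expect_identical(roc$auc, 0.5)
})

test_that("roc tidiers expose the curve and the summary", {
  set.seed(6)
  net <- tiny_network()
  roc <- roc_experiment(net, bg_rate = 0.2, n_stim = 2, n_windows = 20, seed = 2)
  expect_true(all(c("threshold", "fpr", "tpr") %in% names(tidy(roc))))
  g <- glance(roc)
  expect_equal(g$n_stim, 2)
  expect_true(g$auc >= 0 && g$auc <= 1)
})

test_that("the consistent-burst threshold scans from the top of the grid", {
  sweep <- tidyr::expand_grid(w_ee = c(0.01, 0.02, 0.03, 0.04), network = 1:2)
  sweep$burst <- sweep$w_ee >= 0.03
  expect_equal(consistent_burst_threshold(sweep), 0.03)
  # a failure at a grid point invalidates it and everything below
  sweep$burst <- sweep$w_ee >= 0.02 & !(sweep$w_ee == 0.03 & sweep$network == 2)
  expect_equal(consistent_burst_threshold(sweep), 0.04)
  sweep$burst <- FALSE
  expect_true(is.na(consistent_burst_threshold(sweep)))
})

test_that("stability and sensitivity sweeps return tidy per-network tables", {
  res <- stability_sweep(corr_types = c("ACOR"), bg_rates = c(0, 0.2),
                         n_networks = 2, duration_ms = 1500, seed = 3,
                         n_exc = 120, p = 0.1, n_pv = 15, n_sst = 15)
  expect_equal(nrow(res), 4)
  expect_true(all(res$burst_rate >= 0))
  # without background events the network is quiescent: no bursts
  expect_true(all(res$burst_rate[res$bg_rate == 0] == 0))
  expect_true(all(res$mean_rate[res$bg_rate == 0.2] >
                    res$mean_rate[res$bg_rate == 0]))

  sens <- sensitivity_sweep(w_ee_grid = c(0.015, 0.04), corr_types = "UCOR",
                            n_networks = 2, bg_rate = 0.05, n_stim = 3,
                            seed = 4, n_exc = 120, p = 0.1,
                            n_pv = 15, n_sst = 15)
  expect_equal(nrow(sens), 4)
  expect_type(sens$burst, "logical")
  expect_true(all(is.na(sens$latency_ms) | sens$latency_ms >= 0))
})

test_that("the condition sweep returns one AUC per network and condition cell", {
  res <- detection_vs_condition(corr_types = "UCOR", condition = "bg_rate",
                                values = 0.2, n_networks = 2, n_stim = 2,
                                n_windows = 20, seed = 8,
                                n_exc = 120, p = 0.1, n_pv = 15, n_sst = 15)
  expect_equal(nrow(res), 2)
  expect_true(all(c("corr_type", "bg_rate", "network", "auc") %in% names(res)))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
})
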
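test_that("isolated pre/post pairings follow the pairing function", {
  cfg <- plasticity_config("additive")
  # pre leads post by 20 ms: potentiation A+ e^{-1}
  dw <- stdp_train(pre_ms = 100, post_ms = 120, w0 = 0.006, cfg = cfg) - 0.006
  expect_equal(dw, 0.005 * exp(-1), tolerance = 1e-12)
  # post leads pre by one step: depression close to -A-
  dw2 <- stdp_train(pre_ms = 100.1, post_ms = 100, w0 = 0.006, cfg = cfg) - 0.006
  expect_equal(dw2, -0.00525 * exp(-0.1 / 20), tolerance = 1e-12)
  # simultaneous spikes contribute nothing
  dw3 <- stdp_train(pre_ms = 100, post_ms = 100, w0 = 0.006, cfg = cfg) - 0.006
  expect_equal(dw3, 0)
})

test_that("the trace implementation equals the explicit all-pairs sum", {
  # a wide weight bound keeps the trajectory away from clipping, where the
  # trace scheme and the raw pair sum must agree to numerical precision
  cfg <- plasticity_config("additive", w_max = 1)
  set.seed(31)
  for (i in 1:5) {
    pre <- sort(sample(seq(0, 400, by = 0.1), 12))
    post <- sort(sample(seq(0, 400, by = 0.1), 10))
    got <- stdp_train(pre, post, w0 = 0.5, cfg = cfg, duration_ms = 450)
    want <- 0.5 + allpairs_stdp(pre, post, cfg)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("uncorrelated Poisson pre/post trains drift towards depression", {
  cfg <- plasticity_config("additive")
  # A+ tau+ < A- tau- makes the expected pairing integral negative
  expect_lt(cfg$a_plus * cfg$tau_plus - cfg$a_minus * cfg$tau_minus, 0)
  set.seed(32)
  drift <- replicate(100, {
    pre <- cumsum(stats::rexp(200, 1 / 50))   # ~20 Hz for ~10 s
    post <- cumsum(stats::rexp(200, 1 / 50))
    allpairs_stdp(pre, post, cfg)
  })
  expect_lt(mean(drift), 0)
})

test_that("the weight-dependent rule vanishes at w = 0 and stays unimodal in shape", {
  cfg <- plasticity_config("weight_dependent")
  # depression proportional to w: no change from zero weight
  w <- stdp_train(pre_ms = 100.1, post_ms = 100, w0 = 0, cfg = cfg)
  expect_equal(w, 0)
  # potentiation scaled below the additive amount for w < w_max
  dw_wd <- stdp_train(100, 120, w0 = 0.0065, cfg = cfg) - 0.0065
  dw_add <- stdp_train(100, 120, w0 = 0.0065,
                       cfg = plasticity_config("additive")) - 0.0065
  expect_lt(dw_wd, dw_add)
  expect_gt(dw_wd, 0)
})

test_that("homeostatic scaling grows weights at (R_tar - R)/tau_h when the network is silent", {
  set.seed(33)
  net <- tiny_network(w_ee = 0.006)
  cfg <- plasticity_config("additive")
  sim <- simulate_network(net, 200, bg_rate = 0, seed = 3, fluc = FALSE,
                          plasticity = cfg)
  expect_equal(nrow(sim$raster), 0)
  ee <- sim$network$edges$pre <= 120 & sim$network$edges$post <= 120
  w_new <- sim$network$edges$weight[ee]
  # R = 0 for the whole run: every plastic weight multiplied by
  # (1 + dt (1.5 - 0) / tau_h) each slow step
  expected <- 0.006 * (1 + 0.1 * 1.5 / 2000)^2000
  expect_equal(unique(round(w_new, 12)), round(expected, 12))
  # clipped at the hard bound
  expect_true(all(w_new <= cfg$w_max + 1e-15))
  # non-plastic weights untouched
  expect_equal(sim$network$edges$weight[!ee], net$edges$weight[!ee])
})

test_that("weights stay inside [0, w_max] throughout a plastic simulation", {
  set.seed(34)
  net <- tiny_network(p = 0.15)
  cfg <- plasticity_config("additive")
  sim <- simulate_network(net, 300, bg_rate = 0.3, seed = 9, plasticity = cfg)
  for (k in 1:4) {
    sim <- simulate_network(sim$network, 300, bg_rate = 0.3,
                            state = sim$state, plasticity = cfg)
    ee <- sim$network$edges$pre <= 120 & sim$network$edges$post <= 120
    w <- sim$network$edges$weight[ee]
    expect_true(all(w >= 0 & w <= cfg$w_max + 1e-15))
    expect_gt(stats::sd(w), 0)  # STDP is actually differentiating weights
  }
})

test_that("pruning keeps exactly the strongest synapses at the target connectivity", {
  set.seed(35)
  net <- tiny_network(p = 0.1)
  ne <- net$n_exc
  ee <- which(net$edges$pre <= ne & net$edges$post <= ne)
  net$edges$weight[ee] <- stats::runif(length(ee))
  pruned <- prune_to_connectivity(net, p_final = 0.05)
  kept <- pruned$edges[pruned$edges$pre <= ne & pruned$edges$post <= ne, ]
  n_target <- round(0.05 * ne * (ne - 1))
  expect_equal(nrow(kept), n_target)
  # the kept weights are the largest ones
  expect_equal(sort(kept$weight),
               sort(net$edges$weight[ee], decreasing = TRUE)[seq_len(n_target)] |> sort())
  # non-excitatory connections untouched
  expect_equal(sum(pruned$edges$pre > ne | pruned$edges$post > ne),
               sum(net$edges$pre > ne | net$edges$post > ne))
})

test_that("a short development run reorganizes weights and reaches exact connectivity", {
  dev <- development_experiment(seed = 5, duration_s = 3, n_exc = 120,
                                n_pv = 15, n_sst = 15)
  expect_s3_class(dev, "snn_development")
  kept <- dev$network$edges[dev$network$edges$pre <= 120 &
                              dev$network$edges$post <= 120, ]
  expect_equal(nrow(kept), round(0.05 * 120 * 119))
  expect_false(dev$runaway)
  g <- glance(dev)
  expect_true(all(c("mean_rate", "lsr_slope", "quadrant_stat") %in% names(g)))
  expect_equal(nrow(tidy(dev)), 120)
})
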
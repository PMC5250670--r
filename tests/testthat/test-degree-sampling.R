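test_that("degree_spec derives the distribution geometry from n and p", {
  spec <- degree_spec(480, 0.05, "ACOR")
  expect_equal(spec$mu, 24)
  expect_equal(spec$sigma_long, 8)
  expect_equal(spec$sigma_short, 2.4)
  expect_equal(spec$lower, 1)
  expect_equal(spec$upper, 47)
  # 45-degree rotation: equal marginal variances, off-diagonal -(sl^2-ss^2)/2
  expect_equal(spec$sigma[1, 1], spec$sigma[2, 2])
  expect_equal(spec$sigma[1, 2], -(spec$sigma_long^2 - spec$sigma_short^2) / 2)
  expect_gt(degree_spec(480, 0.05, "PCOR")$sigma[1, 2], 0)
  expect_equal(degree_spec(480, 0.05, "UCOR")$sigma[1, 2], 0)
  expect_error(degree_spec(480, 0, "ACOR"))
})

test_that("sampled degrees respect the truncation bounds for every type", {
  set.seed(11)
  for (ct in c("UCOR", "ACOR", "PCOR", "XCOR")) {
    spec <- degree_spec(480, 0.05, ct)
    deg <- sample_joint_degrees(spec)
    expect_equal(nrow(deg), 480)
    expect_true(all(deg$d_in >= spec$lower & deg$d_in <= spec$upper))
    expect_true(all(deg$d_out >= spec$lower & deg$d_out <= spec$upper))
    expect_true(all(deg$d_in == round(deg$d_in)))
  }
})

test_that("correlation structure matches the requested type", {
  set.seed(21)
  spec <- degree_spec(480, 0.05, "PCOR")
  # pool several samples for a tight Monte-Carlo estimate
  pooled <- dplyr::bind_rows(lapply(1:20, function(i) sample_joint_degrees(spec)))
  expect_gt(cor(pooled$d_in, pooled$d_out), 0.8)

  spec_a <- degree_spec(480, 0.05, "ACOR")
  pooled_a <- dplyr::bind_rows(lapply(1:20, function(i) sample_joint_degrees(spec_a)))
  expect_lt(cor(pooled_a$d_in, pooled_a$d_out), -0.8)

  spec_u <- degree_spec(480, 0.05, "UCOR")
  pooled_u <- dplyr::bind_rows(lapply(1:20, function(i) sample_joint_degrees(spec_u)))
  expect_lt(abs(cor(pooled_u$d_in, pooled_u$d_out)), 0.05)
})

test_that("marginal degree distributions are indistinguishable across types", {
  set.seed(31)
  pool <- function(ct) {
    spec <- degree_spec(480, 0.05, ct)
    unlist(lapply(1:20, function(i) sample_joint_degrees(spec)$d_in))
  }
  margins <- lapply(c("UCOR", "ACOR", "PCOR", "XCOR"), pool)
  for (i in 2:4) {
    p <- suppressWarnings(stats::ks.test(margins[[1]], margins[[i]])$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("variance of the summed degree orders ACOR < UCOR < PCOR", {
  set.seed(41)
  vsum <- function(ct) {
    spec <- degree_spec(480, 0.05, ct)
    mean(vapply(1:20, function(i) {
      d <- sample_joint_degrees(spec)
      stats::var(d$d_in + d$d_out)
    }, 0))
  }
  v <- vapply(c("ACOR", "UCOR", "PCOR"), vsum, 0)
  expect_lt(v[["ACOR"]], v[["UCOR"]])
  expect_lt(v[["UCOR"]], v[["PCOR"]])
})

test_that("stub balancing follows the midpoint remove-from-largest/add-to-smallest rule", {
  # hand-traced 6-neuron example: sums 14 vs 19, midpoint 16:
  # remove 3 from the largest out-degrees, add 2 to the smallest in-degrees
  deg <- tibble::tibble(d_in = c(2L, 3L, 1L, 4L, 2L, 2L),
                        d_out = c(4L, 5L, 3L, 3L, 2L, 2L))
  bal <- balance_stubs(deg, lower = 1, upper = 10)
  expect_equal(sum(bal$d_in), sum(bal$d_out))
  expect_equal(bal$d_out, c(3L, 4L, 2L, 3L, 2L, 2L))
  expect_equal(bal$d_in, c(3L, 3L, 2L, 4L, 2L, 2L))
})

test_that("balancing leaves balanced sequences unchanged and handles the mirror case", {
  deg <- tibble::tibble(d_in = c(2L, 2L), d_out = c(2L, 2L))
  expect_identical(balance_stubs(deg), deg)

  # imbalance of 1 changes exactly one degree by 1
  deg1 <- tibble::tibble(d_in = c(2L, 2L), d_out = c(2L, 3L))
  bal1 <- balance_stubs(deg1, lower = 1, upper = 10)
  expect_equal(sum(bal1$d_in), sum(bal1$d_out))
  expect_equal(sum(abs(c(bal1$d_in - deg1$d_in, bal1$d_out - deg1$d_out))), 1)

  # more in-stubs than out-stubs: mirrored rule
  deg2 <- tibble::tibble(d_in = c(5L, 4L, 2L), d_out = c(2L, 2L, 2L))
  bal2 <- balance_stubs(deg2, lower = 1, upper = 10)
  expect_equal(sum(bal2$d_in), sum(bal2$d_out))
  expect_equal(sum(bal2$d_in), (11 + 6) %/% 2)
})

test_that("balancing respects truncation bounds and remove_only mode", {
  set.seed(51)
  spec <- degree_spec(480, 0.05, "PCOR")
  deg <- sample_joint_degrees(spec)
  bal <- balance_stubs(deg, lower = spec$lower, upper = spec$upper)
  expect_true(all(bal$d_in >= 1 & bal$d_in <= 47))
  expect_true(all(bal$d_out >= 1 & bal$d_out <= 47))

  ro <- balance_stubs(deg, lower = spec$lower, upper = spec$upper,
                      mode = "remove_only")
  expect_equal(sum(ro$d_in), sum(ro$d_out))
  expect_equal(sum(ro$d_in), min(sum(deg$d_in), sum(deg$d_out)))
})
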
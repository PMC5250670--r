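#' Specification of a joint in-/out-degree distribution
#'
#' Defines the truncated bivariate Gaussian from which per-neuron
#' (in-degree, out-degree) pairs are drawn for the excitatory subnetwork.
#' The distribution has mean degree `mu = n_exc * p` in both coordinates,
#' a long axis `sigma_long = mu / 3` and a short axis
#' `sigma_short = 0.3 * sigma_long`. Rotating the axis-aligned Gaussian by
#' 45 degrees yields positive (`PCOR`) or negative (`ACOR`) correlation
#' between in- and out-degree; `UCOR` uses the matched diagonal covariance
#' (equal marginal variances) with the out-degree list randomly permuted,
#' and `XCOR` mixes ACOR and PCOR half-and-half. Degrees are truncated at 1
#' (a degree-0 neuron would not be part of the network) and at `2 * mu - 1`,
#' symmetric about the mean.
#'
#' @param n_exc Number of excitatory neurons (default 480).
#' @param p Connection probability of the excitatory subnetwork (default 0.05).
#' @param corr_type One of `"UCOR"`, `"ACOR"`, `"PCOR"`, `"XCOR"`.
#' @return An object of class `degree_spec`: a list with `n_exc`, `p`,
#'   `corr_type`, `mu`, `sigma_long`, `sigma_short`, `lower`, `upper` and the
#'   2x2 covariance matrix `sigma` of the (in, out) coordinates.
#' @examples
#' spec <- degree_spec(480, 0.05, "ACOR")
#' spec$mu
#' @export
degree_spec <- function(n_exc = 480, p = 0.05,
                        corr_type = c("UCOR", "ACOR", "PCOR", "XCOR")) {
  corr_type <- match.arg(corr_type)
  stopifnot(n_exc >= 2, p > 0, p <= 1)
  mu <- n_exc * p
  if (mu <= 0) stop("mean degree must be positive")
  sigma_long <- mu / 3
  sigma_short <- 0.3 * sigma_long
  lower <- 1
  upper <- 2 * mu - 1
  if (upper < lower) stop("truncation bounds exclude all probability mass")
  # 45-degree rotation of diag(sigma_short^2, sigma_long^2):
  # equal marginal variances, off-diagonal +/- (sl^2 - ss^2) / 2
  v <- (sigma_long^2 + sigma_short^2) / 2
  cv <- (sigma_long^2 - sigma_short^2) / 2
  rho <- switch(corr_type, PCOR = 1, ACOR = -1, UCOR = 0, XCOR = NA_real_)
  sigma <- matrix(c(v, rho * cv, rho * cv, v), 2, 2)
  structure(
    list(n_exc = as.integer(n_exc), p = p, corr_type = corr_type, mu = mu,
         sigma_long = sigma_long, sigma_short = sigma_short,
         lower = lower, upper = upper, sigma = sigma),
    class = "degree_spec")
}

#' @export
print.degree_spec <- function(x, ...) {
  cat(sprintf("degree_spec: %d excitatory neurons, p = %g, %s\n",
              x$n_exc, x$p, x$corr_type))
  cat(sprintf("  mu = %g, sigma_long = %g, sigma_short = %g, bounds [%g, %g]\n",
              x$mu, x$sigma_long, x$sigma_short, x$lower, x$upper))
  invisible(x)
}

# rejection sampler: continuous bivariate Gaussian, rounded to integers,
# redrawn while either coordinate is outside [lower, upper]
sample_trunc_gauss <- function(n, mu, sigma, lower, upper) {
  ch <- chol(sigma)
  out <- matrix(0L, 0, 2)
  while (nrow(out) < n) {
    m <- max(n - nrow(out), 64L)
    x <- round(matrix(stats::rnorm(2 * m), m, 2) %*% ch + mu)
    keep <- x[, 1] >= lower & x[, 1] <= upper & x[, 2] >= lower & x[, 2] <= upper
    out <- rbind(out, x[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Sample a joint degree sequence
#'
#' Draws one (in-degree, out-degree) pair per excitatory neuron from the
#' distribution described by a [degree_spec()]. Samples are rounded to
#' integers and redrawn while either coordinate falls outside the truncation
#' bounds. For `UCOR` the out-degree column is randomly permuted, destroying
#' any pairing; for `XCOR` half of the neurons are drawn from the ACOR and
#' half from the PCOR distribution.
#'
#' Uses the R random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param spec A [degree_spec()].
#' @return A tibble with columns `neuron`, `d_in`, `d_out`.
#' @export
sample_joint_degrees <- function(spec) {
  stopifnot(inherits(spec, "degree_spec"))
  n <- spec$n_exc
  if (spec$corr_type == "XCOR") {
    na <- n %/% 2
    xa <- sample_trunc_gauss(na, spec$mu, degree_spec(spec$n_exc, spec$p, "ACOR")$sigma,
                             spec$lower, spec$upper)
    xp <- sample_trunc_gauss(n - na, spec$mu, degree_spec(spec$n_exc, spec$p, "PCOR")$sigma,
                             spec$lower, spec$upper)
    x <- rbind(xa, xp)
  } else {
    x <- sample_trunc_gauss(n, spec$mu, spec$sigma, spec$lower, spec$upper)
  }
  d_in <- as.integer(x[, 1])
  d_out <- as.integer(x[, 2])
  if (spec$corr_type == "UCOR") d_out <- sample(d_out)
  tibble::tibble(neuron = seq_len(n), d_in = d_in, d_out = d_out)
}

#' Balance in- and out-stub counts of a degree sequence
#'
#' The configuration method requires the total number of out-stubs to equal
#' the total number of in-stubs. When the sums differ, stubs are removed one
#' per neuron per pass starting from the largest out-degrees and added one
#' per neuron per pass starting from the smallest in-degrees (mirrored when
#' in-stubs are in excess), until both sums meet at the midpoint
#' `floor((sum(d_in) + sum(d_out)) / 2)`. With `mode = "remove_only"` the
#' excess side is reduced all the way to the deficient side's sum instead.
#' No degree is pushed outside `[lower, upper]`.
#'
#' @param degrees Tibble with columns `d_in`, `d_out` (e.g. from
#'   [sample_joint_degrees()]).
#' @param lower,upper Truncation bounds respected during balancing.
#' @param mode `"midpoint"` (default) or `"remove_only"`.
#' @return The degree tibble with `sum(d_in) == sum(d_out)`.
#' @export
balance_stubs <- function(degrees, lower = 1, upper = Inf,
                          mode = c("midpoint", "remove_only")) {
  mode <- match.arg(mode)
  d_in <- as.integer(degrees$d_in)
  d_out <- as.integer(degrees$d_out)
  if (sum(d_in) == sum(d_out)) return(degrees)

  swap <- sum(d_in) > sum(d_out)  # mirror case: treat in as the excess side
  hi <- if (swap) d_in else d_out
  lo <- if (swap) d_out else d_in
  target <- if (mode == "midpoint") (sum(hi) + sum(lo)) %/% 2 else sum(lo)
  n_rem <- sum(hi) - target
  n_add <- target - sum(lo)

  while (n_rem > 0) {
    ord <- order(-hi, seq_along(hi))
    k <- ord[hi[ord] > lower]
    k <- k[seq_len(min(length(k), n_rem))]
    if (length(k) == 0)
      stop("stub imbalance cannot be absorbed within the truncation bounds")
    hi[k] <- hi[k] - 1L
    n_rem <- n_rem - length(k)
  }
  while (n_add > 0) {
    ord <- order(lo, seq_along(lo))
    k <- ord[lo[ord] < upper]
    k <- k[seq_len(min(length(k), n_add))]
    if (length(k) == 0)
      stop("stub imbalance cannot be absorbed within the truncation bounds")
    lo[k] <- lo[k] + 1L
    n_add <- n_add - length(k)
  }
  degrees$d_in <- if (swap) hi else lo
  degrees$d_out <- if (swap) lo else hi
  degrees
}
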
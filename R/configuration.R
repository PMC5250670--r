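#' Wire a balanced degree sequence with the configuration method
#'
#' Builds the raw edge multiset: the out-stub list is concatenated in neuron
#' order, the in-stub list is concatenated and randomly permuted, and the
#' k-th out-stub is matched to the k-th in-stub. The result may contain self
#' connections and duplicate ordered pairs; see [repair_collisions()].
#'
#' @param degrees Balanced degree tibble (columns `d_in`, `d_out`,
#'   `sum(d_in) == sum(d_out)`), see [balance_stubs()].
#' @return A tibble of directed edges with columns `pre`, `post` (neuron
#'   indices, possibly with repeats and self loops).
#' @export
build_configuration <- function(degrees) {
  d_in <- degrees$d_in
  d_out <- degrees$d_out
  if (sum(d_in) != sum(d_out))
    stop("degree sequence is not balanced; call balance_stubs() first")
  n <- length(d_in)
  pre <- rep.int(seq_len(n), d_out)
  post <- rep.int(seq_len(n), d_in)
  post <- post[sample.int(length(post))]
  tibble::tibble(pre = pre, post = post)
}

#' Collision statistics of a raw configuration-method edge multiset
#'
#' Fraction of connections that duplicate an already-formed ordered pair
#' (every copy beyond the first counts) and fraction of self connections,
#' both before repair.
#'
#' @param edges Edge tibble from [build_configuration()].
#' @return One-row tibble with `n_edges`, `frac_duplicate`, `frac_self`.
#' @export
collision_stats <- function(edges) {
  n_edges <- nrow(edges)
  key <- (edges$pre - 1) * (max(edges$post) + 1) + edges$post
  dup <- n_edges - length(unique(key))
  tibble::tibble(
    n_edges = n_edges,
    frac_duplicate = dup / n_edges,
    frac_self = mean(edges$pre == edges$post))
}

#' Remove self and duplicate connections while preserving all degrees
#'
#' All copies of duplicated ordered pairs and all self connections are
#' collected and their postsynaptic endpoints are mutually permuted (a random
#' k-permutation of the offending in-stubs); this is repeated until the graph
#' is simple. If no progress is possible from the offending edges alone, a
#' random fraction of innocent edges is added to the permutation pool after
#' `escalate_after` rounds (and every round thereafter). Every neuron's in-
#' and out-degree is exactly preserved.
#'
#' @param edges Edge tibble (`pre`, `post`) from [build_configuration()].
#' @param escalate_after Rounds of pure offender permutation before innocent
#'   edges are drawn into the pool (default 100).
#' @param escalate_per_offender Innocent edges added per offending edge in an
#'   escalated round (default 2, at least 4 in total, growing slowly with
#'   further stuck rounds).
#' @param max_rounds Hard iteration cap; exceeding it raises an error with a
#'   diagnostic (default 10000).
#' @return A simple directed edge tibble (`pre`, `post`): no self connections,
#'   no duplicate ordered pairs.
#' @export
repair_collisions <- function(edges, escalate_after = 100,
                              escalate_per_offender = 2, max_rounds = 10000) {
  pre <- edges$pre
  post <- edges$post
  m <- length(pre)
  base <- max(post, pre) + 1
  for (round in seq_len(max_rounds)) {
    key <- (pre - 1) * base + post
    bad <- pre == post | duplicated(key) | duplicated(key, fromLast = TRUE)
    if (!any(bad)) {
      out <- tibble::tibble(pre = pre, post = post)
      attr(out, "repair_rounds") <- round - 1L
      return(out)
    }
    pool <- which(bad)
    if (round > escalate_after) {
      # keep the added pool small: every re-wired edge can itself collide
      # (~10 % for size-biased endpoints, flagging two edges per collision),
      # so pools beyond ~2 innocents per offender regenerate offenders
      # faster than they resolve them
      innocent <- which(!bad)
      k <- min(length(innocent),
               max(4, escalate_per_offender * length(pool)) +
                 (round - escalate_after) %/% 50)
      pool <- c(pool, sample(innocent, k))
    }
    post[pool] <- post[pool][sample.int(length(pool))]
  }
  stop(sprintf(
    "collision repair did not converge within %d rounds (%d offending edges remain)",
    max_rounds, sum(bad)))
}

#' Generate an excitatory subnetwork with prescribed degree correlations
#'
#' Full structural pipeline: sample joint degrees from the truncated
#' (rotated) bivariate Gaussian, balance the stub counts, match stubs with
#' the configuration method, and repair self/duplicate connections. Uses the
#' R random number generator.
#'
#' @param spec A [degree_spec()].
#' @param balance_mode Passed to [balance_stubs()].
#' @param keep_collision_stats Record pre-repair collision fractions
#'   (default TRUE).
#' @return An object of class `exc_graph`: list with `edges` (simple directed
#'   edge tibble), `degrees` (realized, balanced degree tibble), `spec`, and
#'   `collision_stats`.
#' @examples
#' set.seed(1)
#' g <- generate_exc_graph(degree_spec(60, 0.1, "ACOR"))
#' nrow(g$edges)
#' @export
generate_exc_graph <- function(spec, balance_mode = "midpoint",
                               keep_collision_stats = TRUE) {
  deg <- sample_joint_degrees(spec)
  deg <- balance_stubs(deg, lower = spec$lower, upper = spec$upper,
                       mode = balance_mode)
  raw <- build_configuration(deg)
  cs <- if (keep_collision_stats) collision_stats(raw) else NULL
  edges <- repair_collisions(raw)
  structure(list(edges = edges, degrees = deg, spec = spec,
                 collision_stats = cs),
            class = "exc_graph")
}

#' @export
print.exc_graph <- function(x, ...) {
  cat(sprintf("exc_graph: %s, %d neurons, %d edges\n",
              x$spec$corr_type, x$spec$n_exc, nrow(x$edges)))
  invisible(x)
}
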
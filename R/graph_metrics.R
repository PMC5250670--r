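as_igraph <- function(edges, n) {
  igraph::graph_from_edgelist(cbind(edges$pre, edges$post), directed = TRUE) |>
    igraph::add_vertices(max(0, n - max(edges$pre, edges$post)))
}

#' Mean shortest path length of a directed graph
#'
#' Breadth-first distances from every node; the average is taken over
#' ordered, reachable, non-self pairs, and the fraction of unreachable
#' ordered pairs is reported alongside (unreachable pairs are excluded from
#' the average rather than assigned infinity, the standard behaviour of
#' brain-connectivity toolkits).
#'
#' @param edges Edge tibble (`pre`, `post`) or an `exc_graph`.
#' @param n Number of nodes (taken from the degree specification of an `exc_graph`).
#' @return One-row tibble: `mean_path`, `frac_unreachable`.
#' @export
mean_shortest_path <- function(edges, n = NULL) {
  if (inherits(edges, "exc_graph")) {
    n <- edges$spec$n_exc
    edges <- edges$edges
  }
  if (nrow(edges) == 0) stop("graph has no edges")
  if (is.null(n)) n <- max(edges$pre, edges$post)
  d <- igraph::distances(as_igraph(edges, n), mode = "out")
  diag(d) <- NA
  off <- d[!is.na(d)]
  tibble::tibble(mean_path = mean(off[is.finite(off)]),
                 frac_unreachable = mean(!is.finite(off)))
}

#' k-core decomposition on summed in+out degree
#'
#' For each k, the k-core is the maximal subgraph in which every node has
#' summed in- plus out-degree at least k within the subgraph, obtained by
#' recursively peeling nodes below k.
#'
#' @inheritParams mean_shortest_path
#' @return Tibble with `k` (1 to the largest non-empty core) and `size`
#'   (number of nodes in the k-core); sizes are non-increasing in k.
#' @export
kcore_decomposition <- function(edges, n = NULL) {
  if (inherits(edges, "exc_graph")) {
    n <- edges$spec$n_exc
    edges <- edges$edges
  }
  if (is.null(n)) n <- max(edges$pre, edges$post)
  core <- igraph::coreness(as_igraph(edges, n), mode = "all")
  kmax <- max(core)
  tibble::tibble(k = seq_len(kmax),
                 size = vapply(seq_len(kmax), function(k) sum(core >= k), 0L))
}

#' Largest non-empty core order
#'
#' @inheritParams mean_shortest_path
#' @return Integer: the largest k with a non-empty k-core.
#' @export
kcore_max <- function(edges, n = NULL) {
  max(kcore_decomposition(edges, n)$k)
}

#' Degree correlation by least-squares regression
#'
#' Ordinary least-squares fit of out-degree (response) on in-degree
#' (predictor); the slope and its two-sided p-value against a horizontal
#' line quantify the correlation in the joint degree distribution.
#'
#' @param d_in,d_out Integer degree vectors (same length, >= 3 points).
#' @return One-row tibble: `slope`, `intercept`, `p_value`.
#' @export
lsr_correlation <- function(d_in, d_out) {
  stopifnot(length(d_in) == length(d_out), length(d_in) >= 3)
  if (stats::var(d_in) == 0) stop("in-degree has zero variance")
  fit <- stats::lm(d_out ~ d_in)
  s <- summary(fit)$coefficients
  tibble::tibble(slope = s["d_in", "Estimate"],
                 intercept = s["(Intercept)", "Estimate"],
                 p_value = s["d_in", "Pr(>|t|)"])
}

#' Degree correlation by the quadrant method
#'
#' The (in, out) plane is split into four quadrants at the sample means of
#' the realized degrees. Neurons in the upper-right and lower-left quadrants
#' (`P_n`) indicate positive correlation, those in the upper-left and
#' lower-right (`A_n`) anti-correlation; the statistic is `P_n / A_n - 1`.
#' Neurons exactly on a quadrant boundary count in neither group, so
#' `P_n + A_n <= length(d_in)`.
#'
#' @param d_in,d_out Integer degree vectors.
#' @return One-row tibble: `p_n`, `a_n`, `statistic` (`Inf` with a warning
#'   when `A_n = 0`).
#' @export
quadrant_statistic <- function(d_in, d_out) {
  mi <- mean(d_in); mo <- mean(d_out)
  p_n <- sum(d_in > mi & d_out > mo) + sum(d_in < mi & d_out < mo)
  a_n <- sum(d_in > mi & d_out < mo) + sum(d_in < mi & d_out > mo)
  if (p_n + a_n == 0) stop("all points lie on the quadrant boundaries")
  if (a_n == 0) warning("no neurons in the anti-correlation quadrants; statistic is Inf")
  tibble::tibble(p_n = p_n, a_n = a_n, statistic = p_n / a_n - 1)
}

#' Structural summary of an excitatory graph
#'
#' @param g An `exc_graph` (or edge tibble plus `n`).
#' @param n Node count when `g` is a plain edge tibble.
#' @return One-row tibble: `n`, `n_edges`, `mean_path`, `frac_unreachable`,
#'   `kcore_max`, `lsr_slope`, `lsr_p`, `quadrant_stat`.
#' @export
graph_summary <- function(g, n = NULL) {
  if (inherits(g, "exc_graph")) {
    edges <- g$edges
    n <- g$spec$n_exc
    d_in <- g$degrees$d_in
    d_out <- g$degrees$d_out
  } else {
    edges <- g
    if (is.null(n)) n <- max(edges$pre, edges$post)
    d_in <- tabulate(edges$post, nbins = n)
    d_out <- tabulate(edges$pre, nbins = n)
  }
  sp <- mean_shortest_path(edges, n)
  lsr <- lsr_correlation(d_in, d_out)
  qd <- quadrant_statistic(d_in, d_out)
  tibble::tibble(n = n, n_edges = nrow(edges),
                 mean_path = sp$mean_path,
                 frac_unreachable = sp$frac_unreachable,
                 kcore_max = kcore_max(edges, n),
                 lsr_slope = lsr$slope, lsr_p = lsr$p_value,
                 quadrant_stat = qd$statistic)
}
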
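#' PageRank on an undirected network
#'
#' Power iteration of the teleporting random walk:
#' \eqn{x \gets (1-d)/n + d\,M x}, with \eqn{M} the column-stochastic walk
#' matrix over the undirected edges. Columns of isolated nodes are zero, so
#' isolated nodes hold exactly the teleport mass \eqn{(1-d)/n} at the fixed
#' point; the final vector is normalised to sum to one.
#'
#' @param g Non-empty igraph with named vertices.
#' @param damping Damping factor in (0, 1); default 0.85.
#' @param tol Convergence tolerance on the L1 step; default 1e-10.
#' @return Named numeric vector summing to 1, lexicographic node order.
#' @export
pagerank <- function(g, damping = 0.85, tol = 1e-10) {
  stopifnot(damping > 0, damping < 1)
  av <- graph_adj(g)
  n <- length(av$nodes)
  if (n == 0L) rlang::abort("PageRank is undefined for an empty graph")
  deg <- lengths(av$adj)
  x <- rep(1 / n, n)
  repeat {
    spread <- ifelse(deg > 0L, x / deg, 0)
    xn <- rep((1 - damping) / n, n)
    for (u in seq_len(n)) {
      nb <- av$adj[[u]]
      if (length(nb)) xn[u] <- xn[u] + damping * sum(spread[nb])
    }
    if (sum(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  stats::setNames(x / sum(x), av$nodes)
}

#' Degree centrality
#'
#' Degree divided by `n - 1`, the maximum possible degree.
#'
#' @param g igraph with at least two vertices.
#' @return Named numeric vector in `[0, 1]`, lexicographic node order.
#' @export
degree_centrality <- function(g) {
  av <- graph_adj(g)
  n <- length(av$nodes)
  if (n < 2L) rlang::abort("degree centrality needs at least two nodes")
  stats::setNames(lengths(av$adj) / (n - 1), av$nodes)
}

#' HITS scores on an undirected network
#'
#' On an undirected graph hub and authority scores coincide with the
#' principal eigenvector of the adjacency matrix \eqn{A}. Computed by power
#' iteration on \eqn{A + I} from the uniform vector with L2 normalisation:
#' the shift leaves the eigenvectors untouched while making the principal
#' eigenvalue strictly dominant on bipartite graphs, where iterating
#' \eqn{A} alone oscillates. On a disconnected graph whose components tie
#' on the leading eigenvalue the uniform start spreads mass evenly over the
#' tied components — a deterministic, documented outcome.
#'
#' @param g igraph with at least one edge.
#' @param tol Convergence tolerance; default 1e-12.
#' @param max_iter Iteration cap; default 10000.
#' @return Named non-negative numeric vector with unit L2 norm.
#' @export
hits <- function(g, tol = 1e-12, max_iter = 10000L) {
  av <- graph_adj(g)
  n <- length(av$nodes)
  if (n == 0L || sum(lengths(av$adj)) == 0L)
    rlang::abort("HITS is undefined for an edgeless graph")
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    xn <- x + vapply(seq_len(n), function(u) sum(x[av$adj[[u]]]), double(1))
    nrm <- sqrt(sum(xn^2))
    if (nrm == 0) { xn <- x; break }  # only isolated mass left; keep previous
    xn <- xn / nrm
    if (sum(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  stats::setNames(x, av$nodes)
}

#' Shortest-path betweenness centrality
#'
#' Unnormalized betweenness over unordered node pairs with fractional credit
#' across equally short paths (Brandes' accumulation, via igraph). With
#' `normalized = TRUE` values are divided by `(n-1)(n-2)/2`, the number of
#' pairs a node could possibly sit between.
#'
#' @param g igraph with named vertices.
#' @param normalized Divide by `(n-1)(n-2)/2`? Default `FALSE`.
#' @return Named numeric vector, lexicographic node order.
#' @export
betweenness_centrality <- function(g, normalized = FALSE) {
  nodes <- sort(igraph::V(g)$name)
  if (!length(nodes)) return(stats::setNames(numeric(), character()))
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)[nodes]
  if (normalized) {
    n <- length(nodes)
    if (n > 2L) b <- b / ((n - 1) * (n - 2) / 2)
  }
  b
}

#' Node-level centrality statistics table
#'
#' Degree centrality, PageRank, HITS and betweenness for every node, the
#' statistics exported alongside the module tables. Measures that are
#' undefined on the given graph (HITS on an edgeless graph, degree
#' centrality on a single node) come back as `NA` rather than failing the
#' whole table.
#'
#' @param g Non-empty igraph with named vertices (a `seeded_network` is
#'   accepted too).
#' @param damping,tol PageRank parameters.
#' @param normalized_betweenness Passed to [betweenness_centrality()].
#' @return Tibble `node`, `degree_centrality`, `pagerank`, `hits`,
#'   `betweenness`, in lexicographic node order.
#' @export
node_stats <- function(g, damping = 0.85, tol = 1e-10,
                       normalized_betweenness = FALSE) {
  if (inherits(g, "seeded_network")) g <- g$graph
  nodes <- sort(igraph::V(g)$name)
  if (!length(nodes)) rlang::abort("node statistics need a non-empty graph")
  dc <- if (length(nodes) >= 2L) degree_centrality(g) else
    stats::setNames(NA_real_, nodes)
  hs <- if (igraph::ecount(g) > 0L) hits(g) else
    stats::setNames(rep(NA_real_, length(nodes)), nodes)
  tibble::tibble(node = nodes,
                 degree_centrality = unname(dc[nodes]),
                 pagerank = unname(pagerank(g, damping, tol)[nodes]),
                 hits = unname(hs[nodes]),
                 betweenness = unname(betweenness_centrality(
                   g, normalized = normalized_betweenness)[nodes]))
}
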
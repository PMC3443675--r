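#' Build an undirected simple interaction graph from an edge table
#'
#' Nodes are canonical gene identifiers (character). The graph is simple and
#' undirected: self-loops are dropped with a warning, duplicate records (in
#' either orientation) collapse to a single edge, and vertices are kept in
#' lexicographic order so every export is deterministic.
#'
#' @param edges A data frame whose first two columns are the interaction
#'   endpoints (coerced to character; surrounding whitespace is trimmed).
#'   Extra columns are ignored. May have zero rows.
#' @param nodes Optional character vector of node identifiers to include even
#'   when they touch no edge.
#' @return An `igraph` object (undirected, simple, named vertices).
#' @examples
#' g <- ppi_graph(data.frame(a = c("7157", "7157"), b = c("4193", "1026")))
#' igraph::vcount(g)
#' @export
ppi_graph <- function(edges = NULL, nodes = character()) {
  nodes <- trimws(as.character(nodes))
  if (is.null(edges) || nrow(edges) == 0L) {
    ep <- matrix(character(), ncol = 2L)
  } else {
    stopifnot(ncol(edges) >= 2L)
    ep <- cbind(trimws(as.character(edges[[1]])), trimws(as.character(edges[[2]])))
  }
  if (any(ep == "") || any(nodes == "")) {
    rlang::abort("empty node identifiers are not allowed")
  }
  loops <- ep[, 1] == ep[, 2]
  if (any(loops)) {
    rlang::warn(sprintf("dropped %d self-loop record(s)", sum(loops)),
                class = "seednet_self_loop")
    ep <- ep[!loops, , drop = FALSE]
  }
  # canonical unordered orientation, then dedupe
  flip <- ep[, 1] > ep[, 2]
  ep[flip, ] <- ep[flip, 2:1]
  ep <- unique(ep)
  vs <- sort(unique(c(as.vector(ep), nodes)))
  g <- igraph::make_empty_graph(n = length(vs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vs)
  if (nrow(ep) > 0L) {
    g <- igraph::add_edges(g, rbind(match(ep[, 1], vs), match(ep[, 2], vs)))
  }
  g
}

#' Add one undirected edge to a graph
#'
#' Endpoints are created if absent. Re-adding an existing edge is a no-op;
#' a self-loop (`u == v`) leaves the graph unchanged with a warning.
#'
#' @param g An `igraph` object with named vertices.
#' @param u,v Node identifiers (length-1 character).
#' @return The updated graph, vertices in lexicographic order.
#' @export
graph_add_edge <- function(g, u, v) {
  u <- trimws(as.character(u)); v <- trimws(as.character(v))
  if (identical(u, v)) {
    rlang::warn(sprintf("self-loop %s-%s dropped", u, v), class = "seednet_self_loop")
    return(g)
  }
  new <- setdiff(c(u, v), igraph::V(g)$name)
  if (length(new)) g <- igraph::add_vertices(g, length(new), name = new)
  if (!igraph::are_adjacent(g, u, v)) g <- igraph::add_edges(g, c(u, v))
  normalize_graph(g)
}

#' Closed neighborhood of a node
#'
#' Returns the node together with its graph neighbors, the neighborhood used
#' by the structural similarity underlying SCAN clustering.
#'
#' @inheritParams graph_add_edge
#' @param v A node identifier present in `g`.
#' @return Sorted character vector of node identifiers.
#' @export
closed_neighborhood <- function(g, v) {
  v <- as.character(v)
  if (!v %in% igraph::V(g)$name) {
    rlang::abort(sprintf("node '%s' is not in the graph", v))
  }
  sort(unique(c(v, igraph::V(g)$name[as.integer(igraph::neighbors(g, v))])))
}

#' Subgraph induced by a set of nodes
#'
#' Keeps `keep`'s intersection with the graph's node set and every edge with
#' both endpoints kept. Identifiers in `keep` that are not graph nodes are
#' ignored (and reported with a message).
#'
#' @inheritParams graph_add_edge
#' @param keep Character vector of node identifiers.
#' @return The induced subgraph, vertices in lexicographic order.
#' @export
induced_network <- function(g, keep) {
  keep <- unique(trimws(as.character(keep)))
  unknown <- setdiff(keep, igraph::V(g)$name)
  if (length(unknown)) {
    rlang::inform(sprintf("%d identifier(s) in `keep` are not graph nodes and were ignored",
                          length(unknown)))
  }
  normalize_graph(igraph::induced_subgraph(g, intersect(keep, igraph::V(g)$name)))
}

#' @keywords internal
normalize_graph <- function(g) {
  vs <- igraph::V(g)$name
  igraph::permute(g, rank(vs, ties.method = "first"))
}

#' Edge table of a graph
#'
#' @inheritParams graph_add_edge
#' @return A tibble with columns `from`, `to` (lexicographic within and
#'   across rows; `from < to`).
#' @export
graph_edges <- function(g) {
  m <- igraph::as_edgelist(g)
  if (nrow(m)) {
    flip <- m[, 1] > m[, 2]
    m[flip, ] <- m[flip, 2:1]
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  tibble::tibble(from = as.character(m[, 1]), to = as.character(m[, 2]))
}

# Internal adjacency-list view used by SCAN and the centrality code:
# nodes sorted lexicographically, adjacency as sorted integer indices.
#' @keywords internal
graph_adj <- function(g) {
  vs <- igraph::V(g)$name
  o <- order(vs)
  nodes <- vs[o]
  n <- length(nodes)
  inv <- integer(n); inv[o] <- seq_len(n)
  m <- igraph::as_edgelist(g, names = FALSE)
  adj <- rep(list(integer()), n)
  if (nrow(m)) {
    src <- inv[c(m[, 1], m[, 2])]
    tgt <- inv[c(m[, 2], m[, 1])]
    ord <- order(src, tgt)
    adj <- lapply(split(tgt[ord], factor(src[ord], levels = seq_len(n))),
                  as.integer)
    names(adj) <- NULL
  }
  list(nodes = nodes, adj = adj)
}

#' Check the structural invariants of an interaction graph
#'
#' Verifies the graph is undirected, simple (no loops or parallel edges),
#' that every adjacency entry refers to a member node, and that degrees sum
#' to twice the edge count. Used throughout the test-suite after every
#' graph-producing operation.
#'
#' @inheritParams graph_add_edge
#' @return `TRUE` invisibly; aborts with a description otherwise.
#' @export
validate_graph <- function(g) {
  if (igraph::is_directed(g)) rlang::abort("graph must be undirected")
  if (igraph::any_loop(g)) rlang::abort("graph has self-loops")
  if (igraph::any_multiple(g)) rlang::abort("graph has parallel edges")
  if (is.null(igraph::V(g)$name) && igraph::vcount(g) > 0)
    rlang::abort("vertices must be named")
  if (sum(igraph::degree(g)) != 2L * igraph::ecount(g))
    rlang::abort("degree sum does not equal twice the edge count")
  invisible(TRUE)
}

#' Read / write interaction edge lists as TSV
#'
#' Two identifier columns plus an optional third source column; lines
#' starting with `#` are comments. `write_edge_tsv()` accepts either a graph
#' or an edge data frame.
#'
#' @param path File path.
#' @return `read_edge_tsv()`: a tibble with columns `id_a`, `id_b` and, when
#'   present in the file, `source`.
#' @export
read_edge_tsv <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(x) < 2L) rlang::abort("edge list needs at least two columns")
  names(x)[1:2] <- c("id_a", "id_b")
  if (ncol(x) >= 3L) names(x)[3] <- "source"
  x[seq_len(min(3L, ncol(x)))]
}

#' @rdname read_edge_tsv
#' @param x A graph or a data frame of edges.
#' @export
write_edge_tsv <- function(x, path) {
  if (inherits(x, "igraph")) x <- graph_edges(x)
  readr::write_tsv(x, path, col_names = FALSE)
  invisible(path)
}
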
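#' Seed sets
#'
#' Wraps the user's mapped seed identifiers together with the subset actually
#' present in the knowledge-base graph. Seeds missing from the knowledge base
#' are kept (they appear as isolated, flagged nodes in built networks) so the
#' seed accounting always matches the mapped input list.
#'
#' @param ids Character vector of canonical seed identifiers.
#' @param kb_graph Knowledge-base igraph the seeds will be looked up in.
#' @param soft_cap Seed-count warning threshold; very large seed lists make
#'   neighbor expansion unwieldy. Default 3000.
#' @return A `seed_set` object with elements `seeds` and `found`.
#' @export
seed_set <- function(ids, kb_graph, soft_cap = 3000L) {
  ids <- unique(trimws(as.character(ids)))
  ids <- ids[ids != ""]
  if (length(ids) > soft_cap) {
    rlang::warn(sprintf("%d seeds exceeds the soft cap of %d; consider seeds_only mode",
                        length(ids), soft_cap), class = "seednet_seed_cap")
  }
  structure(list(seeds = ids, found = intersect(ids, igraph::V(kb_graph)$name)),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("<seed_set> ", length(x$seeds), " seeds, ", length(x$found),
      " found in the knowledge base\n", sep = "")
  invisible(x)
}

#' Network construction modes
#'
#' Three ways to place a seed list into the knowledge-base network:
#' `direct_neighbors` adds every gene that directly interacts with a seed;
#' `min_seed_links` adds only non-seed genes interacting with more than `t`
#' seeds (default `t = 2`); `seeds_only` restricts to the seeds themselves.
#' In the two expanded modes an edge is added only when at least one endpoint
#' is a seed.
#'
#' @param mode One of `"direct_neighbors"`, `"min_seed_links"`, `"seeds_only"`.
#' @param t Seed-link threshold for `min_seed_links`; kept iff
#'   seed-neighbor count `> t`.
#' @return An `expansion_mode` object.
#' @export
expansion_mode <- function(mode = c("direct_neighbors", "min_seed_links", "seeds_only"),
                           t = 2L) {
  mode <- match.arg(mode)
  t <- as.integer(t)
  if (mode == "min_seed_links" && (is.na(t) || t < 1L))
    rlang::abort("`t` must be an integer >= 1")
  structure(list(mode = mode, t = t), class = "expansion_mode")
}

#' Default construction mode for a given seed-list size
#'
#' Neighbor expansion is the default for lists below 1000 genes; above that
#' the network is restricted to the input genes themselves. The boundary
#' (exactly 1000) resolves to expansion.
#'
#' @param n_seeds Number of seed genes.
#' @return An `expansion_mode`.
#' @export
select_default_mode <- function(n_seeds) {
  stopifnot(n_seeds >= 0)
  if (n_seeds > 1000) expansion_mode("seeds_only") else expansion_mode("direct_neighbors")
}

#' Build the analysis network around a seed set
#'
#' @param kb_graph Knowledge-base igraph (typically a [kvotes_filter()] result).
#' @param seeds A [seed_set()].
#' @param mode An [expansion_mode()]; default neighbor expansion.
#' @return A `seeded_network`: `graph` (igraph) plus `is_seed`, a named
#'   logical over its nodes. All seeds appear in the network, isolated if
#'   need be; in expanded modes no edge joins two non-seed nodes.
#' @export
build_network <- function(kb_graph, seeds, mode = expansion_mode("direct_neighbors")) {
  stopifnot(inherits(seeds, "seed_set"), inherits(mode, "expansion_mode"))
  if (length(seeds$found) == 0L) {
    rlang::abort(paste("none of the seeds are present in the knowledge base;",
                       "check the ID map and seed identifiers"))
  }
  found <- seeds$found
  if (mode$mode == "seeds_only") {
    g <- induced_network(kb_graph, found)
  } else {
    ed <- graph_edges(kb_graph)
    seed_edge <- ed$from %in% found | ed$to %in% found
    ed <- ed[seed_edge, , drop = FALSE]
    if (mode$mode == "min_seed_links") {
      other <- ifelse(ed$from %in% found, ed$to, ed$from)
      ext <- other[!other %in% found]
      n_links <- table(ext)
      keep_ext <- names(n_links)[n_links > mode$t]
      ok <- (ed$from %in% found | ed$from %in% keep_ext) &
            (ed$to %in% found | ed$to %in% keep_ext)
      ed <- ed[ok, , drop = FALSE]
    }
    g <- ppi_graph(ed, nodes = found)
  }
  # mapped seeds absent from the knowledge base ride along as isolated nodes
  missing <- setdiff(seeds$seeds, igraph::V(g)$name)
  if (length(missing)) g <- normalize_graph(igraph::add_vertices(g, length(missing), name = missing))
  is_seed <- stats::setNames(igraph::V(g)$name %in% seeds$seeds, igraph::V(g)$name)
  structure(list(graph = g, is_seed = is_seed, mode = mode), class = "seeded_network")
}

#' @export
print.seeded_network <- function(x, ...) {
  cat("<seeded_network> mode=", x$mode$mode, ": ", igraph::vcount(x$graph),
      " nodes (", sum(x$is_seed), " seeds), ", igraph::ecount(x$graph),
      " edges\n", sep = "")
  invisible(x)
}

#' Node table of a seeded network
#'
#' @param net A [build_network()] result.
#' @return Tibble with columns `node`, `is_seed`, `degree`.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "seeded_network"))
  tibble::tibble(node = igraph::V(net$graph)$name,
                 is_seed = unname(net$is_seed[igraph::V(net$graph)$name]),
                 degree = unname(igraph::degree(net$graph)))
}

#' Read a seed list file (one identifier per line, '#' comments)
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_seed_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x[x != "" & !startsWith(x, "#")]
}
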
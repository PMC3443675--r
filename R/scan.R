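#' Structural similarity of two nodes
#'
#' The cosine overlap of the two closed neighborhoods,
#' \eqn{\sigma(u,v) = |\Gamma(u) \cap \Gamma(v)| / \sqrt{|\Gamma(u)||\Gamma(v)|}},
#' with \eqn{\Gamma(x)} the node together with its neighbors. Adjacent nodes
#' embedded in the same dense region score near 1; bridge edges between
#' modules score low. Always in \eqn{[0, 1]} and symmetric.
#'
#' @param g An igraph with named vertices.
#' @param u,v Node identifiers present in `g`.
#' @return A number in `[0, 1]`.
#' @export
structural_similarity <- function(g, u, v) {
  gu <- closed_neighborhood(g, u)
  gv <- closed_neighborhood(g, v)
  length(intersect(gu, gv)) / sqrt(length(gu) * length(gv))
}

#' SCAN structural clustering of a network
#'
#' Detects functional modules by structural similarity along edges. A node is
#' a *core* when at least `mu` members of its closed neighborhood (itself
#' included, since \eqn{\sigma(v,v)=1}) are epsilon-similar to it; clusters
#' grow by structure-reachability from cores, collecting both cores and the
#' non-core border nodes they reach. Nodes left in no cluster are classified
#' as *hubs* when their neighbors span two or more modules (they bridge
#' modules) and as *outliers* otherwise. Traversal is in lexicographic node
#' order, so module identifiers and border-node assignment are reproducible.
#'
#' @param g An igraph with named vertices (may be empty).
#' @param epsilon Similarity threshold in (0, 1]; default 0.7.
#' @param mu Minimum epsilon-neighborhood size for a core; default 2.
#' @return A `scan_clustering` object: `label` (named integer, `NA` for
#'   non-members), `role` (named character: member/hub/outlier), `modules`
#'   (list of node-name vectors), `is_core` (named logical), plus the
#'   parameters. Use [tidy()] for a per-node tibble.
#' @examples
#' g <- ppi_graph(data.frame(a = c("a","a","b","c","d","d","e"),
#'                           b = c("b","c","c","d","e","f","f")))
#' scan_cluster(g)
#' @export
scan_cluster <- function(g, epsilon = 0.7, mu = 2L) {
  stopifnot(epsilon > 0, epsilon <= 1)
  mu <- as.integer(mu)
  stopifnot(mu >= 1L)
  av <- graph_adj(g)
  nodes <- av$nodes
  adj <- lapply(av$adj, sort)
  n <- length(nodes)
  if (n == 0L) {
    return(new_scan_clustering(integer(), character(), list(), logical(),
                               nodes, epsilon, mu))
  }
  cd <- lengths(adj) + 1L  # closed-neighborhood sizes
  # epsilon-neighbor lists: adjacent nodes with sigma >= epsilon
  eps_nb <- vector("list", n)
  for (u in seq_len(n)) {
    nb <- adj[[u]]
    if (!length(nb)) { eps_nb[[u]] <- integer(); next }
    cu <- c(u, nb)  # closed neighborhood (unsorted union is fine for matching)
    common <- vapply(nb, function(v) {
      cv <- c(v, adj[[v]])
      sum(match(cu, cv, 0L) > 0L)
    }, integer(1))
    sigma <- common / sqrt(cd[u] * cd[nb])
    eps_nb[[u]] <- nb[sigma >= epsilon - 1e-12]
  }
  is_core <- (lengths(eps_nb) + 1L) >= mu  # +1: the node itself
  label <- rep(NA_integer_, n)
  next_id <- 0L
  for (s in seq_len(n)) {
    if (!is_core[s] || !is.na(label[s])) next
    next_id <- next_id + 1L
    queue <- s
    label[s] <- next_id
    while (length(queue)) {
      x <- queue[[1]]; queue <- queue[-1]
      for (w in eps_nb[[x]]) {
        if (is.na(label[w])) {
          label[w] <- next_id
          if (is_core[w]) queue <- c(queue, w)
        }
      }
    }
  }
  # non-members: hubs bridge >= 2 modules among their neighbors
  role <- ifelse(!is.na(label), "member", NA_character_)
  for (u in which(is.na(label))) {
    mods <- unique(label[adj[[u]]])
    role[u] <- if (sum(!is.na(mods)) >= 2L) "hub" else "outlier"
  }
  modules <- lapply(seq_len(next_id), function(i) nodes[which(label == i)])
  new_scan_clustering(label, role, modules, is_core, nodes, epsilon, mu)
}

new_scan_clustering <- function(label, role, modules, is_core, nodes, epsilon, mu) {
  structure(list(label = stats::setNames(label, nodes),
                 role = stats::setNames(role, nodes),
                 modules = modules,
                 is_core = stats::setNames(is_core, nodes),
                 epsilon = epsilon, mu = mu),
            class = "scan_clustering")
}

#' @export
print.scan_clustering <- function(x, ...) {
  cat("<scan_clustering> epsilon=", x$epsilon, ", mu=", x$mu, ": ",
      length(x$modules), " modules over ", length(x$label), " nodes (",
      sum(x$role == "hub"), " hubs, ", sum(x$role == "outlier"),
      " outliers)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-node view of a SCAN clustering
#'
#' @param x A `scan_clustering`.
#' @param ... Unused.
#' @return Tibble with columns `node`, `module` (NA for non-members),
#'   `role`, `is_core`.
#' @export
tidy.scan_clustering <- function(x, ...) {
  tibble::tibble(node = names(x$label),
                 module = unname(x$label),
                 role = unname(x$role),
                 is_core = unname(x$is_core))
}

#' One-row summary of a SCAN clustering
#'
#' @inheritParams tidy.scan_clustering
#' @return Tibble with `n_nodes`, `n_modules`, `n_members`, `n_hubs`,
#'   `n_outliers`, `epsilon`, `mu`.
#' @export
glance.scan_clustering <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$label),
                 n_modules = length(x$modules),
                 n_members = sum(x$role == "member"),
                 n_hubs = sum(x$role == "hub"),
                 n_outliers = sum(x$role == "outlier"),
                 epsilon = x$epsilon, mu = x$mu)
}

#' Per-module contribution to Newman's modularity
#'
#' For module \eqn{i}, \eqn{Q_i = e_{ii} - a_i^2}: the fraction of all edges
#' inside the module minus the squared fraction of edge endpoints attached to
#' it. Summed over a complete partition this is exactly Newman's global
#' modularity Q; the single-module term serves as a quality score when
#' ranking modules.
#'
#' @param g An igraph with at least one edge.
#' @param modules List of node-name vectors (disjoint).
#' @param i Module index into `modules`.
#' @return A number in `[-0.25, 1]`.
#' @export
module_modularity <- function(g, modules, i) {
  m <- igraph::ecount(g)
  if (m == 0L) rlang::abort("modularity is undefined for an edgeless graph")
  mem <- modules[[i]]
  ed <- graph_edges(g)
  e_in <- sum(ed$from %in% mem & ed$to %in% mem) / m
  a <- sum(igraph::degree(g, mem)) / (2 * m)
  e_in - a^2
}

#' Summarise and rank functional modules
#'
#' Modules are ranked by the number of seed genes they contain (default), by
#' total size, or by their per-module modularity. Ties resolve to the larger
#' module, then to the module whose lexicographically smallest member comes
#' first. The default reports the six top modules.
#'
#' @param clustering A [scan_cluster()] result.
#' @param g The clustered igraph (for modularity).
#' @param seeds A [seed_set()] or a character vector of seed identifiers.
#' @param criterion `"seed_count"`, `"size"` or `"modularity"`.
#' @param top_k Number of modules to keep; default 6.
#' @return Tibble `module_id`, `n_nodes`, `n_seeds`, `modularity`, one row
#'   per reported module in rank order.
#' @export
rank_modules <- function(clustering, g, seeds = character(),
                         criterion = c("seed_count", "size", "modularity"),
                         top_k = 6L) {
  stopifnot(inherits(clustering, "scan_clustering"), top_k >= 1L)
  criterion <- match.arg(criterion)
  if (inherits(seeds, "seed_set")) seeds <- seeds$seeds
  mods <- clustering$modules
  if (!length(mods)) {
    return(tibble::tibble(module_id = integer(), n_nodes = integer(),
                          n_seeds = integer(), modularity = double()))
  }
  has_edges <- igraph::ecount(g) > 0L
  out <- tibble::tibble(
    module_id = seq_along(mods),
    n_nodes = lengths(mods),
    n_seeds = vapply(mods, function(v) sum(v %in% seeds), integer(1)),
    modularity = vapply(seq_along(mods), function(i) {
      if (has_edges) module_modularity(g, mods, i) else NA_real_
    }, double(1)),
    first_member = vapply(mods, function(v) min(v), character(1))
  )
  key <- switch(criterion, seed_count = out$n_seeds, size = out$n_nodes,
                modularity = out$modularity)
  ord <- order(-key, -out$n_nodes, out$first_member)
  out <- out[ord, ]
  utils::head(dplyr::select(out, -"first_member"), top_k)
}

#' Module membership table for export
#'
#' @param clustering A [scan_cluster()] result.
#' @param seeds Seed identifiers (or a [seed_set()]).
#' @return Tibble `module_id`, `node`, `is_seed`, `role` covering every node
#'   (non-members carry `NA` module_id).
#' @export
module_table <- function(clustering, seeds = character()) {
  if (inherits(seeds, "seed_set")) seeds <- seeds$seeds
  tidy(clustering) |>
    dplyr::transmute(module_id = .data$module, node = .data$node,
                     is_seed = .data$node %in% seeds, role = .data$role) |>
    dplyr::arrange(.data$module_id, .data$node)
}

#' Plot module sizes and seed content
#'
#' Bar chart of the ranked modules: total genes per module with the seed
#' portion highlighted.
#'
#' @param object A `scan_clustering`.
#' @param g The clustered igraph.
#' @param seeds Seed identifiers (or a [seed_set()]).
#' @param top_k Modules to show; default 6.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_clustering <- function(object, g, seeds = character(), top_k = 6L, ...) {
  rk <- rank_modules(object, g, seeds, top_k = top_k)
  long <- rk |>
    dplyr::mutate(non_seed = .data$n_nodes - .data$n_seeds,
                  module = factor(.data$module_id, levels = .data$module_id)) |>
    tidyr::pivot_longer(c("n_seeds", "non_seed"),
                        names_to = "part", values_to = "genes") |>
    dplyr::mutate(part = ifelse(.data$part == "n_seeds", "seed", "added"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$module, y = .data$genes,
                                     fill = .data$part)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "module (rank order)", y = "genes", fill = NULL,
                  title = "Functional modules: size and seed content") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
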
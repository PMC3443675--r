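# Independent brute-force oracles used to check the implementation.
# Everything here works from first principles (dense matrices, exhaustive
# enumeration) and never calls the code paths it verifies.

# deterministic Erdos-Renyi-style random graph over named nodes
random_named_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  take <- stats::runif(ncol(pairs)) < p
  ed <- if (any(take)) data.frame(a = nodes[pairs[1, take]],
                                  b = nodes[pairs[2, take]]) else NULL
  ppi_graph(ed, nodes = nodes)
}

# dense adjacency matrix in lexicographic node order
dense_adjacency <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ed <- graph_edges(g)
  A[cbind(ed$from, ed$to)] <- 1
  A[cbind(ed$to, ed$from)] <- 1
  A
}

# structural similarity matrix from closed-neighborhood overlaps:
# C = A + I, (C %*% C)[u,v] = |closed(u) \cap closed(v)|
oracle_sigma_matrix <- function(g) {
  A <- dense_adjacency(g)
  C <- A + diag(nrow(A))
  M <- C %*% C
  cd <- diag(M)
  M / sqrt(outer(cd, cd))
}

# Exhaustive check of a SCAN clustering against the definitional predicates.
# Returns a character vector of violations (empty = clean).
oracle_scan_violations <- function(g, cl, epsilon, mu) {
  nodes <- sort(igraph::V(g)$name)
  out <- character()
  if (!length(nodes)) return(out)
  A <- dense_adjacency(g)
  S <- oracle_sigma_matrix(g)
  eps_nb <- (A > 0) & (S >= epsilon)          # adjacent epsilon-neighbors
  core <- (rowSums(eps_nb) + 1L) >= mu        # +1: the node itself
  if (!identical(unname(core[nodes]), unname(cl$is_core[nodes])))
    out <- c(out, "core predicate mismatch")
  # core components under epsilon-closeness (both endpoints core)
  core_adj <- eps_nb & outer(core, core, "&")
  comp <- rep(NA_integer_, length(nodes)); names(comp) <- nodes
  cid <- 0L
  for (v in nodes[core]) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue)) {
      x <- queue[[1]]; queue <- queue[-1]
      nb <- nodes[core_adj[x, ] & is.na(comp)]
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  label <- cl$label[nodes]
  # each module's cores must be exactly one core component
  for (i in seq_along(cl$modules)) {
    mem <- cl$modules[[i]]
    mc <- mem[core[mem]]
    if (!length(mc)) { out <- c(out, sprintf("module %d has no core", i)); next }
    if (length(unique(comp[mc])) != 1L)
      out <- c(out, sprintf("module %d spans multiple core components", i))
    full <- nodes[!is.na(comp) & comp == comp[mc[1]]]
    if (!setequal(mc, full))
      out <- c(out, sprintf("module %d misses cores of its component", i))
    # non-core members must be epsilon-reached by a core of this module
    for (w in setdiff(mem, mc)) {
      if (!any(eps_nb[w, mc]))
        out <- c(out, sprintf("border %s not claimed by module %d", w, i))
    }
  }
  if (length(unique(stats::na.omit(comp))) != length(cl$modules))
    out <- c(out, "module count differs from core-component count")
  # completeness: every node epsilon-claimed by any core must be a member
  claimed <- nodes[colSums(eps_nb[core, , drop = FALSE]) > 0 | core]
  if (!all(!is.na(label[claimed])))
    out <- c(out, "claimed node left unassigned")
  if (!all(is.na(label[setdiff(nodes, claimed)])))
    out <- c(out, "unclaimed node was assigned")
  # roles of non-members
  for (u in nodes[is.na(label)]) {
    mods <- unique(stats::na.omit(label[nodes[A[u, ] > 0]]))
    want <- if (length(mods) >= 2L) "hub" else "outlier"
    if (cl$role[u] != want)
      out <- c(out, sprintf("role of %s should be %s", u, want))
  }
  out
}

# global Newman modularity from the dense definition
oracle_newman_q <- function(g, labels) {
  A <- dense_adjacency(g)
  labels <- labels[rownames(A)]
  m <- sum(A) / 2
  deg <- rowSums(A)
  same <- outer(labels, labels, "==")   # complete partitions only (no NA)
  sum((A - outer(deg, deg) / (2 * m)) * same) / (2 * m)
}

# exhaustive all-shortest-paths betweenness (n small); own BFS throughout
oracle_betweenness <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  A <- dense_adjacency(g)
  n <- length(nodes)
  score <- stats::setNames(rep(0, n), nodes)
  bfs_dist <- function(s) {
    d <- rep(Inf, n); names(d) <- nodes; d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- character()
      for (x in frontier) {
        nb <- nodes[A[x, ] > 0 & is.infinite(d)]
        d[nb] <- d[x] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    d
  }
  all_paths <- function(s, t, d) {
    # enumerate shortest s->t paths by walking distance-decreasing edges back
    walk <- function(x) {
      if (x == s) return(list(s))
      preds <- nodes[A[x, ] > 0 & d[nodes] == d[x] - 1]
      unlist(lapply(preds, function(p) lapply(walk(p), function(pp) c(pp, x))),
             recursive = FALSE)
    }
    walk(t)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- nodes[i]; t <- nodes[j]
    d <- bfs_dist(s)
    if (is.infinite(d[t])) next
    paths <- all_paths(s, t, d)
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tab <- table(inner) / length(paths)
      score[names(tab)] <- score[names(tab)] + as.numeric(tab)
    }
  }
  score
}

# dense linear-system PageRank: x = (1-d)/n + d M x, dangling columns zero,
# then normalised to sum 1
oracle_pagerank <- function(g, damping = 0.85) {
  A <- dense_adjacency(g)
  n <- nrow(A)
  deg <- colSums(A)
  M <- A
  M[, deg > 0] <- sweep(A[, deg > 0, drop = FALSE], 2, deg[deg > 0], "/")
  x <- solve(diag(n) - damping * M, rep((1 - damping) / n, n))
  stats::setNames(x / sum(x), rownames(A))
}

# exhaustive hypergeometric upper-tail sum with choose()
oracle_hyper_tail <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
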
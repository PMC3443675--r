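# Synthetic ground-truth generators. Planted-partition graphs stand in for
# the PPI knowledge base; aligned gene sets stand in for pathway
# annotations; block subsamples stand in for disease gene signatures.
# Everything is reproducible from one integer seed.

with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# uniformly sample `count` of the m possible pairs between two index sets
# (or within one set), without materialising all m pairs
sample_block_pairs <- function(idx_a, idx_b = NULL, p) {
  if (is.null(idx_b)) {             # within-block pairs
    s <- length(idx_a)
    m <- s * (s - 1L) / 2L
    if (m == 0L) return(NULL)
    count <- stats::rbinom(1L, m, p)
    if (count == 0L) return(NULL)
    ks <- sort(sample.int(m, count))
    # unrank k in 1..C(s,2) into (r, c), r < c, row-major over r
    r <- findInterval(ks - 1L, cumsum(c(0L, (s - 1L):1L)), rightmost.closed = FALSE)
    off <- ks - c(0L, cumsum((s - 1L):1L))[r]
    cbind(idx_a[r], idx_a[r + off])
  } else {                          # between-block pairs
    m <- length(idx_a) * length(idx_b)
    count <- stats::rbinom(1L, m, p)
    if (count == 0L) return(NULL)
    ks <- sample.int(m, count) - 1L
    cbind(idx_a[ks %/% length(idx_b) + 1L], idx_b[ks %% length(idx_b) + 1L])
  }
}

#' Planted-partition benchmark graph
#'
#' Nodes are split into blocks; each within-block pair is joined
#' independently with probability `p_in`, each between-block pair with
#' `p_out`. With `p_in` well above `p_out` the blocks are the ground-truth
#' functional modules a clustering method should recover.
#'
#' @param block_sizes Integer vector of block sizes (all >= 1).
#' @param p_in,p_out Edge probabilities in `[0, 1]`.
#' @param rng_seed Integer seed; identical seeds give identical graphs.
#' @return List with `graph` (igraph; node names `g0001`, ...) and `labels`
#'   (named integer vector node -> block id). Blockless isolated nodes do
#'   not occur: every node belongs to a block, isolated or not.
#' @export
planted_partition_graph <- function(block_sizes, p_in, p_out, rng_seed = 1L) {
  stopifnot(all(block_sizes >= 1L), p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  n <- sum(block_sizes)
  nodes <- sprintf("g%04d", seq_len(n))
  block <- rep(seq_along(block_sizes), block_sizes)
  idx <- split(seq_len(n), block)
  pairs <- with_rng_seed(rng_seed, {
    out <- list()
    for (i in seq_along(idx)) {
      out[[length(out) + 1L]] <- sample_block_pairs(idx[[i]], p = p_in)
      if (i < length(idx)) for (j in (i + 1L):length(idx)) {
        out[[length(out) + 1L]] <- sample_block_pairs(idx[[i]], idx[[j]], p_out)
      }
    }
    do.call(rbind, out)
  })
  ed <- if (is.null(pairs)) NULL else
    data.frame(a = nodes[pairs[, 1]], b = nodes[pairs[, 2]])
  list(graph = ppi_graph(ed, nodes = nodes),
       labels = stats::setNames(block, nodes))
}

#' Multi-source interaction records for a known graph
#'
#' Emulates merging several partially overlapping interaction databases:
#' each of `n_sources` sources reports each edge of `g` independently with
#' probability `coverage`. The k-votes union of the sources approaches `g`
#' as coverage rises.
#'
#' @param g igraph whose edges are the ground truth.
#' @param n_sources Number of sources (>= 1); named `src1`, `src2`, ...
#' @param coverage Per-source edge sampling probability in (0, 1].
#' @param rng_seed Integer seed.
#' @return Tibble of records: `id_a`, `id_b`, `source`.
#' @export
make_multisource_kb <- function(g, n_sources, coverage, rng_seed = 1L) {
  stopifnot(n_sources >= 1L, coverage > 0, coverage <= 1)
  ed <- graph_edges(g)
  with_rng_seed(rng_seed, {
    purrr::map_dfr(seq_len(n_sources), function(s) {
      take <- stats::runif(nrow(ed)) < coverage
      if (!any(take)) return(NULL)
      tibble::tibble(id_a = ed$from[take], id_b = ed$to[take],
                     source = sprintf("src%d", s))
    })
  })
}

#' Gene-set annotations aligned with planted blocks
#'
#' One gene set per planted block — with a `noise` fraction of its members
#' swapped for random out-of-block genes — plus `n_decoy_sets` sets drawn
#' uniformly from all genes. The universe is every node. This emulates a
#' pathway collection in which each planted module has a matching pathway.
#'
#' @param labels Named integer vector node -> block id (from
#'   [planted_partition_graph()]).
#' @param n_decoy_sets Number of random decoy sets.
#' @param noise Fraction of each block set to corrupt, in `[0, 0.5)`.
#' @param rng_seed Integer seed.
#' @return A [gene_set_collection()]; block sets are named `block_<id>`,
#'   decoys `decoy_<i>`.
#' @export
make_aligned_annotations <- function(labels, n_decoy_sets = 0L, noise = 0,
                                     rng_seed = 1L) {
  stopifnot(noise >= 0, noise < 0.5)
  nodes <- names(labels)
  blocks <- split(nodes, labels)
  with_rng_seed(rng_seed, {
    sets <- purrr::map_dfr(names(blocks), function(b) {
      members <- blocks[[b]]
      n_swap <- floor(noise * length(members))
      if (n_swap > 0L) {
        out <- sample(members, n_swap)
        pool <- setdiff(nodes, members)
        members <- c(setdiff(members, out), sample(pool, min(n_swap, length(pool))))
      }
      tibble::tibble(set_id = paste0("block_", b),
                     name = paste0("planted block ", b),
                     genes = list(sort(members)))
    })
    if (n_decoy_sets > 0L) {
      size <- max(2L, floor(mean(lengths(blocks))))
      decoys <- purrr::map_dfr(seq_len(n_decoy_sets), function(i) {
        tibble::tibble(set_id = sprintf("decoy_%d", i),
                       name = sprintf("decoy set %d", i),
                       genes = list(sort(sample(nodes, min(size, length(nodes))))))
      })
      sets <- rbind(sets, decoys)
    }
    gene_set_collection(sets, universe = nodes)
  })
}

#' Sample seed genes from chosen planted blocks
#'
#' Takes a uniform without-replacement sample of `floor(fraction * size)`
#' genes from each chosen block, emulating a published disease gene
#' signature drawn from the processes the blocks represent.
#'
#' @param labels Named integer vector node -> block id.
#' @param blocks Block ids to sample from.
#' @param fraction Fraction of each block, in (0, 1].
#' @param rng_seed Integer seed.
#' @return Character vector of seed identifiers.
#' @export
sample_seeds <- function(labels, blocks, fraction, rng_seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  blocks <- intersect(unique(blocks), unique(labels))
  if (!length(blocks)) rlang::abort("no seeds selected: unknown block ids")
  with_rng_seed(rng_seed, {
    out <- unlist(lapply(blocks, function(b) {
      members <- names(labels)[labels == b]
      sample(members, max(1L, floor(fraction * length(members))))
    }))
    sort(out)
  })
}

#' Generate and (optionally) write a complete test scenario
#'
#' Bundles the fixture generators into one call: a planted-partition graph,
#' multi-source interaction records over it, an ID map (identity plus one
#' symbol-style alias per gene), seeds sampled from chosen blocks, and
#' aligned annotations. When `dir` is given, writes `interactions.tsv`,
#' `id_map.tsv`, `seeds.txt` and `annotations.gmt` there.
#'
#' @param block_sizes,p_in,p_out Passed to [planted_partition_graph()].
#' @param n_sources,coverage Passed to [make_multisource_kb()].
#' @param seed_blocks,seed_fraction Passed to [sample_seeds()].
#' @param n_decoy_sets,noise Passed to [make_aligned_annotations()].
#' @param rng_seed Integer master seed; sub-seeds are derived from it.
#' @param dir Optional output directory (created if missing).
#' @return List: `graph`, `labels`, `records`, `id_map_table`, `seeds`,
#'   `collection`, and `paths` when written.
#' @export
make_scenario <- function(block_sizes = rep(20L, 4L), p_in = 0.9, p_out = 0.02,
                          n_sources = 3L, coverage = 0.8,
                          seed_blocks = c(1L, 2L), seed_fraction = 0.5,
                          n_decoy_sets = 4L, noise = 0,
                          rng_seed = 1L, dir = NULL) {
  base <- as.integer(rng_seed) %% 100000L
  pp <- planted_partition_graph(block_sizes, p_in, p_out, rng_seed = base)
  records <- make_multisource_kb(pp$graph, n_sources, coverage, rng_seed = base + 1L)
  coll <- make_aligned_annotations(pp$labels, n_decoy_sets, noise, rng_seed = base + 2L)
  seeds <- sample_seeds(pp$labels, seed_blocks, seed_fraction, rng_seed = base + 3L)
  nodes <- names(pp$labels)
  idmap <- tibble::tibble(alias = c(nodes, paste0("SYM_", toupper(nodes))),
                          canonical = c(nodes, nodes))
  out <- list(graph = pp$graph, labels = pp$labels, records = records,
              id_map_table = idmap, seeds = seeds, collection = coll)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(interactions = file.path(dir, "interactions.tsv"),
                  id_map = file.path(dir, "id_map.tsv"),
                  seeds = file.path(dir, "seeds.txt"),
                  gmt = file.path(dir, "annotations.gmt"))
    readr::write_tsv(records, paths$interactions, col_names = FALSE)
    readr::write_tsv(idmap, paths$id_map, col_names = FALSE)
    readr::write_lines(seeds, paths$seeds)
    write_gmt(coll, paths$gmt)
    out$paths <- paths
  }
  out
}
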
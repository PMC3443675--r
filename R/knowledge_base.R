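#' Identifier maps: alias to canonical gene ID
#'
#' Many heterogeneous identifiers (official symbols, accessions, Entrez IDs)
#' map onto one canonical identifier. Symbol-style aliases are matched
#' case-insensitively; purely numeric aliases (Entrez-style) are matched
#' exactly. Every canonical identifier also maps to itself, so canonical
#' input passes through unchanged. An alias pointing at two different
#' canonical identifiers is an error: silent ambiguity would corrupt seed
#' mapping downstream.
#'
#' @param alias Character vector of aliases.
#' @param canonical Character vector of canonical identifiers, same length.
#' @return An `id_map` object.
#' @export
id_map <- function(alias, canonical) {
  alias <- trimws(as.character(alias))
  canonical <- trimws(as.character(canonical))
  stopifnot(length(alias) == length(canonical))
  if (any(alias == "") || any(canonical == ""))
    rlang::abort("empty identifiers in the ID map")
  tab <- tibble::tibble(alias = alias, canonical = canonical)
  tab <- rbind(tab, tibble::tibble(alias = unique(canonical),
                                   canonical = unique(canonical)))
  tab$key <- fold_alias(tab$alias)
  tab <- unique(tab[c("key", "canonical", "alias")])
  dup <- tab$key[duplicated(tab$key)]
  if (length(dup)) {
    bad <- tab[tab$key %in% dup, ]
    rlang::abort(c("ambiguous ID map: alias maps to multiple canonical IDs",
                   stats::setNames(paste(bad$alias, "->", bad$canonical),
                                   rep("x", nrow(bad)))))
  }
  structure(list(key = tab$key, canonical = tab$canonical), class = "id_map")
}

# numeric aliases compare exactly, symbols case-insensitively
fold_alias <- function(x) ifelse(grepl("^[0-9]+$", x), x, toupper(x))

#' @export
print.id_map <- function(x, ...) {
  cat("<id_map> ", length(x$key), " aliases -> ",
      length(unique(x$canonical)), " canonical IDs\n", sep = "")
  invisible(x)
}

#' Read an ID map from TSV
#'
#' Two columns, `alias` then `canonical`; `#` lines are comments.
#'
#' @param path File path.
#' @return An `id_map` object.
#' @export
read_id_map <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(x) < 2L) rlang::abort("ID map needs two columns: alias, canonical")
  id_map(x[[1]], x[[2]])
}

#' Map raw identifiers to canonical IDs
#'
#' Order-preserving; identifiers that collapse onto an already-seen canonical
#' ID are dropped, and unmappable identifiers are returned verbatim so the
#' caller can report them.
#'
#' @param raw Character vector of identifiers in any supported format.
#' @param m An [id_map()].
#' @return A list with `mapped` (canonical IDs, de-duplicated, input order)
#'   and `unmapped` (original spelling of identifiers not in the map).
#' @export
map_ids <- function(raw, m) {
  stopifnot(inherits(m, "id_map"))
  raw <- trimws(as.character(raw))
  raw <- raw[raw != ""]
  hit <- match(fold_alias(raw), m$key)
  mapped <- m$canonical[hit[!is.na(hit)]]
  list(mapped = mapped[!duplicated(mapped)],
       unmapped = raw[is.na(hit)])
}

#' Merge tagged interaction records into a consensus knowledge base
#'
#' Records from several source databases are mapped to canonical IDs and
#' collapsed to one edge per unordered pair; each edge remembers the set of
#' distinct sources that reported it (record multiplicity within one source
#' does not count). Records with an unmappable endpoint, and records whose
#' endpoints collapse to the same canonical ID, are dropped and counted.
#'
#' @param records Data frame with columns `id_a`, `id_b`, `source` (or any
#'   first three columns in that order).
#' @param m An [id_map()].
#' @return A `knowledge_base` object: `graph` (the union igraph), `support`
#'   (tibble `from`, `to`, `n_sources`, `sources`), `sources` (all source
#'   names seen), and drop counts.
#' @export
merge_sources <- function(records, m) {
  stopifnot(inherits(m, "id_map"))
  if (is.null(records) || nrow(records) == 0L) {
    return(new_knowledge_base(ppi_graph(),
                              tibble::tibble(from = character(), to = character(),
                                             n_sources = integer(), sources = list()),
                              character(), 0L, 0L))
  }
  stopifnot(ncol(records) >= 3L)
  a <- trimws(as.character(records[[1]]))
  b <- trimws(as.character(records[[2]]))
  src <- trimws(as.character(records[[3]]))
  if (any(src == "")) rlang::abort("interaction records must carry a source name")
  ca <- m$canonical[match(fold_alias(a), m$key)]
  cb <- m$canonical[match(fold_alias(b), m$key)]
  unmapped <- is.na(ca) | is.na(cb)
  loop <- !unmapped & ca == cb
  keep <- !unmapped & !loop
  ca <- ca[keep]; cb <- cb[keep]; src <- src[keep]
  flip <- ca > cb
  tmp <- ca[flip]; ca[flip] <- cb[flip]; cb[flip] <- tmp
  support <- tibble::tibble(from = ca, to = cb, source = src) |>
    dplyr::distinct() |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(n_sources = dplyr::n(),
                     sources = list(sort(.data$source)), .groups = "drop") |>
    dplyr::arrange(.data$from, .data$to)
  g <- ppi_graph(support[c("from", "to")])
  new_knowledge_base(g, support, sort(unique(trimws(as.character(records[[3]])))),
                     sum(unmapped), sum(loop))
}

new_knowledge_base <- function(graph, support, sources, n_unmapped, n_self) {
  structure(list(graph = graph, support = support, sources = sources,
                 n_dropped_unmapped = n_unmapped, n_dropped_self = n_self),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base> ", igraph::vcount(x$graph), " proteins/genes, ",
      igraph::ecount(x$graph), " interactions from ",
      length(x$sources), " source(s)\n", sep = "")
  if (x$n_dropped_unmapped || x$n_dropped_self)
    cat("  dropped records: ", x$n_dropped_unmapped, " unmapped, ",
        x$n_dropped_self, " self-interacting\n", sep = "")
  invisible(x)
}

#' Consensus (k-votes) filter of a knowledge base
#'
#' Keeps an interaction only when at least `k` distinct source databases
#' report it; isolated nodes are removed. `k = 1` is the plain union of all
#' sources, `k = `number of sources is their intersection. A stringent
#' consensus (`k = 2`) trades coverage for reliability.
#'
#' @param kb A [merge_sources()] result.
#' @param k Integer vote threshold, `1 <= k <= length(kb$sources)`.
#' @return The filtered igraph.
#' @export
kvotes_filter <- function(kb, k) {
  stopifnot(inherits(kb, "knowledge_base"))
  k <- as.integer(k)
  if (length(kb$sources) == 0L) {
    if (k != 1L) rlang::abort("k out of range for an empty knowledge base")
    return(kb$graph)
  }
  if (is.na(k) || k < 1L || k > length(kb$sources)) {
    rlang::abort(sprintf("k must be in [1, %d], got %s", length(kb$sources), k))
  }
  keep <- kb$support[kb$support$n_sources >= k, c("from", "to")]
  ppi_graph(keep)
}

#' Node/edge counts of a knowledge base per vote threshold
#'
#' @param kb A [merge_sources()] result.
#' @return A tibble with one row per `k` from 1 to the number of sources:
#'   `k`, `n_nodes`, `n_edges`.
#' @export
kb_summary <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  ks <- seq_len(max(1L, length(kb$sources)))
  purrr::map_dfr(ks, function(k) {
    g <- kvotes_filter(kb, k)
    tibble::tibble(k = k, n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g))
  })
}
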
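#' Gene-set collections
#'
#' A list of annotated gene sets (pathways) plus the background universe the
#' enrichment test is performed against. Unless supplied, the universe is
#' every gene appearing in any set — the choice of universe changes every
#' p-value, so it is always explicit in results.
#'
#' @param sets Tibble/data frame with columns `set_id`, `name`, `category`,
#'   `genes` (list column of character vectors); `name`/`category` optional.
#' @param universe Optional character vector of background genes; defaults
#'   to the union of all set members. Set members outside a supplied
#'   universe are trimmed off.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  sets <- tibble::as_tibble(sets)
  stopifnot(all(c("set_id", "genes") %in% names(sets)))
  if (!"name" %in% names(sets)) sets$name <- sets$set_id
  if (!"category" %in% names(sets)) sets$category <- ""
  sets$genes <- lapply(sets$genes, function(g) sort(unique(as.character(g))))
  if (anyDuplicated(sets$set_id)) rlang::abort("duplicate set_id in collection")
  if (any(lengths(sets$genes) == 0L)) rlang::abort("empty gene sets are not allowed")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets$genes)))
  } else {
    universe <- sort(unique(as.character(universe)))
    sets$genes <- lapply(sets$genes, intersect, y = universe)
    if (any(lengths(sets$genes) == 0L))
      rlang::abort("a gene set has no members inside the supplied universe")
  }
  structure(list(sets = sets[c("set_id", "name", "category", "genes")],
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", nrow(x$sets), " sets over a universe of ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`, one
#' set per line. The description field is carried through as the set name
#' and category.
#'
#' @param path File path.
#' @param universe Optional background universe (see [gene_set_collection()]).
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[trimws(lines) != ""]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) rlang::abort(sprintf("%d GMT line(s) have fewer than 3 fields", sum(bad)))
  sets <- tibble::tibble(
    set_id = vapply(parts, `[[`, character(1), 1L),
    name = vapply(parts, `[[`, character(1), 2L),
    genes = lapply(parts, function(p) p[-(1:2)]))
  sets$name[sets$name == ""] <- sets$set_id[sets$name == ""]
  sets$category <- sets$name
  gene_set_collection(sets, universe)
}

#' Write a collection to GMT
#'
#' @param coll A `gene_set_collection`.
#' @param path File path.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "gene_set_collection"))
  lines <- vapply(seq_len(nrow(coll$sets)), function(i) {
    paste(c(coll$sets$set_id[i], coll$sets$name[i], coll$sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' One-sided Fisher exact (hypergeometric tail) p-value for enrichment
#'
#' For a module with `n` genes in a universe of `N`, of which `K` belong to
#' the gene set and `k` to both: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`. This is the one-sided Fisher exact test on
#' the 2x2 table (module-and-set, module-only, set-only, neither); no
#' normal approximation is involved.
#'
#' @param k Overlap count.
#' @param K Gene-set size within the universe.
#' @param n Module size within the universe.
#' @param N Universe size.
#' @return p-value in (0, 1].
#' @export
fisher_greater <- function(k, K, n, N) {
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (any(is.na(c(k, K, n, N))) || k < 0L || K < 0L || n < 0L || N < 0L ||
      K > N || n > N || k > min(K, n))
    rlang::abort("inconsistent 2x2 margins")
  stats::phyper(k - 1L, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Fisher-exact gene-set enrichment of one module
#'
#' Module genes outside the universe are excluded before testing; one result
#' row per gene set with a non-empty overlap, in ascending p-value order
#' (ties: larger overlap first, then set_id). Raw p-values are reported, as
#' pathway summaries conventionally print them; `fdr = TRUE` appends a
#' Benjamini-Hochberg column.
#'
#' @param module_nodes Character vector of module gene identifiers.
#' @param coll A [gene_set_collection()].
#' @param seeds Optional seed identifiers; overlapping seeds are flagged in
#'   `seed_overlap_genes`.
#' @param fdr Append a `p_adjust` (Benjamini-Hochberg) column? Default FALSE.
#' @return Tibble `set_id`, `name`, `category`, `k`, `set_size`,
#'   `module_size`, `universe_size`, `p_value`, `overlap_genes`,
#'   `seed_overlap_genes` (comma-joined).
#' @export
enrich_module <- function(module_nodes, coll, seeds = character(), fdr = FALSE) {
  stopifnot(inherits(coll, "gene_set_collection"))
  if (length(coll$universe) == 0L) rlang::abort("empty enrichment universe")
  if (inherits(seeds, "seed_set")) seeds <- seeds$seeds
  mod <- intersect(unique(as.character(module_nodes)), coll$universe)
  n <- length(mod); N <- length(coll$universe)
  res <- purrr::map_dfr(seq_len(nrow(coll$sets)), function(i) {
    genes <- coll$sets$genes[[i]]
    ov <- intersect(mod, genes)
    if (!length(ov)) return(NULL)
    tibble::tibble(set_id = coll$sets$set_id[i], name = coll$sets$name[i],
                   category = coll$sets$category[i],
                   k = length(ov), set_size = length(genes),
                   module_size = n, universe_size = N,
                   p_value = fisher_greater(length(ov), length(genes), n, N),
                   overlap_genes = paste(sort(ov), collapse = ","),
                   seed_overlap_genes = paste(sort(intersect(ov, seeds)),
                                              collapse = ","))
  })
  if (is.null(res) || nrow(res) == 0L) {
    res <- tibble::tibble(set_id = character(), name = character(),
                          category = character(), k = integer(),
                          set_size = integer(), module_size = integer(),
                          universe_size = integer(), p_value = double(),
                          overlap_genes = character(),
                          seed_overlap_genes = character())
  }
  res <- dplyr::arrange(res, .data$p_value, dplyr::desc(.data$k), .data$set_id)
  if (fdr) res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Render p-values the way pathway summaries print them
#'
#' Values below `1e-4` print as `"<0.0001"`; larger values are rounded to
#' five decimals. Machine-readable outputs keep full precision; this is for
#' the human-readable report only.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  big <- sub("\\.$", "", sub("0+$", "", formatC(p, format = "f", digits = 5)))
  ifelse(p < 1e-4, "<0.0001", big)
}

#' Plot the top enriched pathways of a module
#'
#' @param enrichment An [enrich_module()] result.
#' @param top_n Pathways to show; default 10.
#' @return A ggplot object (horizontal bars of -log10 p).
#' @export
plot_enrichment <- function(enrichment, top_n = 10L) {
  df <- utils::head(enrichment, top_n)
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value), y = .data$name)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(-log[10] ~ "Fisher p-value"), y = NULL,
                  title = "Top enriched gene sets") +
    ggplot2::theme_minimal()
}
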
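#' Pipeline configuration
#'
#' Collects every knob of the seed-to-modules workflow in one object. Paths
#' point at the four plain-text inputs; the remaining fields control the
#' consensus filter, network construction, clustering, ranking and
#' enrichment.
#'
#' @param interactions_path Tab-separated interaction records
#'   (`id_a  id_b  source`).
#' @param idmap_path Tab-separated alias-to-canonical map.
#' @param seeds_path Seed list, one identifier per line.
#' @param gmt_path GMT gene-set collection.
#' @param output_dir Directory the result files are written into.
#' @param kvotes Consensus threshold k (default 1: union of sources; 2 is
#'   the stringent preset).
#' @param mode `"auto"`, `"direct"`, `"min-links"` or `"seeds-only"`;
#'   `"auto"` picks by seed-list size (see [select_default_mode()]).
#' @param min_links_t Seed-link threshold for `"min-links"`; default 2.
#' @param epsilon,mu SCAN parameters; defaults 0.7 and 2.
#' @param rank_by `"seeds"`, `"size"` or `"modularity"`; default `"seeds"`.
#' @param top_k Modules to report; default 6.
#' @param universe `"collection"`, `"network"`, or `"file:PATH"`.
#' @param fdr Append Benjamini-Hochberg column to enrichment output?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(interactions_path, idmap_path, seeds_path, gmt_path,
                            output_dir, kvotes = 1L, mode = "auto",
                            min_links_t = 2L, epsilon = 0.7, mu = 2L,
                            rank_by = "seeds", top_k = 6L,
                            universe = "collection", fdr = FALSE) {
  for (p in list(interactions_path, idmap_path, seeds_path, gmt_path,
                 output_dir)) {
    if (!is.character(p) || length(p) != 1L || is.na(p))
      rlang::abort("all paths and the output directory must be single strings")
  }
  mode <- match.arg(mode, c("auto", "direct", "min-links", "seeds-only"))
  rank_by <- match.arg(rank_by, c("seeds", "size", "modularity"))
  stopifnot(epsilon > 0, epsilon <= 1, mu >= 1, top_k >= 1, kvotes >= 1,
            min_links_t >= 1)
  structure(list(interactions_path = interactions_path, idmap_path = idmap_path,
                 seeds_path = seeds_path, gmt_path = gmt_path,
                 output_dir = output_dir, kvotes = as.integer(kvotes),
                 mode = mode, min_links_t = as.integer(min_links_t),
                 epsilon = epsilon, mu = as.integer(mu), rank_by = rank_by,
                 top_k = as.integer(top_k), universe = universe, fdr = fdr),
            class = "pipeline_config")
}

#' Read a flat `key = value` configuration file
#'
#' Lines of `key = value`; `#` starts a comment; keys match the arguments of
#' [pipeline_config()]. Entries in `overrides` win over the file.
#'
#' @param path Config file path.
#' @param overrides Named list of overriding values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[trimws(lines) != ""])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) rlang::abort(sprintf("malformed config line(s): %s",
                                     paste(lines[bad], collapse = "; ")))
  vals <- stats::setNames(
    lapply(kv, function(p) trimws(paste(p[-1], collapse = "="))),
    vapply(kv, function(p) trimws(p[[1]]), character(1)))
  vals[names(overrides)] <- overrides
  num <- c("kvotes", "min_links_t", "epsilon", "mu", "top_k")
  for (k in intersect(num, names(vals))) vals[[k]] <- as.numeric(vals[[k]])
  if ("fdr" %in% names(vals)) vals$fdr <- tolower(as.character(vals$fdr)) %in% c("true", "1", "yes")
  do.call(pipeline_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 class = "seednet_stage_error", parent = e)
  })
}

#' Run the full seed-to-modules pipeline
#'
#' Executes the whole workflow: map the seed identifiers, merge the tagged
#' interaction sources and apply the k-votes consensus filter, build the
#' seeded network, cluster it with SCAN, rank the modules, enrich the top
#' modules against the gene-set collection, and compute node centrality
#' statistics. Writes `modules.tsv`, `module_summary.tsv`, `enrichment.tsv`,
#' `node_stats.tsv`, `network.gdf` and `run.log` into the output directory.
#' On failure the partially written outputs are removed and the error names
#' the failing stage.
#'
#' @param cfg A [pipeline_config()].
#' @return A `run_report`: input/mapping/network/module counts plus the
#'   result tables and fitted objects.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  outputs <- file.path(cfg$output_dir,
                       c("modules.tsv", "module_summary.tsv", "enrichment.tsv",
                         "node_stats.tsv", "network.gdf", "run.log"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs), add = TRUE)
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)

  records <- stage("read_interactions", read_edge_tsv(cfg$interactions_path))
  if (!"source" %in% names(records))
    stage("read_interactions", rlang::abort("interaction file lacks a source column"))
  m <- stage("read_id_map", read_id_map(cfg$idmap_path))
  raw_seeds <- stage("read_seeds", read_seed_list(cfg$seeds_path))

  mapping <- stage("map_ids", map_ids(raw_seeds, m))
  kb <- stage("merge_sources", merge_sources(records, m))
  kbg <- stage("kvotes_filter", kvotes_filter(kb, cfg$kvotes))

  seeds <- stage("build_network", seed_set(mapping$mapped, kbg))
  mode <- switch(cfg$mode,
                 auto = select_default_mode(length(seeds$seeds)),
                 direct = expansion_mode("direct_neighbors"),
                 `min-links` = expansion_mode("min_seed_links", t = cfg$min_links_t),
                 `seeds-only` = expansion_mode("seeds_only"))
  net <- stage("build_network", build_network(kbg, seeds, mode))

  clustering <- stage("scan_cluster",
                      scan_cluster(net$graph, cfg$epsilon, cfg$mu))
  criterion <- c(seeds = "seed_count", size = "size",
                 modularity = "modularity")[[cfg$rank_by]]
  summary_tab <- stage("rank_modules",
                       rank_modules(clustering, net$graph, seeds,
                                    criterion = criterion, top_k = cfg$top_k))

  coll <- stage("enrichment", {
    if (startsWith(cfg$universe, "file:")) {
      read_gmt(cfg$gmt_path,
               universe = read_seed_list(sub("^file:", "", cfg$universe)))
    } else if (cfg$universe == "network") {
      read_gmt(cfg$gmt_path, universe = igraph::V(net$graph)$name)
    } else read_gmt(cfg$gmt_path)
  })
  enr <- stage("enrichment", {
    purrr::map_dfr(summary_tab$module_id, function(mid) {
      res <- enrich_module(clustering$modules[[mid]], coll, seeds, fdr = cfg$fdr)
      if (nrow(res)) cbind(tibble::tibble(module_id = mid), res) else NULL
    })
  })
  if (is.null(enr) || nrow(enr) == 0L)
    enr <- tibble::tibble(module_id = integer(), set_id = character(),
                          name = character(), category = character(),
                          k = integer(), set_size = integer(),
                          module_size = integer(), universe_size = integer(),
                          p_value = double(), overlap_genes = character(),
                          seed_overlap_genes = character())
  stats_tab <- stage("centrality", node_stats(net$graph))

  mod_tab <- module_table(clustering, seeds)
  report <- structure(list(
    n_seeds_input = length(raw_seeds),
    n_seeds_mapped = length(mapping$mapped),
    unmapped_seeds = mapping$unmapped,
    n_seeds_found = length(seeds$found),
    n_records_dropped_unmapped = kb$n_dropped_unmapped,
    n_records_dropped_self = kb$n_dropped_self,
    n_nodes = igraph::vcount(net$graph),
    added_genes = igraph::vcount(net$graph) - sum(net$is_seed),
    added_edges = igraph::ecount(net$graph),
    n_modules = length(clustering$modules),
    mode = mode$mode,
    config = cfg,
    network = net, clustering = clustering,
    modules = mod_tab, module_summary = summary_tab,
    enrichment = enr, node_stats = stats_tab), class = "run_report")

  stage("write_outputs", {
    readr::write_tsv(mod_tab, outputs[1])
    readr::write_tsv(summary_tab, outputs[2])
    enr_out <- enr
    enr_out$p_value_printed <- format_p_value(enr_out$p_value)
    readr::write_tsv(enr_out, outputs[3])
    readr::write_tsv(stats_tab, outputs[4])
    write_gdf(net, clustering, stats_tab, outputs[5])
    writeLines(run_log_lines(report), outputs[6])
  })
  ok <- TRUE
  report
}

run_log_lines <- function(r) {
  cfg <- r$config
  c("# seednet run log",
    "[parameters]",
    sprintf("%s = %s", names(unclass(cfg)),
            vapply(unclass(cfg), function(v) paste(format(v), collapse = ","),
                   character(1))),
    "[counts]",
    sprintf("seeds_input = %d", r$n_seeds_input),
    sprintf("seeds_mapped = %d", r$n_seeds_mapped),
    sprintf("seeds_found_in_kb = %d", r$n_seeds_found),
    sprintf("seeds_unmapped = %d", length(r$unmapped_seeds)),
    sprintf("records_dropped_unmapped = %d", r$n_records_dropped_unmapped),
    sprintf("records_dropped_self = %d", r$n_records_dropped_self),
    sprintf("network_mode = %s", r$mode),
    sprintf("network_nodes = %d", r$n_nodes),
    sprintf("added_genes = %d", r$added_genes),
    sprintf("added_edges = %d", r$added_edges),
    sprintf("modules_found = %d", r$n_modules),
    "[unmapped_seeds]",
    r$unmapped_seeds)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n",
      "  seeds: ", x$n_seeds_input, " input, ", x$n_seeds_mapped, " mapped, ",
      x$n_seeds_found, " in knowledge base\n",
      "  network (", x$mode, "): ", x$n_nodes, " nodes, ", x$added_edges,
      " edges, ", x$added_genes, " added genes\n",
      "  modules: ", x$n_modules, "\n", sep = "")
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `run_report`.
#' @param ... Unused.
#' @return Tibble mirroring the mapped/added-gene accounting of a seed-gene
#'   analysis summary.
#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(n_seeds_input = x$n_seeds_input,
                 n_seeds_mapped = x$n_seeds_mapped,
                 n_seeds_found = x$n_seeds_found,
                 added_genes = x$added_genes,
                 added_edges = x$added_edges,
                 n_modules = x$n_modules)
}

gdf_num <- function(x) sprintf("%.12g", x)

#' Write a clustered, annotated network in GDF format
#'
#' GDF is the plain-text graph format of the GUESS visualization tool: a
#' `nodedef>` header with typed node attributes, node rows, an `edgedef>`
#' header, then edge rows. Node and edge rows are in lexicographic order;
#' an unassigned module renders as the empty string.
#'
#' @param net A [build_network()] result.
#' @param clustering A [scan_cluster()] result on its graph.
#' @param stats A [node_stats()] table for its graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gdf <- function(net, clustering, stats, path) {
  stopifnot(inherits(net, "seeded_network"))
  nodes <- sort(igraph::V(net$graph)$name)
  if (!setequal(nodes, names(clustering$label)) || !setequal(nodes, stats$node))
    rlang::abort("network, clustering and stats cover different node sets")
  if (any(grepl("[,\n]", nodes))) rlang::abort("node names may not contain commas")
  st <- stats[match(nodes, stats$node), ]
  mod <- clustering$label[nodes]
  node_rows <- paste(nodes, nodes,
                     ifelse(unname(net$is_seed[nodes]), "true", "false"),
                     ifelse(is.na(mod), "", as.character(mod)),
                     unname(clustering$role[nodes]),
                     gdf_num(st$pagerank), gdf_num(st$betweenness), sep = ",")
  ed <- graph_edges(net$graph)
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(c(paste0("nodedef>name VARCHAR,label VARCHAR,is_seed BOOLEAN,",
                      "module VARCHAR,role VARCHAR,pagerank DOUBLE,",
                      "betweenness DOUBLE"),
               node_rows,
               "edgedef>node1 VARCHAR,node2 VARCHAR",
               paste(ed$from, ed$to, sep = ",")), con = con, sep = "\n")
  invisible(path)
}

#' Read a GDF file written by [write_gdf()]
#'
#' @param path File path.
#' @return List with `graph` (igraph over all listed nodes) and `nodes`
#'   (tibble of the node attributes).
#' @export
read_gdf <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  ni <- which(startsWith(lines, "nodedef>"))
  ei <- which(startsWith(lines, "edgedef>"))
  if (length(ni) != 1L || length(ei) != 1L || ei < ni)
    rlang::abort("not a GDF file written by this package")
  parse_rows <- function(rows, n_fields) {
    if (!length(rows)) return(matrix(character(), ncol = n_fields))
    do.call(rbind, strsplit(rows, ",", fixed = TRUE))
  }
  nm <- parse_rows(if (ei > ni + 1L) lines[(ni + 1L):(ei - 1L)] else character(), 7L)
  em <- parse_rows(if (ei < length(lines)) lines[(ei + 1L):length(lines)] else character(), 2L)
  nodes <- tibble::tibble(node = nm[, 1], label = nm[, 2],
                          is_seed = nm[, 3] == "true",
                          module = ifelse(nm[, 4] == "", NA_integer_,
                                          suppressWarnings(as.integer(nm[, 4]))),
                          role = nm[, 5],
                          pagerank = as.numeric(nm[, 6]),
                          betweenness = as.numeric(nm[, 7]))
  g <- ppi_graph(data.frame(a = em[, 1], b = em[, 2]), nodes = nodes$node)
  list(graph = g, nodes = nodes)
}
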
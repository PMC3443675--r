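test_that("planted-partition extremes give cliques and reproducible graphs", {
  pp <- planted_partition_graph(c(4L, 3L), p_in = 1, p_out = 0, rng_seed = 1)
  comp <- igraph::components(pp$graph)
  expect_equal(comp$no, 2)
  expect_equal(igraph::ecount(pp$graph), choose(4, 2) + choose(3, 2))
  expect_true(validate_graph(pp$graph))
  # determinism
  a <- planted_partition_graph(c(10L, 10L), 0.5, 0.1, rng_seed = 7)
  b <- planted_partition_graph(c(10L, 10L), 0.5, 0.1, rng_seed = 7)
  expect_true(igraph::identical_graphs(a$graph, b$graph))
  expect_identical(a$labels, b$labels)
  c_ <- planted_partition_graph(c(10L, 10L), 0.5, 0.1, rng_seed = 8)
  expect_false(igraph::identical_graphs(a$graph, c_$graph))
})

test_that("single-block edge counts match the binomial mean within 3 SD", {
  m <- choose(10, 2); p <- 0.5
  counts <- vapply(1:200, function(s) {
    igraph::ecount(planted_partition_graph(10L, p, 0, rng_seed = s)$graph)
  }, double(1))
  mean_expected <- m * p
  sd_mean <- sqrt(m * p * (1 - p) / 200)
  expect_lt(abs(mean(counts) - mean_expected), 3 * sd_mean)
})

test_that("multi-source sampling covers the graph and has binomial support", {
  pp <- planted_partition_graph(c(10L, 10L), 0.6, 0.05, rng_seed = 11)
  # coverage 1: every source reports every edge; intersection recovers g
  recs <- make_multisource_kb(pp$graph, n_sources = 3L, coverage = 1, rng_seed = 1)
  m <- id_map(names(pp$labels), names(pp$labels))
  kb <- merge_sources(recs, m)
  # edge-for-edge identical to g (k-votes strips isolated nodes)
  expect_equal(graph_edges(kvotes_filter(kb, 3)), graph_edges(pp$graph))
  # single source, partial coverage: union equals the sampled subset
  recs1 <- make_multisource_kb(pp$graph, n_sources = 1L, coverage = 0.5,
                               rng_seed = 2)
  kb1 <- merge_sources(recs1, m)
  expect_equal(igraph::ecount(kvotes_filter(kb1, 1)), nrow(unique(recs1[1:2])))
  # expected support per edge ~ n_sources * coverage
  recs2 <- make_multisource_kb(pp$graph, n_sources = 5L, coverage = 0.8,
                               rng_seed = 3)
  kb2 <- merge_sources(recs2, m)
  n_edges <- igraph::ecount(pp$graph)
  mean_support <- sum(kb2$support$n_sources) / n_edges
  sd_mean <- sqrt(5 * 0.8 * 0.2 / n_edges)
  expect_lt(abs(mean_support - 4), 3 * sd_mean + 0.05)
})

test_that("aligned annotations mirror blocks exactly when noise-free", {
  pp <- planted_partition_graph(c(6L, 5L), 0.8, 0.05, rng_seed = 4)
  coll <- make_aligned_annotations(pp$labels, n_decoy_sets = 0L, noise = 0,
                                   rng_seed = 5)
  expect_equal(nrow(coll$sets), 2)
  expect_setequal(coll$sets$genes[[1]], names(pp$labels)[pp$labels == 1])
  expect_setequal(coll$universe, names(pp$labels))
  # with noise, size preserved but membership perturbed
  coll_n <- make_aligned_annotations(pp$labels, n_decoy_sets = 2L, noise = 0.3,
                                     rng_seed = 6)
  expect_equal(lengths(coll_n$sets$genes[1:2]), c(6L, 5L))
  expect_equal(nrow(coll_n$sets), 4)
  # determinism
  coll_n2 <- make_aligned_annotations(pp$labels, n_decoy_sets = 2L, noise = 0.3,
                                      rng_seed = 6)
  expect_identical(coll_n$sets, coll_n2$sets)
})

test_that("seed sampling floors the fraction and respects block boundaries", {
  pp <- planted_partition_graph(c(20L, 20L, 20L), 0.9, 0.02, rng_seed = 9)
  s1 <- sample_seeds(pp$labels, 1L, 0.5, rng_seed = 10)
  expect_length(s1, 10)
  expect_true(all(pp$labels[s1] == 1))
  s_all <- sample_seeds(pp$labels, 2L, 1, rng_seed = 10)
  expect_setequal(s_all, names(pp$labels)[pp$labels == 2])
  s12 <- sample_seeds(pp$labels, 1:2, 0.5, rng_seed = 10)
  expect_length(intersect(s12, names(pp$labels)[pp$labels == 3]), 0)
  expect_error(sample_seeds(pp$labels, 99L, 0.5), "unknown block")
})

test_that("scenario writing produces the four input files and reloads", {
  dir <- withr::local_tempdir()
  sc <- make_scenario(rng_seed = 21, dir = dir)
  expect_true(all(file.exists(unlist(sc$paths))))
  expect_equal(nrow(read_edge_tsv(sc$paths$interactions)), nrow(sc$records))
  m <- read_id_map(sc$paths$id_map)
  expect_equal(map_ids("SYM_G0001", m)$mapped, "g0001")
  expect_setequal(read_seed_list(sc$paths$seeds), sc$seeds)
  coll <- read_gmt(sc$paths$gmt)
  expect_equal(nrow(coll$sets), nrow(sc$collection$sets))
})
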
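test_that("the hypergeometric tail reproduces worked values and edge cases", {
  expect_equal(fisher_greater(0, 6, 5, 50), 1.0)
  expect_equal(fisher_greater(3, 6, 5, 50), oracle_hyper_tail(3, 6, 5, 50),
               tolerance = 1e-12)
  expect_equal(fisher_greater(3, 6, 5, 50), 9.244086e-3, tolerance = 1e-7)
  expect_equal(fisher_greater(4, 50, 10, 50), 1.0)   # set equals universe
  expect_error(fisher_greater(6, 5, 10, 50), "margins")
  expect_error(fisher_greater(1, 5, 60, 50), "margins")
})

test_that("the tail agrees with exhaustive enumeration on all small tables", {
  for (N in c(5L, 11L, 23L)) {
    for (K in seq(0L, N, by = 3L)) for (n in seq(1L, N, by = 3L)) {
      for (k in 0:min(K, n)) {
        expect_equal(fisher_greater(k, K, n, N), oracle_hyper_tail(k, K, n, N),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the tail is monotone in k and symmetric in the margins", {
  for (case in list(c(8, 12, 40), c(3, 3, 10), c(20, 25, 60))) {
    K <- case[1]; n <- case[2]; N <- case[3]
    ps <- vapply(0:min(K, n), function(k) fisher_greater(k, K, n, N), double(1))
    expect_true(all(diff(ps) <= 1e-15))
    for (k in 0:min(K, n)) {
      expect_equal(fisher_greater(k, K, n, N), fisher_greater(k, n, K, N),
                   tolerance = 1e-12)
    }
  }
})

test_that("module enrichment filters to the universe and sorts by p-value", {
  coll <- gene_set_collection(tibble::tibble(
    set_id = c("s1", "s2", "s3"),
    genes = list(c("a", "b", "c", "d"), c("a", "x1"), c("x2", "x3", "x4"))))
  expect_equal(length(coll$universe), 8)
  res <- enrich_module(c("a", "b", "c", "offworld"), coll)
  expect_equal(res$set_id, c("s1", "s2"))               # s3 overlap 0 dropped
  expect_equal(res$k, c(3L, 1L))
  expect_equal(res$module_size, c(3L, 3L))              # offworld excluded
  expect_equal(res$p_value,
               c(oracle_hyper_tail(3, 4, 3, 8), oracle_hyper_tail(1, 2, 3, 8)),
               tolerance = 1e-12)
  # disjoint module
  expect_equal(nrow(enrich_module("nowhere", coll)), 0)
  # module equal to one set in a larger universe ranks that set first
  coll2 <- gene_set_collection(tibble::tibble(
    set_id = c("hit", "other"),
    genes = list(c("a", "b"), c("p", "q", "r", "s", "t", "u"))))
  expect_equal(enrich_module(c("a", "b"), coll2)$set_id[1], "hit")
})

test_that("seed overlaps are flagged and FDR column is optional", {
  coll <- gene_set_collection(tibble::tibble(
    set_id = "s1", genes = list(c("a", "b", "c", "d", "e"))))
  res <- enrich_module(c("a", "b"), coll, seeds = "a", fdr = TRUE)
  expect_equal(res$seed_overlap_genes, "a")
  expect_true("p_adjust" %in% names(res))
  res2 <- enrich_module(c("a", "b"), coll)
  expect_false("p_adjust" %in% names(res2))
})

test_that("GMT files round-trip and carry names through", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("sA\tpathway A\tg1\tg2\tg3", "sB\tpathway B\tg2\tg4"), path)
  coll <- read_gmt(path)
  expect_equal(coll$sets$set_id, c("sA", "sB"))
  expect_equal(coll$sets$name, c("pathway A", "pathway B"))
  expect_setequal(coll$universe, c("g1", "g2", "g3", "g4"))
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, out)
  coll2 <- read_gmt(out)
  expect_equal(coll2$sets$genes, coll$sets$genes)
  # restricted universe trims members
  coll3 <- read_gmt(path, universe = c("g1", "g2", "g4"))
  expect_equal(coll3$sets$genes[[1]], c("g1", "g2"))
})

test_that("p-values print in the report convention below 1e-4", {
  expect_equal(format_p_value(c(0.5, 2e-5, 0.00015)),
               c("0.5", "<0.0001", "0.00015"))
})

test_that("planted-block sets win the enrichment of their module", {
  wins <- 0L; total <- 0L
  for (rep in 1:10) {
    pp <- planted_partition_graph(rep(15L, 3L), 0.9, 0.03, rng_seed = 6000L + rep)
    coll <- make_aligned_annotations(pp$labels, n_decoy_sets = 5L, noise = 0.1,
                                     rng_seed = 6100L + rep)
    cl <- scan_cluster(pp$graph)
    for (i in seq_along(cl$modules)) {
      mod <- cl$modules[[i]]
      if (length(mod) < 5) next
      block <- names(which.max(table(pp$labels[mod])))
      res <- enrich_module(mod, coll)
      total <- total + 1L
      if (nrow(res) && res$set_id[1] == paste0("block_", block)) wins <- wins + 1L
    }
  }
  expect_gte(wins / total, 0.95)
})
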
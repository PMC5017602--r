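# Native enrichment engine: running-sum ES, permutation null, NES and p.

ranked_fixture <- function(genes, stats = rev(seq_along(genes))) {
  structure(data.frame(gene_id = genes, statistic = as.numeric(stats)),
            class = c("ranked_list", "data.frame"))
}

test_that("extreme single-gene sets reach the ES bounds", {
  rk <- ranked_fixture(paste0("g", 1:5))
  expect_equal(enrichment_score(rk, "g1")$es, 1.0)
  expect_equal(enrichment_score(rk, "g5")$es, -1.0)
})

test_that("the 4-step walk matches its hand enumeration", {
  # N = 4, set = {gene at rank 2}: steps -1/3, +1, -1/3, -1/3
  rk <- ranked_fixture(paste0("g", 1:4))
  res <- enrichment_score(rk, "g2")
  expect_equal(res$running_sum, c(-1/3, 2/3, 1/3, 0))
  expect_equal(res$es, 2/3)
  expect_identical(res$leading_edge, "g2")
})

test_that("degenerate sets are rejected", {
  rk <- ranked_fixture(paste0("g", 1:4))
  expect_error(enrichment_score(rk, c("x", "y")), "no overlap")
  expect_error(enrichment_score(rk, paste0("g", 1:4)), "whole universe")
})

test_that("weight-0 ES is within [-1,1], ends at 0 and negates on reversal", {
  set.seed(11)
  for (rep in 1:25) {
    N <- sample(5:40, 1)
    k <- sample(1:(N - 1), 1)
    genes <- paste0("g", seq_len(N))
    rk <- ranked_fixture(genes, stats = sort(rnorm(N), decreasing = TRUE))
    set_genes <- sample(genes, k)
    res <- enrichment_score(rk, set_genes)
    expect_lte(abs(res$es), 1)
    expect_equal(res$running_sum[N], 0, tolerance = 1e-12)
    expect_equal(res$es, oracle_es_walk(genes %in% set_genes))
    rev_rk <- ranked_fixture(rev(genes), stats = sort(rnorm(N), decreasing = TRUE))
    rev_es <- enrichment_score(rev_rk, set_genes)$es
    # reversal preserves the deviation magnitude always, and negates the
    # score whenever its sign is determined (no max/min deviation tie)
    expect_equal(abs(rev_es), abs(res$es), tolerance = 1e-12)
    tie <- abs(max(res$running_sum) + min(res$running_sum)) < 1e-12
    if (!tie) expect_equal(rev_es, -res$es, tolerance = 1e-12)
  }
})

test_that("weighted ES steps are proportional to |statistic|^weight", {
  rk <- ranked_fixture(paste0("g", 1:4), stats = c(4, 3, 2, 1))
  res <- enrichment_score(rk, c("g1", "g3"), weight = 1)
  # hit weights 4 and 2 (sum 6); misses step -1/2
  expect_equal(res$running_sum, c(4/6, 4/6 - 1/2, 4/6 - 1/2 + 2/6, 0))
  expect_equal(res$es, 4/6)
})

test_that("NES and p follow the signed add-one convention", {
  r <- nes_and_p(0.6, c(0.2, 0.4, -0.3))
  expect_equal(r$nes, 2.0)
  expect_equal(r$p_perm, 1/3)

  r2 <- nes_and_p(0.5, rep(0.5, 4))
  expect_equal(r2$nes, 1.0)
  expect_equal(r2$p_perm, 1.0)

  # es above every same-signed null: the add-one floor 1/(B+1)
  r3 <- nes_and_p(0.9, c(0.1, 0.2, 0.3, -0.5))
  expect_equal(r3$p_perm, 1/4)

  # no null shares the sign: NES undefined
  r4 <- nes_and_p(0.5, c(-0.1, -0.2))
  expect_true(is.na(r4$nes))
})

test_that("permutation nulls are reproducible and exhaustive mode enumerates once", {
  fx <- make_two_group_matrix(n_genes = 30, n1 = 3, n2 = 3, shifted = 5,
                              delta = 1.5, seed = 3)
  set5 <- fx$shifted_genes
  n1 <- permutation_null(fx$matrix, fx$annotations, "target", set5,
                         n_perm = 50, seed = 42)
  n2 <- permutation_null(fx$matrix, fx$annotations, "target", set5,
                         n_perm = 50, seed = 42)
  expect_identical(n1, n2)

  ex <- permutation_null(fx$matrix, fx$annotations, "target", set5,
                         exhaustive = TRUE, seed = 0)
  expect_length(ex, choose(6, 3))
  # the observed labeling is one of the enumerated relabelings
  rk <- rank_genes(fx$matrix, fx$annotations, "target")
  expect_true(any(abs(ex - enrichment_score(rk, set5)$es) < 1e-12))
})

test_that("gene_label nulls of a singleton set come from the N possible scores", {
  fx <- make_two_group_matrix(n_genes = 10, n1 = 5, n2 = 5, shifted = 0, seed = 9)
  rk <- rank_genes(fx$matrix, fx$annotations, "target")
  possible <- vapply(rk$gene_id, function(g) enrichment_score(rk, g)$es, numeric(1))
  null <- permutation_null(fx$matrix, fx$annotations, "target", rk$gene_id[1],
                           n_perm = 200, seed = 1, mode = "gene_label")
  expect_true(all(vapply(null, function(v) any(abs(v - possible) < 1e-12), logical(1))))
  # and all 10 scores appear in 200 draws with near-certainty
  expect_length(unique(round(null, 12)), 10L)
})

test_that("gsea detects a planted signal and reports a tight p", {
  fx <- make_two_group_matrix(n_genes = 300, n1 = 10, n2 = 10, shifted = 30,
                              delta = 2, sd = 1, seed = 0)
  res <- gsea(fx$matrix, fx$annotations, "target", fx$shifted_genes,
              n_perm = 199, seed = 0)
  expect_identical(res$mode, "phenotype")
  expect_gt(res$es, 0)
  expect_lte(res$p_perm, 0.05)
  expect_true(all(res$leading_edge %in% fx$shifted_genes))
  expect_error(gsea(fx$matrix, fx$annotations, "target", c("nope1", "nope2"),
                    n_perm = 19, seed = 0), "no overlap")
})

test_that("auto mode falls back to gene_label for small groups", {
  fx <- make_two_group_matrix(n_genes = 50, n1 = 3, n2 = 8, shifted = 5, seed = 2)
  res <- gsea(fx$matrix, fx$annotations, "target", fx$shifted_genes,
              n_perm = 49, seed = 0)
  expect_identical(res$mode, "gene_label")
})

test_that("type-I error of the permutation p is near nominal under the null", {
  # 200 unshifted cohorts; fraction of p <= 0.05 should be close to 0.05
  hits <- vapply(1:200, function(r) {
    fx <- make_two_group_matrix(n_genes = 120, n1 = 8, n2 = 8, shifted = 0,
                                seed = 5000 + r)
    set.seed(r)
    gs <- sample(rownames(fx$matrix), 15)
    res <- gsea(fx$matrix, fx$annotations, "target", gs, n_perm = 99, seed = r)
    res$p_perm <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.09)
})

test_that("enrichment results export as TSV", {
  fx <- make_two_group_matrix(n_genes = 50, n1 = 5, n2 = 5, shifted = 10, seed = 6)
  res <- gsea(fx$matrix, fx$annotations, "target", fx$shifted_genes,
              n_perm = 49, seed = 1)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_results(res, out)
  tab <- utils::read.delim(out)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$es, res$es, tolerance = 1e-12)
  expect_equal(tab$p_perm, res$p_perm, tolerance = 1e-12)
})
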
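test_that("gene matching is a case-insensitive inner join", {
  a <- diff_table(c("G1", "G2"), c(1, -1), c(0.01, 0.2))
  b <- diff_table(c("g2", "G3"), c(0.5, 2), c(0.03, 0.8))
  paired <- suppressMessages(match_genes(a, b))
  expect_equal(paired$gene_symbol, "G2")
  expect_equal(paired$lfc_a, -1)
  expect_equal(paired$lfc_b, 0.5)

  disjoint <- diff_table("G9", 1, 0.5)
  expect_warning(suppressMessages(match_genes(a, disjoint)), "no genes in common")

  selfp <- suppressMessages(match_genes(a, a))
  expect_equal(selfp$lfc_a, selfp$lfc_b)
  expect_equal(nrow(selfp), 2)

  dup <- diff_table(c("G1", "g1"), c(1, 1), c(0.1, 0.1))
  expect_error(suppressMessages(match_genes(dup, b)), "duplicate")
})

test_that("the five concordance categories follow the stated rules", {
  paired <- data.frame(
    gene_symbol = sprintf("G%d", 1:4),
    lfc_a = c(1.2, 1.2, 1.2, 0.4), padj_a = c(0.01, 0.01, 0.01, 0.5),
    lfc_b = c(0.8, -0.8, 0.8, 0.3), padj_b = c(0.03, 0.03, 0.50, 0.9))
  out <- classify_concordance(paired, alpha = 0.05)
  expect_equal(out$records$category,
               c("both_concordant", "both_opposite", "only_a", "neither"))
  expect_equal(sum(out$counts), nrow(paired))

  # symmetry: swapping datasets exchanges only_a and only_b
  swapped <- data.frame(gene_symbol = paired$gene_symbol,
                        lfc_a = paired$lfc_b, padj_a = paired$padj_b,
                        lfc_b = paired$lfc_a, padj_b = paired$padj_a)
  out2 <- classify_concordance(swapped, alpha = 0.05)
  map <- c(both_concordant = "both_concordant", both_opposite = "both_opposite",
           only_a = "only_b", only_b = "only_a", neither = "neither")
  expect_equal(unname(map[out$records$category]), out2$records$category)

  # lfc exactly 0 with both significant counts as concordant
  zero <- data.frame(gene_symbol = "Z", lfc_a = 0, padj_a = 0.01,
                     lfc_b = -1, padj_b = 0.01)
  expect_equal(classify_concordance(zero)$records$category, "both_concordant")

  expect_error(classify_concordance(paired, alpha = 1.5), "alpha")
})

test_that("fold-change correlation matches the raw-definition oracle", {
  p <- data.frame(gene_symbol = sprintf("G%d", 1:4),
                  lfc_a = c(1, 2, 3, 4), padj_a = 0.5,
                  lfc_b = c(1, 3, 2, 4), padj_b = 0.5)
  ct <- correlation_with_test(p)
  expect_equal(ct$r, 0.8)
  expect_equal(ct$n, 4)

  p$lfc_b <- p$lfc_a
  expect_equal(correlation_with_test(p)$r, 1)
  p$lfc_b <- -p$lfc_a
  expect_equal(correlation_with_test(p)$r, -1)

  set.seed(23)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    q <- data.frame(gene_symbol = sprintf("G%d", 1:n),
                    lfc_a = rnorm(n), padj_a = 0.5,
                    lfc_b = rnorm(n), padj_b = 0.5)
    expect_equal(correlation_with_test(q)$r, oracle_pearson(q$lfc_a, q$lfc_b),
                 tolerance = 1e-12)
  }
  const <- data.frame(gene_symbol = c("a", "b", "c"), lfc_a = c(1, 1, 1),
                      padj_a = 0.5, lfc_b = rnorm(3), padj_b = 0.5)
  expect_error(correlation_with_test(const), "zero variance")
})

test_that("strong-responder quadrants require both cutoffs in both datasets", {
  paired <- data.frame(
    gene_symbol = c("Gin", "Gcut", "Gdown", "Gbig"),
    lfc_a = c(0.6, 0.6, -1.0, 1.0), padj_a = rep(0.01, 4),
    lfc_b = c(0.7, 0.4, -1.0, 1.0), padj_b = rep(0.01, 4))
  rec <- classify_concordance(paired)$records
  out <- strong_responders(rec, lfc_cut = 0.5, alpha = 0.05, top_k = 1)
  expect_equal(out$strong_quadrant[out$gene_symbol == "Gin"], "both_up")
  expect_equal(out$strong_quadrant[out$gene_symbol == "Gcut"], "none")
  expect_equal(out$strong_quadrant[out$gene_symbol == "Gdown"], "both_down")
  # ranking by summed |lfc|: Gbig (2.0) above Gin (1.3)
  expect_equal(out$quadrant_rank[out$gene_symbol == "Gbig"], 1L)
  expect_equal(out$quadrant_rank[out$gene_symbol == "Gin"], 2L)
  expect_true(out$top_labelled[out$gene_symbol == "Gbig"])
  expect_false(out$top_labelled[out$gene_symbol == "Gin"])
})

test_that("triple concordance keeps consistent down genes, ranked and flagged", {
  a <- diff_table(c("G1", "G2", "G3", "G4"), c(-1, -0.5, -1, -1),
                  c(0.01, 0.01, 0.01, 0.01))
  b <- diff_table(c("g1", "g2", "g3", "g4"), c(-2, -0.5, 0.3, -0.2),
                  c(0.01, 0.01, 0.01, 0.01))
  cc <- diff_table(c("G1", "G2", "G3", "G4"), c(-0.5, -2, -1, -1),
                   c(0.01, 0.01, 0.01, 0.2))
  wt <- diff_table(c("G1", "G2"), c(1.4, -0.2), c(0.01, 0.01))
  out <- suppressMessages(triple_concordance(a, b, cc, wt, rank_by = "b"))
  # G3 excluded (positive lfc in b), G4 excluded (not significant in c)
  expect_equal(out$gene_symbol, c("G1", "G2"))
  # most negative ranking lfc first: b fold changes -2 < -0.5
  expect_equal(out$rank, c(1L, 2L))
  expect_equal(out$lfc_b, c(-2, -0.5))
  expect_true(out$no_inducible[1])    # induced by stimulation in WT
  expect_false(out$no_inducible[2])

  # absent from the wt_stim table -> NA flag
  out2 <- suppressMessages(triple_concordance(a, b, cc, wt[1, ], rank_by = "b"))
  expect_true(is.na(out2$no_inducible[2]))

  # ties in the ranking fold change break by gene symbol
  b2 <- diff_table(c("g1", "g2"), c(-1, -1), c(0.01, 0.01))
  out3 <- suppressMessages(triple_concordance(a[1:2, ], b2, cc[1:2, ], wt,
                                              rank_by = "b"))
  expect_equal(out3$gene_symbol, c("G1", "G2"))
})
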
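log2_im <- function(v) {
  structure(list(values = v, design = NULL, scale_state = "log2"),
            class = "intensity_matrix")
}

test_that("PCA variance shares, orientation and completeness hold", {
  set.seed(14)
  v <- matrix(rnorm(20 * 8, 20), 20, 8,
              dimnames = list(sprintf("f%02d", 1:20), sprintf("s%d", 1:8)))
  pc <- run_pca(log2_im(v))
  expect_equal(sum(pc$variance_explained), 100, tolerance = 1e-6)
  # loadings columns are orthonormal
  g <- crossprod(pc$loadings)
  expect_equal(g, diag(ncol(pc$loadings)), tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: dominant loading of each component is positive
  for (k in seq_len(ncol(pc$loadings))) {
    l <- pc$loadings[, k]
    expect_gte(l[which.max(abs(l))], 0)
  }
  # reconstruction from all components reproduces the scaled matrix
  x <- scale(t(v))
  expect_equal(pc$scores %*% t(pc$loadings), x, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("component SDs of 2 and 1 yield variance shares of 80% and 20%", {
  # two unit-variance features with empirical correlation exactly 0.6 give
  # principal variances 1.6 and 0.4, i.e. component SDs in ratio 2:1 and
  # variance shares 4/(4+1) and 1/(4+1)
  set.seed(15)
  n_s <- 50
  raw <- scale(cbind(rnorm(n_s), rnorm(n_s)))
  e1 <- raw[, 1] / sqrt(sum(raw[, 1]^2))
  e2 <- raw[, 2] - sum(raw[, 2] * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  v <- t(cbind(e1, 0.6 * e1 + 0.8 * e2))
  dimnames(v) <- list(c("f1", "f2"), sprintf("s%03d", seq_len(n_s)))
  pc <- run_pca(log2_im(v))
  expect_equal(pc$variance_explained, c(80, 20), tolerance = 1e-9)
})

test_that("duplicating every sample leaves PCA loadings unchanged", {
  set.seed(16)
  v <- matrix(rnorm(30 * 6, 20), 30, 6,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%d", 1:6)))
  v2 <- cbind(v, v)
  colnames(v2) <- sprintf("s%02d", 1:12)
  p1 <- run_pca(log2_im(v))
  p2 <- run_pca(log2_im(v2))
  k <- min(5, ncol(p1$loadings), ncol(p2$loadings))
  expect_equal(abs(p1$loadings[, 1:k]), abs(p2$loadings[, 1:k]), tolerance = 1e-6)
})

test_that("contributor selection applies the mean +/- k*sd rule", {
  set.seed(7)
  l <- rnorm(500, 0, 0.1)
  names(l) <- sprintf("f%03d", 1:500)
  l[c(13, 377)] <- c(1, -1)
  sel <- select_contributors(l, 2)
  expect_true("f013" %in% sel$positive)
  expect_true("f377" %in% sel$negative)
  # exact agreement with direct evaluation of the rule
  expect_identical(sel$positive, names(l)[l > mean(l) + 2 * sd(l)])
  expect_identical(sel$negative, names(l)[l < mean(l) - 2 * sd(l)])

  tight <- setNames(rnorm(100, 0, 0.01), sprintf("g%d", 1:100))
  sel2 <- select_contributors(tight, 5)
  expect_length(sel2$positive, 0)
  expect_length(sel2$negative, 0)

  sel0 <- select_contributors(l, 0)
  expect_setequal(c(sel0$positive, sel0$negative), names(l)[l != mean(l)])

  expect_warning(out <- select_contributors(setNames(rep(1, 5), letters[1:5])),
                 "constant")
  expect_length(out$positive, 0)
})

test_that("correlation-distance Ward clustering matches its definition", {
  set.seed(18)
  base <- rnorm(10)
  v <- rbind(a = base, b = 2 * base + 5, c = -base, d = rnorm(10), e = rnorm(10))
  colnames(v) <- sprintf("s%d", 1:10)
  z <- structure(list(values = v, design = NULL, scale_state = "zscored"),
                 class = "intensity_matrix")
  cl <- cluster_rows(z)
  # proportional rows have distance 0 and merge first
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(hclust_merge_sets(cl$hclust)[[1]], c(1, 2))
  # anti-correlated rows sit at distance 2
  d <- 1 - cor(t(v))
  expect_equal(d["a", "c"], 2, tolerance = 1e-12)

  # merge order equals the naive recompute-everything oracle
  orc <- oracle_ward_merges(as.dist(d))
  expect_equal(hclust_merge_sets(cl$hclust), orc$merges)
  expect_equal(cl$hclust$height, orc$heights, tolerance = 1e-9)

  vc <- rbind(v, const = rep(3, 10))
  zc <- structure(list(values = vc, design = NULL, scale_state = "zscored"),
                  class = "intensity_matrix")
  expect_error(cluster_rows(zc), "constant")
})

test_that("dendrograms export as parseable Newick", {
  set.seed(19)
  v <- matrix(rnorm(40), 4, 10,
              dimnames = list(sprintf("f%d", 1:4), sprintf("s%d", 1:10)))
  z <- structure(list(values = v, design = NULL, scale_state = "zscored"),
                 class = "intensity_matrix")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cluster_rows(z), path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(v))
})

test_that("the four NO-dependence rules label the documented effect triples", {
  expect_equal(classify_effect_triple(1.0, 0.2), "NO_dep_up")      # no_effect 0.8
  expect_equal(classify_effect_triple(-0.6, 0.1), "NO_dep_down")   # no_effect -0.7
  expect_equal(classify_effect_triple(0.5, 0.5), "NO_independent") # no_effect 0
  expect_equal(classify_effect_triple(0.3, 0.1), "under_threshold")
})

test_that("classification from z-scores computes condition-mean effects", {
  des <- raw_design(replicates = 2)
  # one gene engineered so condition means are exactly known
  zrow <- numeric(nrow(des))
  zrow[des$genotype == "WT" & des$stimulation == "stim"] <- 1.2
  zrow[des$genotype == "WT" & des$stimulation == "unstim"] <- -0.4
  zrow[des$genotype == "iNOS_KO" & des$stimulation == "stim"] <- -0.2
  zrow[des$genotype == "iNOS_KO" & des$stimulation == "unstim"] <- -0.6
  v <- rbind(g1 = zrow)
  colnames(v) <- des$sample_id
  z <- structure(list(values = v, design = des, scale_state = "zscored"),
                 class = "intensity_matrix")
  cls <- classify_no_dependence(z)
  expect_equal(cls$wt_stim_effect, 1.6)
  expect_equal(cls$inos_stim_effect, 0.4)
  expect_equal(cls$no_effect, 1.2)
  expect_equal(cls$no_effect, cls$wt_stim_effect - cls$inos_stim_effect,
               tolerance = 1e-12)
  expect_equal(cls$category, "NO_dep_up")

  des_missing <- des[des$stimulation == "stim", ]
  zm <- structure(list(values = v[, des_missing$sample_id, drop = FALSE],
                       design = des_missing, scale_state = "zscored"),
                  class = "intensity_matrix")
  expect_error(classify_no_dependence(zm), "four donor-free")
})
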
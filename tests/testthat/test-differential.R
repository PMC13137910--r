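test_that("welch_test reproduces the hand-computed example and symmetries", {
  w <- welch_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(w$t, -1.0954451, tolerance = 1e-6)
  expect_equal(w$df, 6)
  expect_equal(w$p, 2 * pt(-1.0954451, 6), tolerance = 1e-6)

  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(0.3, 1.2, 2.2, 0.9); b <- c(1.8, 2.5, 2.0)
  expect_equal(welch_test(a, b)$t, -welch_test(b, a)$t)
  expect_equal(welch_test(a, b)$p, welch_test(b, a)$p)

  expect_error(welch_test(c(1, 1), c(2, 2)), "zero pooled")
  expect_equal(welch_test(c(1, 1), c(1, 1))$p, 1)
  expect_error(welch_test(1, c(1, 2)), ">= 2")
})

test_that("welch_test matches the direct-formula oracle on random draws", {
  set.seed(21)
  for (i in 1:200) {
    x <- rnorm(sample(2:10, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(2:10, 1), mean = runif(1, -1, 1))
    w <- welch_test(x, y)
    o <- oracle_welch(x, y)
    expect_equal(w$t, o$t, tolerance = 1e-12)
    expect_equal(w$df, o$df, tolerance = 1e-12)
    expect_equal(w$p, o$p, tolerance = 1e-10)
  }
})

test_that("BH adjustment evaluates the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.1, 1.1)), "\\(0, 1\\]")
})

test_that("differential intensity testing recovers construction and symmetry", {
  des <- raw_design()
  set.seed(31)
  n <- 60
  base <- 2^rnorm(n, 20, 1)
  noise <- matrix(2^rnorm(n * nrow(des), 0, 0.05), n)
  fold <- ifelse(des$genotype == "iNOS_KO" & des$stimulation == "stim", 2, 1)
  v <- (base %o% fold) * noise
  dimnames(v) <- list(sprintf("g%03d", 1:n), des$sample_id)
  m <- intensity_matrix(v, design = des)
  de <- diff_intensity(m, no_contrast)
  expect_equal(mean(de$log2fc), 1, tolerance = 0.05)
  expect_true(all(abs(de$log2fc - 1) < 0.3))

  # antisymmetry under swapping reference and contrast
  flipped <- contrast_spec(reference = no_contrast$contrast,
                           contrast = no_contrast$reference, label = "flip")
  de2 <- diff_intensity(m, flipped)
  expect_equal(de2$log2fc, -de$log2fc)
  expect_equal(de2$p_raw, de$p_raw, tolerance = 1e-12)

  # permuting sample columns within groups changes nothing
  perm <- sample(ncol(v))
  mp <- intensity_matrix(v[, perm], design = des[perm, ])
  expect_equal(diff_intensity(mp, no_contrast), de)

  empty_ref <- contrast_spec(reference = list(donor = "DETA"),
                             contrast = list(genotype = "WT"), label = "bad")
  expect_error(diff_intensity(m, empty_ref), "at least 2")
})

test_that("size factors follow the median-of-ratios definition", {
  cm <- count_matrix(matrix(c(4, 10, 8, 20), 2, 2,
                            dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  expect_equal(unname(size_factors(cm)), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-7)

  same <- count_matrix(matrix(rep(c(5, 9, 14), 3), 3, 3,
                              dimnames = list(letters[1:3], sprintf("s%d", 1:3))))
  expect_equal(unname(size_factors(same)), rep(1, 3))

  set.seed(8)
  v <- matrix(rpois(60, 40) + 1, 10, 6,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:6)))
  sf <- size_factors(count_matrix(v))
  # size factors are defined up to a global scale (the geometric-mean
  # reference moves too), so scaling one sample by c multiplies its size
  # factor relative to any other sample by c
  v2 <- v; v2[, 3] <- v2[, 3] * 5
  sf2 <- size_factors(count_matrix(v2))
  expect_equal((sf2[3] / sf2[1]) / (sf[3] / sf[1]), 5, tolerance = 1e-12,
               ignore_attr = TRUE)

  zeros <- count_matrix(matrix(c(0, 1, 1, 0), 2, 2,
                               dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_error(size_factors(zeros), "all-positive")
})

test_that("size factors agree with the reference NB-GLM implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(12)
  v <- matrix(rnbinom(200 * 8, mu = 80, size = 10), 200, 8,
              dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:8)))
  expect_equal(unname(size_factors(count_matrix(v))),
               unname(DESeq2::estimateSizeFactorsForMatrix(v)), tolerance = 1e-8)
})

test_that("low-count filtering applies the fewer-than-10-reads rule", {
  v <- rbind(nine = c(4, 3, 2, 0), ten = c(4, 3, 2, 1), big = c(20, 10, 10, 10))
  colnames(v) <- sprintf("s%d", 1:4)
  cm <- count_matrix(v)
  f <- suppressMessages(filter_low_counts(cm, 10))
  expect_identical(rownames(f$values), c("ten", "big"))
  expect_identical(suppressMessages(filter_low_counts(cm, 0))$values, cm$values)
})

test_that("NB Wald recovers planted fold changes on balanced simulated data", {
  set.seed(42)
  des <- factorial_design(genotypes = "WT", replicates = 8)
  n <- 2000; up <- 1:500; down <- 501:1000
  mu0 <- exp(rnorm(n, log(200), 1))
  fc <- rep(1, n); fc[up] <- 2; fc[down] <- 0.5
  stim <- des$stimulation == "stim"
  cnt <- sapply(seq_len(nrow(des)), function(j) {
    rnbinom(n, mu = if (stim[j]) mu0 * fc else mu0, size = 1 / 0.05)
  })
  dimnames(cnt) <- list(sprintf("g%04d", 1:n), des$sample_id)
  de <- suppressMessages(nb_wald(count_matrix(cnt, design = des), wt_stim_contrast))
  iu <- match(sprintf("g%04d", up), de$gene_symbol)
  expect_lt(abs(mean(de$log2fc[iu]) - 1), 0.1)
  expect_gt(mean(de$p_adj[iu] < 0.05), 0.9)
  inull <- match(sprintf("g%04d", 1001:2000), de$gene_symbol)
  expect_lt(abs(mean(de$log2fc[inull])), 0.05)
})

test_that("NB Wald handles identical groups and zero-mean genes", {
  des <- factorial_design(genotypes = "WT", replicates = 3)
  v <- matrix(rep(c(10, 20, 30, 40), each = 6), 4, 6, byrow = TRUE,
              dimnames = list(sprintf("g%d", 1:4), des$sample_id))
  de <- suppressMessages(nb_wald(count_matrix(v, design = des), wt_stim_contrast))
  expect_equal(de$log2fc, rep(0, 4))

  v2 <- v
  v2["g2", des$stimulation == "stim"] <- 0
  de2 <- suppressMessages(nb_wald(count_matrix(v2, design = des), wt_stim_contrast))
  expect_equal(de2$log2fc[de2$gene_symbol == "g2"], -10)
  expect_true(de2$lfc_capped[de2$gene_symbol == "g2"])
})
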
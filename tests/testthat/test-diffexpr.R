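test_that("fpkm matches the plug-in formula and is depth-scale invariant", {
  counts <- rbind(f1 = c(10, 20), f2 = c(999990, 1999980))
  colnames(counts) <- c("s1", "s2")
  x <- expression_matrix(counts, c("A-ED", "NC"), "mRNA",
                         lengths = c(f1 = 1000, f2 = 2000))
  f <- fpkm(x)
  expect_equal(f["f1", "s1"], 10)  # 10 reads, 1 kb, 1e6 library
  # doubling every count (and hence the library) leaves FPKM unchanged
  x2 <- expression_matrix(counts * 2, c("A-ED", "NC"), "mRNA",
                          lengths = c(f1 = 1000, f2 = 2000))
  expect_equal(fpkm(x2), f)
  x3 <- expression_matrix(counts, c("A-ED", "NC"), "mRNA")
  expect_error(fpkm(x3), "lengths")
})

test_that("fpkm agrees with a naive per-cell recomputation", {
  cfg <- sim_config(seed = 3, n_lnc = 40, n_mir = 6, n_mrna = 10,
                    n_planted_triplets = 2)
  x <- simulate_counts(cfg)$lncRNA
  f <- fpkm(x)
  lib <- colSums(x$counts)
  for (i in sample(nrow(x$counts), 10)) {
    for (j in seq_len(ncol(x$counts))) {
      expect_equal(f[i, j],
                   as.numeric(x$counts[i, j] * 1e9 / (x$lengths[i] * lib[j])),
                   tolerance = 1e-9)
    }
  }
})

test_that("TMM factors are 1 for identical or purely depth-shifted samples", {
  counts <- cbind(s1 = c(10, 50, 100, 3, 7), s2 = c(10, 50, 100, 3, 7),
                  s3 = c(20, 100, 200, 6, 14), s4 = c(10, 50, 100, 3, 7))
  rownames(counts) <- sprintf("f%d", 1:5)
  x <- expression_matrix(counts, c("A-ED", "A-ED", "NC", "NC"), "mRNA")
  nf <- normalization_factors(x)
  expect_equal(unname(nf$factors), rep(1, 4), tolerance = 1e-12)
  expect_equal(exp(mean(log(nf$factors))), 1, tolerance = 1e-12)
  bad <- counts; bad[, 2] <- 0
  expect_error(expression_matrix(bad, c("A-ED", "A-ED", "NC", "NC"), "mRNA"),
               NA)  # zeros are valid counts
  expect_error(normalization_factors(
    expression_matrix(bad, c("A-ED", "A-ED", "NC", "NC"), "mRNA")), "all-zero")
})

test_that("effective library sizes track the planted multipliers", {
  cfg <- sim_config(seed = 8, n_lnc = 5, n_mir = 5, n_mrna = 2000,
                    n_planted_triplets = 0, lib_size_range = c(0.5, 2))
  sim <- simulate_counts(cfg)
  nf <- normalization_factors(sim$mRNA)
  rho <- cor(nf$effective_lib_size, sim$lib_sizes[names(nf$effective_lib_size)],
             method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("TMM factors agree with the independent edgeR implementation", {
  skip_if_not_installed("edgeR")
  cfg <- sim_config(seed = 8, n_lnc = 5, n_mir = 5, n_mrna = 1000,
                    n_planted_triplets = 0)
  x <- simulate_counts(cfg)$mRNA
  ours <- normalization_factors(x)$factors
  theirs <- edgeR::calcNormFactors(x$counts, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
})

test_that("exact test returns p = 1 under exact symmetry and for all-zero features", {
  counts <- matrix(rep(c(5, 9, 13, 0), 6), nrow = 4,
                   dimnames = list(c("a", "b", "c", "zero"), sprintf("s%d", 1:6)))
  x <- expression_matrix(counts, rep(c("A-ED", "NC"), each = 3), "mRNA")
  res <- exact_test(x)
  expect_equal(res$p, rep(1, 4))
  expect_equal(res$log2FC[res$feature_id == "zero"], 0)
})

test_that("swapping group labels negates log2FC and preserves p", {
  cfg <- sim_config(seed = 12, n_lnc = 5, n_mir = 6, n_mrna = 60,
                    n_planted_triplets = 2)
  x <- simulate_counts(cfg)$mRNA
  y <- x
  y$groups <- factor(ifelse(x$groups == "A-ED", "NC", "A-ED"),
                     levels = c("NC", "A-ED"))
  a <- exact_test(x); b <- exact_test(y)
  expect_equal(b$log2FC, -a$log2FC, tolerance = 1e-10)
  expect_equal(b$p, a$p, tolerance = 1e-10)
})

test_that("null p-values are roughly uniform and BH keeps fdr >= p", {
  cfg <- sim_config(seed = 5, n_lnc = 5, n_mir = 5, n_mrna = 2000,
                    n_planted_triplets = 0, dispersion = 0.1)
  res <- exact_test(simulate_counts(cfg)$mRNA)
  expect_gt(mean(res$p < 0.05), 0.025)
  expect_lt(mean(res$p < 0.05), 0.075)
  expect_true(all(res$fdr >= res$p - 1e-15))
  # BH is monotone in the rank of p
  ord <- order(res$p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-15))
})

test_that("DE and candidate filters use strict inequalities", {
  res <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    rna_class = "lncRNA",
    log2FC = c(2.5, 2.0, 2.5, 1.2),
    p = c(0.05, 0.01, 0.01, 0.01),
    fdr = c(0.1, 0.05, 0.05, 0.05),
    direction = "up", stringsAsFactors = FALSE
  )
  kept <- apply_de_filter(res, lfc_threshold = 2, p_threshold = 0.05)
  expect_identical(kept$feature_id, "c")  # a: p not < 0.05; b: |lfc| not > 2

  counts <- rbind(a = rep(119, 6), b = rep(120, 6), c = rep(1, 6), d = rep(50, 6))
  colnames(counts) <- sprintf("s%d", 1:6)
  x <- expression_matrix(counts, rep(c("A-ED", "NC"), each = 3), "lncRNA")
  res2 <- data.frame(
    feature_id = c("a", "b", "c", "d"), rna_class = "lncRNA",
    log2FC = c(1.5, 1.5, 1.5, 1.5), p = rep(0.01, 4), fdr = rep(0.02, 4),
    direction = "up", stringsAsFactors = FALSE
  )
  cand <- select_candidate_lncrnas(res2, x)
  # mean count must lie strictly inside (1, 120)
  expect_setequal(cand$feature_id, c("a", "d"))
})

test_that("single-sample groups are flagged untested with p = 1", {
  counts <- matrix(c(50, 9, 3, 80, 20, 30, 60, 25, 40), nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  x <- expression_matrix(counts, c("A-ED", "NC", "NC"), "mRNA")
  res <- exact_test(x)
  expect_false(any(res$tested))
  expect_equal(res$p, rep(1, 3))
})
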
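make_counts <- function(m) {
  colnames(m) <- sprintf("d%d_R%d", rep(c(7, 14), each = 2), rep(1:2, 2))[seq_len(ncol(m))]
  if (is.null(rownames(m))) rownames(m) <- sprintf("p%d", seq_len(nrow(m)))
  count_matrix(m, parse_sample_names(colnames(m)))
}

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(rep(c(10L, 40L, 100L), 4), 3, 4)
  expect_equal(unname(estimate_size_factors(make_counts(m))), rep(1, 4))

  set.seed(3)
  x <- matrix(rpois(200, 50) + 1L, 100, 2)
  x[, 2] <- 2L * x[, 1]
  # doubled-column pair: factors 1/sqrt(2) and sqrt(2)
  sf2 <- estimate_size_factors(make_counts(x))
  expect_equal(unname(sf2), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
})

test_that("peaks with zeros are excluded from the reference and errors advise pseudocounts", {
  m <- matrix(c(0L, 10L, 10L, 10L, 20L, 20L), 3, 2)
  # row 1 has a zero: reference built from rows 2-3 only; col2 doubled
  sf <- estimate_size_factors(make_counts(m))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  all_zero <- matrix(c(0L, 5L, 3L, 0L), 2, 2)
  expect_error(estimate_size_factors(make_counts(all_zero)), "pseudocount")
})

test_that("size factors are order invariant and scale equivariant", {
  set.seed(4)
  m <- matrix(rpois(400, 80) + 1L, 100, 4)
  cm <- make_counts(m)
  sf <- estimate_size_factors(cm)
  perm <- sample(nrow(m))
  expect_equal(estimate_size_factors(make_counts(m[perm, ])), sf)
  # scaling one sample by c multiplies its factor by c relative to the others
  m2 <- m; m2[, 3] <- m2[, 3] * 5L
  sf2 <- estimate_size_factors(make_counts(m2))
  expect_equal(unname(sf2[3] / sf2[1]), unname(5 * sf[3] / sf[1]),
               tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  m <- matrix(rnbinom(1200, mu = 150, size = 10) + 1L, 300, 4)
  ours <- estimate_size_factors(make_counts(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("normalization maps counts to log2(count/factor + pseudocount)", {
  m <- matrix(c(0L, 6L, 8L, 12L), 2, 2)
  cm <- make_counts(m)
  norm <- normalize_counts(cm, factors = c(1, 2))
  expect_equal(norm[1, 1], 0)           # zero count -> log2(1) = 0
  expect_equal(norm[2, 1], log2(7))
  expect_equal(norm[1, 2], log2(4 + 1)) # 8/2 + 1
  # monotone in counts for fixed factor
  expect_true(all(diff(normalize_counts(make_counts(matrix(c(0:3, 0:3), 4, 2)),
                                        factors = c(1, 1))[, 1]) > 0))
})

test_that("pairwise test gives null results on identical groups and needs replicates", {
  set.seed(6)
  mu <- rep(200, 500)
  m <- matrix(rnbinom(500 * 8, mu = mu, size = 20), 500, 8)
  rownames(m) <- sprintf("p%d", 1:500)
  colnames(m) <- sprintf("d%d_R%d", rep(c(7, 14), each = 4), rep(1:4, 2))
  cm <- count_matrix(m, parse_sample_names(colnames(m)))
  res <- pairwise_differential(cm, 7, 14)
  expect_lt(mean(abs(res$log2_fc)), 0.2)
  expect_gt(mean(res$p_value), 0.35)  # no systematic signal
  expect_true(all(res$fdr >= res$p_value - 1e-12))
  one_rep <- count_matrix(m[, c(1, 5), drop = FALSE],
                          parse_sample_names(colnames(m)[c(1, 5)]))
  expect_error(pairwise_differential(one_rep, 7, 14), ">= 2 replicates")
})

test_that("FDR column equals hand-computed Benjamini-Hochberg", {
  expect_equal(bf_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  set.seed(7)
  m <- matrix(rnbinom(200 * 4, mu = 150, size = 10), 200, 4)
  rownames(m) <- sprintf("p%d", 1:200)
  colnames(m) <- c("d7_R1", "d7_R2", "d14_R1", "d14_R2")
  res <- pairwise_differential(count_matrix(m, parse_sample_names(colnames(m))), 7, 14)
  expect_equal(res$fdr, bf_bh(res$p_value))
})

test_that("a planted 64-fold change is detected at P < 0.01 in >= 95% of simulations", {
  set.seed(8)
  n_sim <- 200
  a <- matrix(rnbinom(n_sim * 2, mu = 200 * 64, size = 20), n_sim, 2)
  b <- matrix(rnbinom(n_sim * 2, mu = 200, size = 20), n_sim, 2)
  m <- cbind(a, b)
  rownames(m) <- sprintf("p%d", seq_len(n_sim))
  colnames(m) <- c("d7_R1", "d7_R2", "d14_R1", "d14_R2")
  cm <- count_matrix(m, parse_sample_names(colnames(m)))
  res <- pairwise_differential(cm, 7, 14, factors = rep(1, 4))
  expect_gte(mean(res$p_value < 0.01), 0.95)
  expect_equal(median(res$log2_fc), 6, tolerance = 0.1)
})

test_that("p-values are approximately uniform under the global null", {
  set.seed(9)
  n <- 5000
  m <- matrix(rnbinom(n * 12, mu = 200, size = 20), n, 12)
  rownames(m) <- sprintf("p%d", 1:n)
  colnames(m) <- sprintf("d%d_R%d", rep(c(7, 14), each = 6), rep(1:6, 2))
  cm <- count_matrix(m, parse_sample_names(colnames(m)))
  res <- pairwise_differential(cm, 7, 14, factors = rep(1, 12))
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("intrinsic scores separate between-timepoint from replicate variance", {
  set.seed(10)
  base <- matrix(rnorm(50 * 4, mean = rep(1:4, each = 50)), 50, 4)
  dup <- base[, rep(1:4, each = 2)]  # exact replicate duplication: within = 0
  colnames(dup) <- sprintf("d%d_R%d", rep(c(7, 14, 19, 21), each = 2), rep(1:2, 4))
  rownames(dup) <- sprintf("p%d", 1:50)
  sc <- intrinsic_scores(dup)
  expect_true(all(is.finite(sc$intrinsic_z)))
  # shift invariance
  sc2 <- intrinsic_scores(dup + 7)
  expect_equal(sc2$intrinsic_z, sc$intrinsic_z)
  one_tp <- dup[, 1:2]
  expect_error(intrinsic_scores(one_tp), ">= 2 timepoints")
  no_rep <- dup[, c(1, 3, 5, 7)]
  expect_error(intrinsic_scores(no_rep), ">= 2 replicates")
})

test_that("selection respects thresholds, modes and monotonicity", {
  d <- get_diff(42)
  ds <- get_sim(42)
  sel_u <- d$sel
  sel_i <- select_differential_peaks(d$res, d$intr, mode = "intersection")
  expect_true(all(sel_i$selected %in% sel_u$selected))
  # nothing passes absurd thresholds
  sel_none <- select_differential_peaks(
    d$res, d$intr, thresholds = list(p = 1e-300, abs_log2_fc = 100, fdr = 1e-300, z = 100))
  expect_length(sel_none$selected, 0)
  # loosening any threshold never shrinks the set
  sel_loose <- select_differential_peaks(
    d$res, d$intr, thresholds = list(p = 0.05, abs_log2_fc = 3, fdr = 0.05, z = 0.5))
  expect_true(all(sel_u$selected %in% sel_loose$selected))
})

test_that("selection recovers the recoverable planted peaks and excludes stable ones", {
  ds <- get_sim(42)
  d <- get_diff(42)
  labs <- ds$truth$cluster_labels
  # planted differential peaks whose fold exceeds the |log2 FC| > 5 gate
  # even from the partially open day-7 baseline are always recovered
  strong <- names(labs)[labs %in% c("I", "III") & ds$truth$folds > 40]
  expect_gte(mean(strong %in% d$sel$selected), 0.98)
  stable <- names(labs)[labs == "stable"]
  expect_gte(mean(!stable %in% d$sel$selected), 0.90)
  # the selected set carries all three planted temporal patterns
  expect_setequal(unique(labs[d$sel$selected][labs[d$sel$selected] != "stable"]),
                  c("I", "II", "III"))
})
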
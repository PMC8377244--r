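#' Median-of-ratios size factors
#'
#' Per-sample scale factors for sequencing-depth normalization. The
#' reference is the per-peak geometric mean across samples (peaks with any
#' zero count are excluded from the reference set); each sample's factor is
#' the median across peaks of its counts over the reference.
#'
#' @param counts a [count_matrix()] or plain integer matrix.
#' @return Named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  m <- counts_of(counts)
  if (ncol(m) < 2) stop("estimate_size_factors: need >= 2 samples")
  use <- rowSums(m == 0) == 0
  if (!any(use)) {
    stop("estimate_size_factors: no peak has nonzero counts in all samples; ",
         "add a pseudocount to the matrix first")
  }
  lm <- log(m[use, , drop = FALSE])
  ref <- rowMeans(lm)
  sf <- exp(apply(lm - ref, 2, stats::median))
  stats::setNames(sf, colnames(m))
}

counts_of <- function(x) if (inherits(x, "count_matrix")) x$counts else x

samples_of <- function(x) {
  if (inherits(x, "count_matrix")) return(x$samples)
  parse_sample_names(colnames(x))
}

#' Normalized log2 accessibility matrix
#'
#' `log2(count / size_factor + pseudocount)`.
#'
#' @param counts a [count_matrix()] or matrix.
#' @param factors size factors from [estimate_size_factors()]; estimated if
#'   `NULL`.
#' @param pseudocount added before the log (default 1, so a zero count maps
#'   to 0).
#' @return Numeric matrix, same dimnames as the counts.
#' @export
normalize_counts <- function(counts, factors = NULL, pseudocount = 1) {
  m <- counts_of(counts)
  if (is.null(factors)) factors <- estimate_size_factors(m)
  if (length(factors) != ncol(m)) stop("normalize_counts: factors do not match samples")
  log2(sweep(m, 2, factors, "/") + pseudocount)
}

#' Size-factor-normalized linear-scale matrix
#'
#' `count / size_factor + pseudocount`; the scale on which stage
#' fold-change criteria are evaluated.
#'
#' @inheritParams normalize_counts
#' @export
normalize_linear <- function(counts, factors = NULL, pseudocount = 1) {
  m <- counts_of(counts)
  if (is.null(factors)) factors <- estimate_size_factors(m)
  sweep(m, 2, factors, "/") + pseudocount
}

#' Pairwise differential accessibility test between two timepoints
#'
#' Negative-binomial Wald test on size-factor-normalized counts. The log2
#' fold change is the ratio of normalized group means (pseudocount 1), the
#' per-peak dispersion is a pooled within-group method-of-moments estimate
#' (floored at 1e-8), the Wald statistic divides the fold change by its
#' delta-method standard error under Var = mu + alpha mu^2, and the p value
#' is two-sided normal. FDR is Benjamini-Hochberg within the comparison.
#'
#' @param counts a [count_matrix()].
#' @param group_a,group_b timepoint days defining the two groups; each must
#'   have >= 2 replicate samples.
#' @param factors optional precomputed size factors.
#' @return data.frame with columns `peak`, `log2_fc` (a over b), `p_value`,
#'   `fdr`, `mean_a`, `mean_b`.
#' @export
pairwise_differential <- function(counts, group_a, group_b, factors = NULL) {
  m <- counts_of(counts)
  meta <- samples_of(counts)
  ia <- which(meta$day == group_a)
  ib <- which(meta$day == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("pairwise_differential: each group needs >= 2 replicates ",
         "(variance is undefined otherwise)")
  }
  if (is.null(factors)) factors <- estimate_size_factors(m)
  y <- sweep(m, 2, factors, "/")
  ya <- y[, ia, drop = FALSE]; yb <- y[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  mu_a <- rowMeans(ya); mu_b <- rowMeans(yb)
  va <- apply(ya, 1, stats::var); vb <- apply(yb, 1, stats::var)
  s2_pool <- (va * (na - 1) + vb * (nb - 1)) / (na + nb - 2)
  mu_pool <- (na * mu_a + nb * mu_b) / (na + nb)
  alpha <- pmax((s2_pool - mu_pool) / pmax(mu_pool, 1e-8)^2, 1e-8)
  lfc <- log2((mu_a + 1) / (mu_b + 1))
  nb_var <- function(mu) mu + alpha * mu^2
  se <- sqrt(nb_var(mu_a) / (na * (mu_a + 1)^2) +
             nb_var(mu_b) / (nb * (mu_b + 1)^2)) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(peak = rownames(m), log2_fc = lfc, p_value = p,
             fdr = stats::p.adjust(p, "BH"),
             mean_a = mu_a, mean_b = mu_b, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' All pairwise comparisons across the timepoint categories
#'
#' Runs [pairwise_differential()] for every unordered pair of timepoints
#' (28 comparisons for an 8-timepoint design).
#'
#' @param counts a [count_matrix()].
#' @param factors optional precomputed size factors.
#' @return Named list of per-comparison data.frames (`"dA_vs_dB"`).
#' @export
all_pairwise_differential <- function(counts, factors = NULL) {
  meta <- samples_of(counts)
  days <- sort(unique(meta$day))
  if (is.null(factors)) factors <- estimate_size_factors(counts_of(counts))
  pairs <- utils::combn(days, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    pairwise_differential(counts, pairs[1, i], pairs[2, i], factors)
  })
  names(out) <- apply(pairs, 2, function(p) sprintf("d%d_vs_d%d", p[1], p[2]))
  out
}

#' Intrinsic variance scores
#'
#' Highlights peaks whose accessibility varies across timepoints but not
#' between replicates of the same timepoint. Per peak, `between` is the
#' variance across timepoints of the replicate-mean normalized signal and
#' `within` the mean across timepoints of the replicate variance; the score
#' is `log2((between + eps) / (within + eps))` and is standardized to a
#' z-score over all peaks.
#'
#' @param normalized normalized log2 matrix from [normalize_counts()].
#' @param days integer day per column (taken from column names `d<day>_R<i>`
#'   if omitted).
#' @param eps variance floor guarding the ratio (default 0.01).
#' @return data.frame with columns `peak`, `score`, `intrinsic_z`.
#' @export
intrinsic_scores <- function(normalized, days = NULL, eps = 0.01) {
  if (is.null(days)) days <- parse_sample_names(colnames(normalized))$day
  ud <- sort(unique(days))
  if (length(ud) < 2) stop("intrinsic_scores: need >= 2 timepoints")
  if (any(table(days) < 2)) stop("intrinsic_scores: every timepoint needs >= 2 replicates")
  day_means <- sapply(ud, function(d) rowMeans(normalized[, days == d, drop = FALSE]))
  day_vars <- sapply(ud, function(d) apply(normalized[, days == d, drop = FALSE], 1, stats::var))
  between <- apply(day_means, 1, stats::var)
  within <- rowMeans(day_vars)
  score <- log2((between + eps) / (within + eps))
  z <- (score - mean(score)) / stats::sd(score)
  data.frame(peak = rownames(normalized), score = score, intrinsic_z = z,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select differentially accessible peaks
#'
#' A peak passes the pairwise criterion if it is significant in at least one
#' pairwise comparison at all three thresholds (p, |log2 FC|, FDR); the
#' final set is the union (default) or intersection with the intrinsic
#' criterion (z-score above `z`).
#'
#' @param results list from [all_pairwise_differential()].
#' @param intrinsic data.frame from [intrinsic_scores()].
#' @param thresholds list with `p`, `abs_log2_fc`, `fdr`, `z` (defaults
#'   0.01, 5, 0.01, 1).
#' @param mode `"union"` or `"intersection"` of the two criteria.
#' @return List with `selected` (peak names), `passes_pairwise`,
#'   `passes_intrinsic` (logical vectors named by peak), and `counts` per
#'   criterion.
#' @export
select_differential_peaks <- function(results, intrinsic,
                                      thresholds = list(p = 0.01, abs_log2_fc = 5,
                                                        fdr = 0.01, z = 1),
                                      mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  peaks <- results[[1]]$peak
  pass_pw <- rep(FALSE, length(peaks))
  for (res in results) {
    pass_pw <- pass_pw | (res$p_value < thresholds$p &
                          abs(res$log2_fc) > thresholds$abs_log2_fc &
                          res$fdr < thresholds$fdr)
  }
  names(pass_pw) <- peaks
  pass_in <- stats::setNames(intrinsic$intrinsic_z > thresholds$z, intrinsic$peak)
  pass_in <- pass_in[peaks]
  sel <- if (mode == "union") pass_pw | pass_in else pass_pw & pass_in
  list(selected = peaks[sel],
       passes_pairwise = pass_pw,
       passes_intrinsic = pass_in,
       counts = c(pairwise = sum(pass_pw), intrinsic = sum(pass_in),
                  selected = sum(sel)),
       mode = mode, thresholds = thresholds)
}
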
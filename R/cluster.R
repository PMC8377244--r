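#' Center (and scale) matrix rows
#'
#' Each row is shifted to mean zero and, by default, scaled to unit
#' variance. Zero-variance rows are left centered but unscaled and recorded
#' in the `"flagged"` attribute. Idempotent.
#'
#' @param m numeric matrix with >= 2 columns.
#' @param scale divide rows by their standard deviation (default `TRUE`).
#' @return Matrix of the same shape; attribute `"flagged"` holds the row
#'   names (or indices) of constant rows.
#' @export
center_rows <- function(m, scale = TRUE) {
  if (ncol(m) < 2) stop("center_rows: need >= 2 columns")
  mu <- rowMeans(m)
  out <- m - mu
  flagged <- character(0)
  if (scale) {
    sds <- apply(out, 1, stats::sd)
    zero <- sds == 0 | !is.finite(sds)
    out[!zero, ] <- out[!zero, , drop = FALSE] / sds[!zero]
    flagged <- if (!is.null(rownames(m))) rownames(m)[zero] else as.character(which(zero))
  }
  attr(out, "flagged") <- flagged
  out
}

cor_dist <- function(m) {
  # rows of m as observations; 1 - Pearson correlation
  stats::as.dist(1 - stats::cor(t(m)))
}

#' Hierarchical clustering with correlation distance
#'
#' Average-linkage hierarchical clustering of rows (or columns) under
#' distance `1 - Pearson correlation`. If a range of candidate k is given,
#' k is selected by maximum mean silhouette width.
#'
#' @param m numeric matrix.
#' @param axis `"rows"` or `"cols"`.
#' @param k fixed number of clusters, or `NULL` to use `k_range`.
#' @param k_range candidate k values for silhouette selection (default 2:8).
#' @return List with `labels` (integer cluster per row/col, labels
#'   contiguous from 1 in order of first appearance), `k`, `silhouette`
#'   (named vector over candidates, `NA` when k fixed), and the `hclust`
#'   tree.
#' @export
hier_cluster <- function(m, axis = c("rows", "cols"), k = NULL, k_range = 2:8) {
  axis <- match.arg(axis)
  x <- if (axis == "rows") m else t(m)
  n <- nrow(x)
  if (!is.null(k) && k > n) stop("hier_cluster: k exceeds number of items")
  d <- cor_dist(x)
  tree <- stats::hclust(d, method = "average")
  sil <- NULL
  if (is.null(k)) {
    k_range <- k_range[k_range <= n - 1 & k_range >= 2]
    if (!length(k_range)) stop("hier_cluster: no feasible k in k_range")
    sil <- vapply(k_range, function(kk) {
      mean(cluster::silhouette(stats::cutree(tree, k = kk), d)[, "sil_width"])
    }, 0)
    names(sil) <- k_range
    k <- k_range[which.max(sil)]
  }
  raw <- stats::cutree(tree, k = k)
  labels <- match(raw, unique(raw))  # contiguous from 1 by first appearance
  names(labels) <- rownames(x)
  list(labels = labels, k = k, silhouette = sil, tree = tree, dist = d)
}

#' PCA of samples
#'
#' Principal components of the sample (column) vectors after row
#' centering/scaling.
#'
#' @param m numeric matrix (features x samples).
#' @param scale scale rows to unit variance before PCA (default `TRUE`).
#' @return List with `coords` (samples x PCs), `var_explained`
#'   (non-increasing, sums to <= 1).
#' @export
pca_samples <- function(m, scale = TRUE) {
  if (ncol(m) < 2) stop("pca_samples: need >= 2 samples")
  x <- center_rows(m, scale = scale)
  p <- stats::prcomp(t(x), center = FALSE, scale. = FALSE)
  list(coords = p$x, var_explained = p$sdev^2 / sum(p$sdev^2))
}

#' Cluster samples into stages on principal components
#'
#' Partitioning-around-medoids (PAM) on the first two PCs with k selected
#' by maximum mean silhouette width.
#'
#' @param coords sample x PC coordinate matrix from [pca_samples()].
#' @param k fixed k, or `NULL` for silhouette selection over `k_range`.
#' @param k_range candidate k (default 2:6).
#' @param n_pcs number of leading PCs to use (default 2).
#' @return List with `labels`, `k`, `silhouette` over candidates.
#' @export
cluster_samples <- function(coords, k = NULL, k_range = 2:6, n_pcs = 2) {
  x <- coords[, seq_len(min(n_pcs, ncol(coords))), drop = FALSE]
  sil <- NULL
  if (is.null(k)) {
    k_range <- k_range[k_range <= nrow(x) - 1 & k_range >= 2]
    sil <- vapply(k_range, function(kk) cluster::pam(x, kk)$silinfo$avg.width, 0)
    names(sil) <- k_range
    k <- k_range[which.max(sil)]
  }
  fit <- cluster::pam(x, k)
  list(labels = fit$clustering, k = k, silhouette = sil)
}

#' Stage-specific elements
#'
#' An element (peak or gene) is specific to stage S when its mean
#' normalized linear-scale signal in S exceeds `fc` times the maximum mean
#' over all other stages.
#'
#' @param m numeric matrix on the linear normalized scale (see
#'   [normalize_linear()]; for log-scale expression pass `2^values`).
#' @param groups factor/vector of stage labels, one per column; every
#'   level must have >= 1 column.
#' @param fc fold-change threshold (default 1.5).
#' @return Named list of element-name vectors, one per stage level; the
#'   `"assignment"` attribute maps every row to its stage or `NA`.
#' @export
stage_specific_elements <- function(m, groups, fc = 1.5) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("stage_specific_elements: stage with no samples")
  if (!nrow(m)) {
    out <- stats::setNames(rep(list(character(0)), nlevels(groups)), levels(groups))
    attr(out, "assignment") <- character(0)
    return(out)
  }
  gm <- vapply(levels(groups), function(g) rowMeans(m[, groups == g, drop = FALSE]),
               numeric(nrow(m)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1, dimnames = list(rownames(m), levels(groups)))
  assignment <- rep(NA_character_, nrow(m))
  for (g in levels(groups)) {
    other_max <- apply(gm[, setdiff(colnames(gm), g), drop = FALSE], 1, max)
    hit <- gm[, g] > fc * other_max
    assignment[hit] <- g
  }
  names(assignment) <- rownames(m)
  out <- lapply(levels(groups), function(g) rownames(m)[!is.na(assignment) & assignment == g])
  names(out) <- levels(groups)
  attr(out, "assignment") <- assignment
  out
}

#' Conserved (stage-invariant accessible) elements
#'
#' Peaks whose stage-mean normalized signal is at least `min_signal` at
#' every stage.
#'
#' @inheritParams stage_specific_elements
#' @param min_signal accessibility floor; default is the 25th percentile of
#'   all peak-stage means.
#' @return Character vector of element names; attribute `"min_signal"`.
#' @export
conservative_elements <- function(m, groups, min_signal = NULL) {
  groups <- as.factor(groups)
  gm <- sapply(levels(groups), function(g) rowMeans(m[, groups == g, drop = FALSE]))
  if (is.null(min_signal)) min_signal <- stats::quantile(gm, 0.25)
  if (min_signal < 0) stop("conservative_elements: min_signal must be >= 0")
  keep <- rownames(m)[apply(gm >= min_signal, 1, all)]
  attr(keep, "min_signal") <- unname(min_signal)
  keep
}
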
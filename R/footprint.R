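#' Aggregate insertion signal around motif occurrences
#'
#' Stacks per-base insertion counts in windows of `W` bases either side of
#' each motif hit (minus-strand hits are reversed before stacking) and
#' averages over sites. Sites whose window would run off the covered
#' coordinates are skipped and counted.
#'
#' @param track an `insertion_track` (see [insertion_track()]).
#' @param hits data.frame of hits of one motif with columns `chrom` (or
#'   `seq_name` naming a track chromosome), `start`, `end`, `strand`.
#' @param W window half-width in bp (default 100).
#' @return List of class `footprint_profile`: `profile` (mean insertions
#'   per site per bp, length `2W + L`), `n_sites`, `n_skipped`, `L`, `W`,
#'   `depth` (flank mean minus core mean), `label`.
#' @export
aggregate_footprint <- function(track, hits, W = 100) {
  if (!nrow(hits)) stop("aggregate_footprint: no hits supplied")
  chrom_col <- if ("chrom" %in% names(hits)) "chrom" else "seq_name"
  L <- unique(hits$end - hits$start)
  if (length(L) != 1) stop("aggregate_footprint: hits must come from a single motif length")
  width <- 2L * W + L
  acc <- numeric(width)
  n_used <- 0L; n_skip <- 0L
  for (i in seq_len(nrow(hits))) {
    ch <- hits[[chrom_col]][i]
    cov <- track$cov[[ch]]
    lo <- hits$start[i] - W  # 0-based inclusive
    hi <- hits$end[i] + W    # 0-based exclusive
    if (is.null(cov) || lo < 0 || hi > length(cov)) { n_skip <- n_skip + 1L; next }
    win <- as.numeric(cov[(lo + 1L):hi])
    if (identical(hits$strand[i], "-")) win <- rev(win)
    acc <- acc + win
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("aggregate_footprint: zero usable sites after window extension")
  profile <- acc / n_used
  fp <- structure(list(profile = profile, n_sites = n_used, n_skipped = n_skip,
                       L = L, W = W, label = track$label),
                  class = "footprint_profile")
  fp$depth <- footprint_depth(fp)$depth
  fp
}

#' Footprint depth and flank-normalized profile
#'
#' The core is the central `L` positions (the motif), the flank the
#' outermost `flank_margin` positions on each side. Depth is
#' `mean(flank) - mean(core)` in insertions/site/bp; the normalized profile
#' divides by the flank mean so depths are comparable across timepoints
#' with different global accessibility.
#'
#' @param profile a `footprint_profile` (or bare numeric profile vector, in
#'   which case `L` must be given).
#' @param L motif length (taken from the profile object if omitted).
#' @param flank_margin flank width in bp (default 20); requires `W >
#'   flank_margin`.
#' @return List with `depth`, `normalized` (profile / flank mean, `NULL`
#'   if the flank mean is zero), `core_mean`, `flank_mean`,
#'   `normalized_depth` (depth / flank mean).
#' @export
footprint_depth <- function(profile, L = NULL, flank_margin = 20) {
  if (inherits(profile, "footprint_profile")) {
    v <- profile$profile
    if (is.null(L)) L <- profile$L
    if (profile$W <= flank_margin) stop("footprint_depth: need W > flank_margin")
  } else v <- profile
  n <- length(v)
  core_idx <- ((n - L) %/% 2 + 1L):((n - L) %/% 2 + L)
  flank_idx <- c(seq_len(flank_margin), (n - flank_margin + 1L):n)
  core_mean <- mean(v[core_idx]); flank_mean <- mean(v[flank_idx])
  depth <- flank_mean - core_mean
  normalized <- if (flank_mean > 0) v / flank_mean else NULL
  list(depth = depth, normalized = normalized, core_mean = core_mean,
       flank_mean = flank_mean,
       normalized_depth = if (flank_mean > 0) depth / flank_mean else NA_real_)
}

#' Footprint time course of one motif
#'
#' Aggregates the same hit set against one insertion track per timepoint
#' and reports flank-normalized depths, so deepening protection can be
#' compared along differentiation.
#'
#' @param tracks named list of `insertion_track`s, one per timepoint
#'   (names like `"d7"`).
#' @param hits hits of one motif (see [aggregate_footprint()]).
#' @param W window half-width (default 100).
#' @param flank_margin flank width for depth (default 20).
#' @return List with `profiles` (per-timepoint `footprint_profile`) and
#'   `depths` data.frame (`timepoint`, `depth`, `normalized_depth`,
#'   `n_sites`).
#' @export
footprint_timecourse <- function(tracks, hits, W = 100, flank_margin = 20) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stop("footprint_timecourse: tracks must be named by timepoint")
  }
  profiles <- lapply(names(tracks), function(tp) {
    aggregate_footprint(tracks[[tp]], hits, W)
  })
  names(profiles) <- names(tracks)
  depths <- do.call(rbind, lapply(names(profiles), function(tp) {
    d <- footprint_depth(profiles[[tp]], flank_margin = flank_margin)
    data.frame(timepoint = tp, depth = d$depth,
               normalized_depth = d$normalized_depth,
               n_sites = profiles[[tp]]$n_sites, stringsAsFactors = FALSE)
  }))
  rownames(depths) <- NULL
  list(profiles = profiles, depths = depths)
}
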
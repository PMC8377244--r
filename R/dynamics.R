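#' Mean trajectory of an element set
#'
#' Replicate-averaged mean signal across a set of elements per timepoint,
#' min-max scaled to [0, 1] (for comparing accessibility, expression, and
#' phenotype series on one axis).
#'
#' @param m numeric matrix (elements x samples or elements x timepoints).
#' @param elements row names of the set to average; must be non-empty.
#' @param days integer day per column (parsed from `d<day>_R<i>` or
#'   `d<day>` column names if omitted).
#' @return Numeric vector named by day, in [0, 1]; attributes `"raw"` (the
#'   unscaled per-day means) and `"flat"` (`TRUE` when the series was
#'   constant, in which case zeros are returned).
#' @export
mean_trajectory <- function(m, elements = rownames(m), days = NULL) {
  if (!length(elements)) stop("mean_trajectory: empty element set")
  missing <- setdiff(elements, rownames(m))
  if (length(missing)) stop("mean_trajectory: unknown elements: ",
                            paste(utils::head(missing, 3), collapse = ", "))
  if (is.null(days)) {
    cn <- colnames(m)
    days <- if (all(grepl("^d[0-9]+$", cn))) as.integer(sub("^d", "", cn))
            else parse_sample_names(cn)$day
  }
  sub <- m[elements, , drop = FALSE]
  ud <- sort(unique(days))
  raw <- vapply(ud, function(d) mean(sub[, days == d, drop = FALSE]), 0)
  names(raw) <- ud
  rng <- range(raw)
  flat <- diff(rng) == 0
  scaled <- if (flat) stats::setNames(rep(0, length(raw)), names(raw))
            else (raw - rng[1]) / diff(rng)
  attr(scaled, "raw") <- raw
  attr(scaled, "flat") <- flat
  scaled
}

#' Single change-point (onset) estimation
#'
#' Fits two constant segments to a short series by least squares over all
#' split positions. The onset day is the first timepoint of the second
#' segment (ties broken toward the earlier day). A sub-grid refinement
#' interpolates a parabola through the segment SSE at the best split and
#' its neighbours, using the midpoint between the last day of the first
#' segment and the first day of the second segment as the split coordinate,
#' and returns the vertex as a fractional day (clamped to the neighbouring
#' boundaries). At an edge split, or when the parabola is degenerate, the
#' refined onset equals the grid onset.
#'
#' @param series numeric vector (typically from [mean_trajectory()]).
#' @param timepoints increasing day grid, same length as `series` (>= 3).
#' @return List with `onset_day` (grid day), `onset_refined` (fractional
#'   day), `split` (index of last point in segment 1), `sse` (per-split),
#'   `flat` (`TRUE` and `onset_day = NA` for a constant series).
#' @export
onset_changepoint <- function(series, timepoints = as.numeric(names(series))) {
  n <- length(series)
  if (n < 3) stop("onset_changepoint: need >= 3 timepoints")
  if (length(timepoints) != n || is.unsorted(timepoints, strictly = TRUE)) {
    stop("onset_changepoint: timepoints must be strictly increasing and match the series")
  }
  if (diff(range(series)) == 0) {
    return(list(onset_day = NA_real_, onset_refined = NA_real_, split = NA_integer_,
                sse = rep(NA_real_, n - 1), flat = TRUE))
  }
  sse_two_seg <- function(j) {
    a <- series[1:j]; b <- series[(j + 1):n]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }
  sse <- vapply(seq_len(n - 1), sse_two_seg, 0)
  j <- which.min(sse)  # first minimum -> earlier onset on ties
  onset <- timepoints[j + 1]
  boundary <- (timepoints[-n] + timepoints[-1]) / 2  # split coordinate per j
  refined <- onset
  if (j > 1 && j < n - 1) {
    x <- boundary[(j - 1):(j + 1)]
    y <- sse[(j - 1):(j + 1)]
    d21 <- x[2] - x[1]; d23 <- x[2] - x[3]
    num <- d21^2 * (y[2] - y[3]) - d23^2 * (y[2] - y[1])
    den <- d21 * (y[2] - y[3]) - d23 * (y[2] - y[1])
    if (is.finite(den) && abs(den) > .Machine$double.eps) {
      v <- x[2] - 0.5 * num / den
      refined <- min(max(v, x[1]), x[3])
    } else {
      refined <- boundary[j]
    }
  }
  list(onset_day = onset, onset_refined = refined, split = j, sse = sse,
       flat = FALSE)
}

#' Onset lags between signal classes
#'
#' `lag(a -> b) = onset(b) - onset(a)` in days for every ordered pair of
#' summaries; pairs with a null onset are omitted with a warning.
#'
#' @param onsets named numeric vector of onset days (grid or refined), e.g.
#'   `c(accessibility = 14, expression = 16, phenotype = 28)`.
#' @return data.frame with columns `from`, `to`, `lag_days`.
#' @export
onset_lags <- function(onsets) {
  bad <- names(onsets)[is.na(onsets)]
  if (length(bad)) {
    warning("onset_lags: null onset for ", paste(bad, collapse = ", "), "; omitted")
    onsets <- onsets[!is.na(onsets)]
  }
  if (length(onsets) < 2) stop("onset_lags: need >= 2 non-null onsets")
  pairs <- expand.grid(from = names(onsets), to = names(onsets),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  pairs$lag_days <- onsets[pairs$to] - onsets[pairs$from]
  rownames(pairs) <- NULL
  pairs
}
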
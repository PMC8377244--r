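#' Construct a peak-by-sample count matrix
#'
#' @param counts non-negative integer matrix; rownames = peak names,
#'   colnames = sample names.
#' @param sample_meta data.frame with columns `sample`, `day` (integer
#'   timepoint), `replicate` (e.g. "R1"/"R2"), one row per column of
#'   `counts`.
#' @return List of class `count_matrix` with elements `counts` and `samples`.
#' @export
count_matrix <- function(counts, sample_meta) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count_matrix: counts must have row and column names")
  }
  if (any(counts < 0)) stop("count_matrix: negative counts")
  if (any(counts != round(counts))) stop("count_matrix: counts must be integers")
  if (!all(colnames(counts) == sample_meta$sample)) {
    stop("count_matrix: sample_meta rows must match count columns in order")
  }
  if (anyNA(sample_meta$day)) stop("count_matrix: every sample needs a timepoint")
  structure(list(counts = counts, samples = sample_meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d peaks x %d samples over days %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$samples$day)), collapse = ",")))
  invisible(x)
}

#' Read a TSV matrix of counts or expression values
#'
#' First column holds row identifiers, header holds sample (counts) or
#' timepoint (expression) identifiers. For `kind = "counts"` sample names
#' are parsed as `d<day>_R<rep>`; fractional or negative values are
#' rejected. For `kind = "expression"` column names are parsed as `d<day>`
#' and must be strictly increasing; missing cells are rejected.
#'
#' @param path TSV path.
#' @param kind `"counts"` or `"expression"`.
#' @return A [count_matrix()] or an `expr_matrix` (see [expr_matrix()]).
#' @export
read_matrix <- function(path, kind = c("counts", "expression")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("read_matrix: duplicate row identifiers")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("read_matrix: non-numeric cell in ", path)
  if (anyNA(m)) stop("read_matrix: missing value in ", path)
  rownames(m) <- ids
  if (kind == "counts") {
    if (any(m != round(m))) stop("read_matrix: fractional value in count matrix")
    if (any(m < 0)) stop("read_matrix: negative count")
    meta <- parse_sample_names(colnames(m))
    storage.mode(m) <- "integer"
    count_matrix(m, meta)
  } else {
    days <- as.integer(sub("^d", "", colnames(m)))
    if (anyNA(days)) stop("read_matrix: expression columns must be named d<day>")
    expr_matrix(m, days)
  }
}

parse_sample_names <- function(x) {
  ok <- grepl("^d[0-9]+_R[0-9]+$", x)
  if (!all(ok)) stop("sample names must look like d<day>_R<rep>; offending: ",
                     x[!ok][1])
  data.frame(
    sample = x,
    day = as.integer(sub("^d([0-9]+)_R.*$", "\\1", x)),
    replicate = sub("^d[0-9]+_", "", x),
    stringsAsFactors = FALSE
  )
}

#' Construct a gene-by-timepoint expression matrix
#'
#' @param values numeric matrix, rownames = gene ids, one column per
#'   timepoint (log-scale expression, no missing values).
#' @param timepoints strictly increasing integer days.
#' @param tf_flags optional logical vector (or character vector of gene ids)
#'   marking which genes are transcription factors.
#' @return List of class `expr_matrix` with `values`, `timepoints`, `tf`.
#' @export
expr_matrix <- function(values, timepoints, tf_flags = NULL) {
  if (anyNA(values)) stop("expr_matrix: missing values not allowed")
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("expr_matrix: timepoints must be strictly increasing")
  }
  if (ncol(values) != length(timepoints)) stop("expr_matrix: dimension mismatch")
  colnames(values) <- sprintf("d%d", timepoints)
  tf <- rep(FALSE, nrow(values))
  names(tf) <- rownames(values)
  if (is.character(tf_flags)) tf[intersect(tf_flags, names(tf))] <- TRUE
  if (is.logical(tf_flags)) tf <- stats::setNames(rep_len(tf_flags, nrow(values)), rownames(values))
  structure(list(values = values, timepoints = as.integer(timepoints), tf = tf),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes (%d TFs) x %d timepoints\n",
              nrow(x$values), sum(x$tf), length(x$timepoints)))
  invisible(x)
}

#' Write a matrix as TSV (inverse of [read_matrix()])
#'
#' @param x a [count_matrix()], `expr_matrix`, or plain matrix.
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  m <- if (inherits(x, "count_matrix")) x$counts
       else if (inherits(x, "expr_matrix")) x$values
       else x
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-base insertion tracks as bedGraph
#'
#' An insertion track is a named list of per-base non-negative integer
#' vectors (one per chromosome, 0-based positions) with a sample/timepoint
#' label. bedGraph intervals are run-length encoded; zero runs are omitted
#' on write and implied on read.
#'
#' @param path bedGraph path.
#' @param chrom_lengths named integer vector of chromosome lengths (needed
#'   to restore trailing zeros on read).
#' @param label track label (e.g. `"d14"`).
#' @return `read_bedgraph`: list of class `insertion_track` with `cov`
#'   (named list of integer vectors) and `label`.
#' @export
read_bedgraph <- function(path, chrom_lengths, label = NA_character_) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "value"))
  cov <- lapply(chrom_lengths, function(n) integer(n))
  for (i in seq_len(nrow(tab))) {
    ch <- tab$chrom[i]
    cov[[ch]][(tab$start[i] + 1L):tab$end[i]] <- tab$value[i]
  }
  insertion_track(cov, label)
}

#' @rdname read_bedgraph
#' @param track an `insertion_track`.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$cov)) {
    r <- rle(track$cov[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(paste(ch, starts[keep], ends[keep], r$values[keep], sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname read_bedgraph
#' @param cov named list of per-base integer vectors.
#' @export
insertion_track <- function(cov, label = NA_character_) {
  if (any(vapply(cov, function(v) any(v < 0), TRUE))) {
    stop("insertion_track: negative counts")
  }
  structure(list(cov = cov, label = label), class = "insertion_track")
}
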
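#' Construct a motif set
#'
#' A motif set holds position probability matrices (PPMs) in A/C/G/T row
#' order, one per motif, with a motif identifier and the TF name it belongs
#' to.
#'
#' @param motifs list of motifs; each a list with `id`, `name`, and `prob`
#'   (4 x L matrix, columns summing to 1) and optionally `counts`.
#' @return List of class `motif_set`.
#' @export
motif_set <- function(motifs) {
  ids <- vapply(motifs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("motif_set: duplicate motif ids")
  for (m in motifs) {
    p <- m$prob
    if (!is.matrix(p) || nrow(p) != 4) stop("motif_set: prob must be a 4 x L matrix")
    if (any(abs(colSums(p) - 1) > 1e-6)) stop("motif_set: PPM columns must sum to 1")
  }
  names(motifs) <- ids
  class(motifs) <- "motif_set"
  motifs
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("motif_set with %d motifs (lengths %s)\n", length(x),
              paste(range(vapply(x, function(m) ncol(m$prob), 0L)), collapse = "-")))
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Read motifs from JASPAR PFM text
#'
#' Parses the JASPAR position frequency matrix format: a `>ID NAME` header
#' followed by four rows of counts in A/C/G/T order, either bare numbers or
#' the bracketed `A [ 1 2 3 ]` dialect. Counts are converted to position
#' probabilities after adding a pseudocount split evenly across the four
#' bases per column.
#'
#' @param path path to a JASPAR PFM text file.
#' @param pseudocount total pseudocount added per column (default 0.8, i.e.
#'   0.2 per base).
#' @return A [motif_set()]; each motif keeps the raw `counts` alongside the
#'   normalized `prob` matrix.
#' @export
read_jaspar <- function(path, pseudocount = 0.8) {
  if (!file.exists(path)) stop("read_jaspar: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("read_jaspar: no '>' header found")
  bounds <- c(hdr, length(lines) + 1L)
  motifs <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4) {
      stop("read_jaspar: motif block must have exactly 4 rows (A,C,G,T), got ",
           length(block), " near line ", hdr[i])
    }
    head_fields <- strsplit(sub("^>", "", lines[hdr[i]]), "[ \t]+")[[1]]
    id <- head_fields[1]
    name <- if (length(head_fields) > 1) head_fields[2] else id
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[?", "", trimws(l))
      l <- gsub("\\]", "", l)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "[ \t]+")[[1]]))
      if (anyNA(vals)) stop("read_jaspar: non-numeric count in motif ", id)
      vals
    })
    len <- unique(lengths(rows))
    if (length(len) != 1) stop("read_jaspar: row length mismatch in motif ", id)
    counts <- do.call(rbind, rows)
    rownames(counts) <- DNA_BASES
    if (any(counts < 0)) stop("read_jaspar: negative counts in motif ", id)
    padded <- counts + pseudocount / 4
    prob <- sweep(padded, 2, colSums(padded), "/")
    motifs[[i]] <- list(id = id, name = name, counts = counts, prob = prob)
  }
  motif_set(motifs)
}

#' Write a motif set in JASPAR PFM text format
#'
#' Writes counts when present, otherwise probabilities; inverse of
#' [read_jaspar()] up to the pseudocount normalization.
#'
#' @param ms a [motif_set()].
#' @param path output path.
#' @export
write_jaspar <- function(ms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in ms) {
    mat <- if (!is.null(m$counts)) m$counts else m$prob
    writeLines(sprintf(">%s %s", m$id, m$name), con)
    for (b in 1:4) {
      writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                         paste(format(mat[b, ], trim = TRUE), collapse = " ")), con)
    }
  }
  invisible(path)
}
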
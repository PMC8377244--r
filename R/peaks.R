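#' Construct a peak set
#'
#' A peak set is the accessibility universe: an ordered collection of genomic
#' intervals (0-based, half-open) with unique names, optionally carrying the
#' offset of the peak summit from the interval start.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open coordinates with
#'   `0 <= start < end`.
#' @param name unique interval identifiers; auto-named `peak_<i>` if `NULL`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @param summit_offset optional integer offset of the summit from `start`.
#' @param score optional numeric score (BED column 5).
#' @return A `data.frame` of class `peak_set`, sorted by (chrom, start).
#' @export
peak_set <- function(chrom, start, end, name = NULL, strand = ".",
                     summit_offset = NA_integer_, score = 0) {
  n <- length(chrom)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  ps <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = rep_len(score, n),
    strand = rep_len(as.character(strand), n),
    summit_offset = rep_len(as.integer(summit_offset), n),
    stringsAsFactors = FALSE
  )
  validate_peak_set(ps)
  ps <- ps[order(ps$chrom, ps$start), , drop = FALSE]
  rownames(ps) <- NULL
  class(ps) <- c("peak_set", "data.frame")
  ps
}

validate_peak_set <- function(ps) {
  if (any(ps$start < 0)) stop("peak_set: negative start coordinate")
  bad <- which(ps$start >= ps$end)
  if (length(bad)) {
    stop(sprintf("peak_set: start >= end for interval %d (%s:%d-%d)",
                 bad[1], ps$chrom[bad[1]], ps$start[bad[1]], ps$end[bad[1]]))
  }
  if (!all(ps$strand %in% c("+", "-", "."))) {
    stop("peak_set: strand must be one of '+', '-', '.'")
  }
  if (anyDuplicated(ps$name)) {
    stop("peak_set: interval names must be unique; first duplicate: ",
         ps$name[duplicated(ps$name)][1])
  }
  invisible(ps)
}

#' Read intervals from a BED file
#'
#' BED coordinates are preserved as 0-based half-open. Columns 4-6 are
#' name/score/strand when present; an optional 7th column is interpreted as
#' the summit offset from the interval start. Unnamed rows are auto-named
#' `peak_<i>`.
#'
#' @param path path to a tab-separated BED file (>= 3 columns).
#' @return A [peak_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("read_bed: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(peak_set(character(), integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop(sprintf("read_bed: malformed line %d: fewer than 3 columns",
                 which(ncol < 3)[1]))
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else as.character(default), "")
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("read_bed: malformed line %d: non-integer coordinate",
                 which(is.na(start) | is.na(end))[1]))
  }
  name <- get(4, "")
  name[name == "" | name == "."] <- sprintf("peak_%d", which(name == "" | name == "."))
  score <- suppressWarnings(as.numeric(get(5, "0")))
  score[is.na(score)] <- 0
  strand <- get(6, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  summit <- suppressWarnings(as.integer(get(7, NA)))
  peak_set(get(1, NA), start, end, name, strand, summit, score)
}

#' Write a peak set to BED
#'
#' Inverse of [read_bed()]: coordinates are written unchanged (0-based,
#' half-open), with the summit offset as a 7th column when any is present.
#'
#' @param ps a [peak_set()].
#' @param path output path.
#' @export
write_bed <- function(ps, path) {
  validate_peak_set(ps)
  cols <- list(ps$chrom, ps$start, ps$end, ps$name, ps$score, ps$strand)
  if (any(!is.na(ps$summit_offset))) cols <- c(cols, list(ps$summit_offset))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Extract interval sequences from a genome
#'
#' @param genome named character vector of chromosome sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param ps a [peak_set()].
#' @return Named character vector of sequences (names = interval names).
#' @export
interval_sequences <- function(genome, ps) {
  genome <- as_genome(genome)
  missing <- setdiff(unique(ps$chrom), names(genome))
  if (length(missing)) stop("interval_sequences: chromosome(s) absent from genome: ",
                            paste(missing, collapse = ", "))
  out <- substring(genome[ps$chrom], ps$start + 1L, ps$end)
  names(out) <- ps$name
  out
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  if (!is.character(genome) || is.null(names(genome))) {
    stop("genome must be a named character vector or DNAStringSet")
  }
  genome
}

#' Read / write genome FASTA
#'
#' Thin wrappers over Biostrings FASTA IO returning the package's plain
#' named-character genome representation.
#'
#' @param path FASTA file path.
#' @return `read_genome`: named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  as_genome(Biostrings::readDNAStringSet(path))
}

#' @rdname read_genome
#' @param genome named character vector of chromosome sequences.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(as_genome(genome))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
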
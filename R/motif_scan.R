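#' PWM log-odds matrix
#'
#' Converts a position probability matrix to log2 odds against background:
#' `log2((prob + pc) / (bg + pc))`.
#'
#' @param pwm a motif (list with `prob`) or a bare 4 x L probability matrix.
#' @param background base frequencies in A/C/G/T order (default uniform).
#' @param pc regularizing pseudo-probability (default 1e-3).
#' @return 4 x L numeric matrix of log2 odds.
#' @export
pwm_logodds <- function(pwm, background = rep(0.25, 4), pc = 1e-3) {
  p <- if (is.list(pwm)) pwm$prob else pwm
  log2((p + pc) / (background + pc))
}

#' Maximum attainable PWM score
#'
#' Sum of per-column maxima of the log-odds matrix.
#'
#' @inheritParams pwm_logodds
#' @export
pwm_max_score <- function(pwm, background = rep(0.25, 4), pc = 1e-3) {
  sum(apply(pwm_logodds(pwm, background, pc), 2, max))
}

encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  match(chars, DNA_BASES)  # N and anything else -> NA
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgtNn", "TGCAtgcaNn", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Score every window of an integer-encoded sequence under a log-odds matrix.
# Windows containing NA (ambiguous base) score NA.
score_windows <- function(code, lo) {
  L <- ncol(lo)
  W <- length(code) - L + 1L
  if (W < 1L) return(numeric(0))
  sc <- numeric(W)
  lov <- as.vector(lo)  # column-major: (l-1)*4 + base
  for (l in seq_len(L)) {
    sc <- sc + lov[(l - 1L) * 4L + code[l:(l + W - 1L)]]
  }
  sc
}

#' Scan one sequence with one PWM
#'
#' Scores every window on both strands (the reverse strand via the reverse
#' complement) and reports hits whose score reaches `threshold_frac` times
#' the PWM's maximum attainable score. Windows containing an ambiguous base
#' (N) are skipped. Hits are reported in forward-strand coordinates,
#' 0-based half-open within the sequence.
#'
#' @param seq character scalar over A/C/G/T/N.
#' @param pwm a motif (list with `id`, `prob`) or bare 4 x L PPM.
#' @param threshold_frac hit threshold as a fraction of the maximum score
#'   (default 0.8).
#' @param background,pc passed to [pwm_logodds()].
#' @return data.frame with columns `start`, `end`, `strand`, `score`
#'   (log-odds bits); empty if the sequence is shorter than the motif.
#' @export
scan_sequence <- function(seq, pwm, threshold_frac = 0.8,
                          background = rep(0.25, 4), pc = 1e-3) {
  lo <- pwm_logodds(pwm, background, pc)
  L <- ncol(lo)
  thr <- threshold_frac * pwm_max_score(pwm, background, pc)
  code_f <- encode_dna(seq)
  n <- length(code_f)
  hits <- list()
  sc_f <- score_windows(code_f, lo)
  i <- which(!is.na(sc_f) & sc_f >= thr)
  if (length(i)) {
    hits$f <- data.frame(start = i - 1L, end = i - 1L + L, strand = "+",
                         score = sc_f[i], stringsAsFactors = FALSE)
  }
  sc_r <- score_windows(encode_dna(revcomp(seq)), lo)
  j <- which(!is.na(sc_r) & sc_r >= thr)
  if (length(j)) {
    # window at offset j-1 on the reverse strand starts at n - (j-1) - L forward
    hits$r <- data.frame(start = n - (j - 1L) - L, end = n - (j - 1L), strand = "-",
                         score = sc_r[j], stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(), end = integer(), strand = character(),
               score = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a collection of sequences with a motif set
#'
#' Concatenates the sequences with N spacers so each motif is scanned in a
#' single vectorized pass, then maps hits back to individual sequences.
#' Identical in output to calling [scan_sequence()] per sequence.
#'
#' @param seqs named character vector of sequences.
#' @param motifs a [motif_set()] (or a single motif list).
#' @inheritParams scan_sequence
#' @return data.frame with columns `seq_name`, `motif_id`, `start`, `end`,
#'   `strand`, `score`.
#' @export
scan_sequences <- function(seqs, motifs, threshold_frac = 0.8,
                           background = rep(0.25, 4), pc = 1e-3) {
  if (!inherits(motifs, "motif_set")) motifs <- motif_set(list(motifs))
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%d", seq_along(seqs))
  max_L <- max(vapply(motifs, function(m) ncol(m$prob), 0L))
  spacer <- strrep("N", max_L)
  cat_seq <- paste(seqs, collapse = spacer)
  lens <- nchar(seqs)
  offsets <- cumsum(c(0L, utils::head(lens, -1) + max_L))  # 0-based start of each seq
  code_f <- encode_dna(cat_seq)
  code_r <- encode_dna(revcomp(cat_seq))
  n <- length(code_f)
  seq_of_pos <- function(starts) {
    findInterval(starts, offsets)
  }
  res <- list()
  for (m in motifs) {
    lo <- pwm_logodds(m, background, pc)
    L <- ncol(lo)
    thr <- threshold_frac * sum(apply(lo, 2, max))
    sc_f <- score_windows(code_f, lo)
    i <- which(!is.na(sc_f) & sc_f >= thr)
    sc_r <- score_windows(code_r, lo)
    j <- which(!is.na(sc_r) & sc_r >= thr)
    starts <- c(i - 1L, n - (j - 1L) - L)
    if (!length(starts)) next
    strands <- rep(c("+", "-"), c(length(i), length(j)))
    scores <- c(sc_f[i], sc_r[j])
    k <- seq_of_pos(starts)
    res[[m$id]] <- data.frame(
      seq_name = names(seqs)[k],
      motif_id = m$id,
      start = starts - offsets[k],
      end = starts - offsets[k] + L,
      strand = strands,
      score = scores,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(seq_name = character(), motif_id = character(), start = integer(),
               end = integer(), strand = character(), score = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$motif_id, out$seq_name, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric motif enrichment of a target peak set
#'
#' Peaks are counted by presence/absence of at least one hit. For each
#' motif, enrichment is the hypergeometric upper tail P(X >= k_target) given
#' the universe size, the universe peaks with a hit, and the target size;
#' depletion is the lower tail P(X <= k_target). The signed score is
#' `-log10(p)` with a positive sign for enrichment and negative for
#' depletion (p floored at 1e-300); FDR is Benjamini-Hochberg across motifs.
#'
#' @param target character vector of target peak names (subset of universe).
#' @param universe character vector of all peak names hits were computed on.
#' @param hits data.frame from [scan_sequences()] over the universe
#'   sequences (`seq_name`, `motif_id`).
#' @param motif_ids motifs to report (default: all in `hits`).
#' @return data.frame per motif: `motif_id`, `n_target`, `k_target`,
#'   `n_universe`, `k_universe`, `p_value`, `signed_score`, `fdr`,
#'   `enriched`.
#' @export
enrich_motifs <- function(target, universe, hits, motif_ids = NULL) {
  if (!all(target %in% universe)) stop("enrich_motifs: target must be a subset of universe")
  if (is.null(motif_ids)) motif_ids <- sort(unique(hits$motif_id))
  N <- length(universe); n <- length(target)
  rows <- lapply(motif_ids, function(mid) {
    with_hit <- unique(hits$seq_name[hits$motif_id == mid])
    with_hit <- intersect(with_hit, universe)
    K <- length(with_hit)
    k <- length(intersect(with_hit, target))
    p_enr <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_dep <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
    enriched <- k / max(n, 1) >= K / max(N, 1)
    p <- if (enriched) p_enr else p_dep
    signed <- (if (enriched) 1 else -1) * -log10(max(p, 1e-300))
    data.frame(motif_id = mid, n_target = n, k_target = k, n_universe = N,
               k_universe = K, p_value = p, signed_score = signed,
               enriched = enriched, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Motif-by-sample module map
#'
#' Signed -log10 enrichment p of each motif in each sample-specific peak
#' set against the common universe (the analogue of a module-map matrix:
#' red = enriched, blue = depleted). Rows are ordered by hierarchical
#' clustering of the matrix.
#'
#' @param sets named list of peak-name vectors (one per sample).
#' @param hits hits over the universe from [scan_sequences()].
#' @param universe character vector of universe peak names.
#' @param motif_ids motifs to include (default all in `hits`).
#' @return Numeric matrix motif x sample of signed scores, with attribute
#'   `"empty_sets"` naming any empty input set (its column is zero).
#' @export
module_map <- function(sets, hits, universe, motif_ids = NULL) {
  if (is.null(motif_ids)) motif_ids <- sort(unique(hits$motif_id))
  empty <- names(sets)[lengths(sets) == 0]
  cols <- lapply(sets, function(s) {
    if (!length(s)) return(stats::setNames(rep(0, length(motif_ids)), motif_ids))
    e <- enrich_motifs(s, universe, hits, motif_ids)
    stats::setNames(e$signed_score, e$motif_id)
  })
  m <- do.call(cbind, cols)
  rownames(m) <- motif_ids
  if (nrow(m) > 2) {
    ord <- stats::hclust(stats::dist(m), method = "average")$order
    m <- m[ord, , drop = FALSE]
  }
  attr(m, "empty_sets") <- empty
  m
}

#' TF expression x enrichment bubble table
#'
#' Joins per-motif enrichment significance with the expression of the gene
#' encoding each TF, per timepoint (the data behind expression/size bubble
#' charts of candidate regulators).
#'
#' @param enrichment data.frame from [enrich_motifs()].
#' @param expression an `expr_matrix`.
#' @param mapping data.frame with columns `motif_id`, `gene` mapping motifs
#'   to expression gene ids.
#' @return data.frame with one row per (TF, timepoint): `motif_id`, `gene`,
#'   `day`, `expression`, `neg_log10_p`. TFs lacking an expression row are
#'   dropped with a warning.
#' @export
tf_bubble_table <- function(enrichment, expression, mapping) {
  mapping <- mapping[mapping$motif_id %in% enrichment$motif_id, , drop = FALSE]
  missing <- setdiff(mapping$gene, rownames(expression$values))
  if (length(missing)) {
    warning("tf_bubble_table: no expression for ", paste(missing, collapse = ", "),
            "; omitted")
    mapping <- mapping[!mapping$gene %in% missing, , drop = FALSE]
  }
  if (!nrow(mapping)) stop("tf_bubble_table: empty join between motifs and expression")
  rows <- lapply(seq_len(nrow(mapping)), function(i) {
    mid <- mapping$motif_id[i]; g <- mapping$gene[i]
    p <- enrichment$p_value[enrichment$motif_id == mid][1]
    data.frame(motif_id = mid, gene = g, day = expression$timepoints,
               expression = as.numeric(expression$values[g, ]),
               neg_log10_p = -log10(max(p, 1e-300)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
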
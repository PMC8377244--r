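#' Promoter regions upstream of TSS
#'
#' The promoter of a gene is the `upstream` bases 5' of its transcription
#' start site: for a + strand TSS at x the interval `[x - upstream, x)`,
#' for a - strand TSS at x the interval `[x, x + upstream)`, clipped to the
#' chromosome.
#'
#' @param tss a [peak_set()] of single-base TSS entries with strand; the
#'   `name` column is the gene id.
#' @param upstream promoter length in bp (default 2000).
#' @param chrom_lengths named integer vector for clipping at chromosome
#'   ends (optional; clipping at 0 always applies).
#' @return A [peak_set()] of promoters (name = gene) with a logical
#'   `clipped` column.
#' @export
promoter_regions <- function(tss, upstream = 2000, chrom_lengths = NULL) {
  if (any(tss$strand == ".")) stop("promoter_regions: TSS entries must have strand")
  pos <- tss$start
  p_start <- ifelse(tss$strand == "+", pos - upstream, pos)
  p_end <- ifelse(tss$strand == "+", pos, pos + upstream)
  clipped <- p_start < 0
  p_start <- pmax(p_start, 0L)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[tss$chrom]
    clipped <- clipped | p_end > lim
    p_end <- pmin(p_end, lim)
  }
  out <- peak_set(tss$chrom, p_start, p_end, tss$name, tss$strand)
  out$clipped <- clipped[match(out$name, tss$name)]
  out
}

#' Candidate regulator TFs
#'
#' TFs whose motif is enriched (p below `p`) in the early- or late-cluster
#' peak set and whose gene is expressed above the expressed-threshold at at
#' least one timepoint.
#'
#' @param enrichments list of [enrich_motifs()] results (e.g. for cluster I
#'   and cluster II peak sets).
#' @param expression an `expr_matrix`.
#' @param mapping data.frame with columns `motif_id`, `gene`.
#' @param p enrichment p threshold (default 0.05).
#' @param expressed_threshold absolute log-expression cutoff; default is
#'   the 50th percentile of all gene-timepoint values.
#' @return data.frame of candidates: `motif_id`, `gene`, `min_p`.
#' @export
candidate_tfs <- function(enrichments, expression, mapping, p = 0.05,
                          expressed_threshold = NULL) {
  if (is.data.frame(enrichments)) enrichments <- list(enrichments)
  if (is.null(expressed_threshold)) {
    expressed_threshold <- stats::median(expression$values)
  }
  min_p <- Reduce(pmin, lapply(enrichments, function(e) {
    ifelse(e$enriched, e$p_value, 1)[match(mapping$motif_id, e$motif_id)]
  }))
  min_p[is.na(min_p)] <- 1
  expressed <- vapply(mapping$gene, function(g) {
    g %in% rownames(expression$values) &&
      any(expression$values[g, ] >= expressed_threshold)
  }, TRUE)
  keep <- min_p < p & expressed
  out <- data.frame(motif_id = mapping$motif_id[keep], gene = mapping$gene[keep],
                    min_p = min_p[keep], stringsAsFactors = FALSE)
  attr(out, "expressed_threshold") <- expressed_threshold
  out
}

#' Timepoint-specific TFs
#'
#' Applies the stage fold-change criterion to TF expression rows with each
#' timepoint as its own group on the linear scale: a TF is specific to day
#' t when `2^x_t` exceeds `fc` times the maximum over all other days.
#'
#' @param expression an `expr_matrix` (log2-scale values).
#' @param genes TF gene ids to consider (default: flagged TFs).
#' @param fc fold-change threshold (default 1.5).
#' @return Named list (one per day, `"d<day>"`) of gene id vectors.
#' @export
stage_specific_tfs <- function(expression, genes = NULL, fc = 1.5) {
  if (is.null(genes)) genes <- names(expression$tf)[expression$tf]
  genes <- intersect(genes, rownames(expression$values))
  lin <- 2^expression$values[genes, , drop = FALSE]
  sets <- stage_specific_elements(lin, groups = colnames(lin), fc = fc)
  sets[sprintf("d%d", expression$timepoints)]
}

#' Infer directed regulatory edges from promoter motif hits
#'
#' Edge A -> B exists when at least one hit of A's motif lies in B's
#' promoter sequence, for A and B both candidate TFs. Self-loops (a TF's
#' motif in its own promoter) are kept and flagged.
#'
#' @param candidates data.frame from [candidate_tfs()] (`motif_id`, `gene`).
#' @param promoter_hits data.frame from [scan_sequences()] over promoter
#'   sequences named by gene (`seq_name` = target gene, `motif_id`).
#' @return data.frame of edges: `source`, `target` (gene ids),
#'   `source_motif`, `n_hits`, `self_loop`.
#' @export
infer_edges <- function(candidates, promoter_hits) {
  no_motif <- candidates$gene[is.na(candidates$motif_id)]
  if (length(no_motif)) {
    warning("infer_edges: no motif for ", paste(no_motif, collapse = ", "),
            "; no outgoing edges")
  }
  h <- promoter_hits[promoter_hits$motif_id %in% candidates$motif_id &
                     promoter_hits$seq_name %in% candidates$gene, , drop = FALSE]
  if (!nrow(h)) {
    return(data.frame(source = character(), target = character(),
                      source_motif = character(), n_hits = integer(),
                      self_loop = logical(), stringsAsFactors = FALSE))
  }
  key <- paste(h$motif_id, h$seq_name)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, " ", fixed = TRUE)
  motif <- vapply(parts, `[[`, "", 1L)
  target <- vapply(parts, `[[`, "", 2L)
  source <- candidates$gene[match(motif, candidates$motif_id)]
  out <- data.frame(source = source, target = target, source_motif = motif,
                    n_hits = agg$Freq, self_loop = source == target,
                    stringsAsFactors = FALSE)
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Type edges by expression correlation
#'
#' Pearson correlation of the two endpoint expression time courses:
#' positive when PCC > `threshold`, negative when PCC < `-threshold`, none
#' otherwise (the closed interval maps to none). Zero-variance profiles
#' give an undefined PCC, typed none and flagged.
#'
#' @param edges data.frame from [infer_edges()].
#' @param expression an `expr_matrix` covering both endpoints of each edge.
#' @param threshold PCC cutoff (default 0.4).
#' @return `edges` with added columns `pcc`, `edge_type`, `pcc_undefined`.
#' @export
classify_edges <- function(edges, expression, threshold = 0.4) {
  v <- expression$values
  pcc <- vapply(seq_len(nrow(edges)), function(i) {
    a <- v[edges$source[i], ]; b <- v[edges$target[i], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
  edge_type <- ifelse(is.na(pcc), "none",
                      ifelse(pcc > threshold, "positive",
                             ifelse(pcc < -threshold, "negative", "none")))
  edges$pcc <- pcc
  edges$edge_type <- edge_type
  edges$pcc_undefined <- is.na(pcc)
  edges
}

#' Assemble the regulatory network of one timepoint
#'
#' Nodes are the TFs specifically expressed at the timepoint (strict mode,
#' default) or additionally any candidate expressed above threshold at that
#' timepoint; edges are restricted to retained nodes. Node attributes carry
#' the expression at the timepoint and the enrichment significance.
#'
#' @param timepoint integer day.
#' @param candidates data.frame from [candidate_tfs()].
#' @param stage_tfs list from [stage_specific_tfs()].
#' @param edges typed edges from [classify_edges()].
#' @param expression an `expr_matrix`.
#' @param strict if `TRUE` (default) only timepoint-specific TFs are nodes.
#' @param expressed_threshold cutoff used in non-strict mode (default: the
#'   one recorded on `candidates`, else the median).
#' @return List of class `regulatory_network`: `timepoint`, `nodes`
#'   (data.frame `tf`, `expression`, `neg_log10_p`, `stage_specific`),
#'   `edges` (restricted, typed).
#' @export
build_timepoint_network <- function(timepoint, candidates, stage_tfs, edges,
                                    expression, strict = TRUE,
                                    expressed_threshold = NULL) {
  key <- sprintf("d%d", timepoint)
  specific <- intersect(stage_tfs[[key]], candidates$gene)
  nodes <- specific
  if (!strict) {
    if (is.null(expressed_threshold)) {
      expressed_threshold <- attr(candidates, "expressed_threshold")
      if (is.null(expressed_threshold)) expressed_threshold <- stats::median(expression$values)
    }
    expressed_now <- candidates$gene[
      expression$values[candidates$gene, key] >= expressed_threshold]
    nodes <- union(specific, expressed_now)
  }
  if (!length(nodes)) warning("build_timepoint_network: empty node set at day ", timepoint)
  keep <- edges$source %in% nodes & edges$target %in% nodes
  node_df <- data.frame(
    tf = nodes,
    expression = if (length(nodes)) as.numeric(expression$values[nodes, key]) else numeric(0),
    neg_log10_p = -log10(pmax(candidates$min_p[match(nodes, candidates$gene)], 1e-300)),
    stage_specific = nodes %in% specific,
    stringsAsFactors = FALSE
  )
  structure(list(timepoint = timepoint, nodes = node_df,
                 edges = edges[keep, , drop = FALSE]),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network at day %s: %d TFs, %d edges (%s)\n",
              x$timepoint, nrow(x$nodes), nrow(x$edges),
              paste(sprintf("%s=%d", names(table(x$edges$edge_type)),
                            as.integer(table(x$edges$edge_type))), collapse = ", ")))
  invisible(x)
}

#' Write a regulatory network to disk
#'
#' `edge_tsv` writes an edge list (`source`, `target`, `pcc`, `edge_type`)
#' plus a companion `<path>.nodes.tsv` node table (`tf`, `expression`,
#' `neg_log10_p`); `graphml` encodes the same attributes in GraphML via
#' igraph.
#'
#' @param network a `regulatory_network`.
#' @param path output path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  e <- network$edges[, c("source", "target", "pcc", "edge_type"), drop = FALSE]
  n <- network$nodes[, c("tf", "expression", "neg_log10_p"), drop = FALSE]
  if (format == "edge_tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(n, paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(d = e, directed = TRUE, vertices = n)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
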
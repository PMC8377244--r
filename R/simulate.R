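#' Simulation configuration
#'
#' Defaults emulate an 8-timepoint (days 7-35), 2-replicate in vitro NK
#' differentiation time course at desk scale: 640 differential peaks split
#' into a decreasing early cluster (I), an increasing late cluster (II)
#' whose logistic midpoint sits at the accessibility onset day, and a small
#' transiently accessible interim cluster (III), plus flat-high stable
#' peaks; negative-binomial counts (Var = mu + alpha mu^2); matched
#' log-scale expression with the late program lagging accessibility by
#' `expression_lag_days`; planted TF motifs, promoter-embedded regulatory
#' edges, per-timepoint insertion tracks with footprint protection, and an
#' NK-fraction phenotype rising after `phenotype_onset_day`.
#'
#' @param seed RNG seed driving every random draw.
#' @param timepoints day grid.
#' @param n_replicates ATAC replicates per timepoint.
#' @param n_diff_peaks,cluster_proportions differential peaks and their
#'   split over clusters I/II/III.
#' @param n_stable_peaks flat-high non-differential peaks; the default
#'   keeps differential peaks a minority so median-of-ratios normalization
#'   retains its majority-unchanged assumption.
#' @param nb_dispersion NB dispersion alpha.
#' @param baseline_mean count level of a closed diff peak (stable peaks sit
#'   at 4x this).
#' @param fold_range accessibility fold range (low, high) for diff peaks.
#' @param onset_day_accessibility cluster II logistic midpoint (day).
#' @param expression_lag_days lag of the late expression program (days).
#' @param phenotype_onset_day day after which the NK fraction rises.
#' @param n_tfs total TF genes (including `n_decoy_tfs` inactive ones).
#' @param n_decoy_tfs TFs with no embedded motif and low flat expression.
#' @param n_decoy_motifs extra motifs placed nowhere (enrichment true
#'   negatives).
#' @param n_planted_edges promoter-embedded regulatory edges.
#' @param motif_length_range motif length range (bp).
#' @param footprint_protection rho: fractional insertion depletion in bound
#'   motif cores.
#' @param promoter_length promoter size upstream of TSS (bp).
#' @param peak_width,peak_gap peak geometry on the synthetic chromosome;
#'   peaks are wide enough that a +/-100 bp footprint window around any
#'   embedded motif stays inside the accessible region.
#' @param embed_fraction fraction of a cluster's peaks carrying each
#'   associated TF's motif.
#' @param size_factor_range per-sample depth factors, drawn log-uniform.
#' @param expression_noise_sd Gaussian noise sd on log2 expression.
#' @param insertion_rate insertions/bp at full accessibility inside peaks.
#' @param background_insertion_rate insertions/bp outside peaks.
#' @param n_linked_genes genes tied to clusters I and II (length-2 vector).
#' @param n_noise_genes unstructured genes.
#' @param accessibility_tau cluster II logistic time scale (days).
#' @param early_midpoint,early_tau cluster I decline midpoint/scale (days);
#'   the decline midpoint sits in the gap between the early and interim
#'   stages so stage transitions fall between sampled days.
#' @param transient_on,transient_off,transient_tau cluster III transient
#'   plateau: product of a rise at `transient_on` and a fall at
#'   `transient_off` (days), covering the interim stage.
#' @param expression_base,expression_amplitude log2 expression baseline and
#'   dynamic range of linked genes.
#' @param tf_base,tf_stage_amplitude,tf_bump_amplitude,decoy_tf_level TF
#'   expression shape parameters (log2 scale).
#' @param tf_bump_sd width (days) of the TF day-specific expression bump.
#' @param phenotype_offset,phenotype_scale NK-fraction logistic midpoint
#'   offset from `phenotype_onset_day` and time scale (chosen so the
#'   fraction is ~5% at the onset day).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       timepoints = c(7, 14, 19, 21, 24, 26, 28, 35),
                       n_replicates = 2,
                       n_diff_peaks = 640,
                       cluster_proportions = c(0.247, 0.697, 0.056),
                       n_stable_peaks = 960,
                       nb_dispersion = 0.05,
                       baseline_mean = 200,
                       fold_range = c(8, 64),
                       onset_day_accessibility = 14,
                       expression_lag_days = 2,
                       phenotype_onset_day = 21,
                       n_tfs = 30,
                       n_decoy_tfs = 6,
                       n_decoy_motifs = 10,
                       n_planted_edges = 40,
                       motif_length_range = c(8, 12),
                       footprint_protection = 0.4,
                       promoter_length = 2000,
                       peak_width = 500,
                       peak_gap = 200,
                       embed_fraction = 0.5,
                       size_factor_range = c(0.7, 1.4),
                       expression_noise_sd = 0.2,
                       insertion_rate = 0.5,
                       background_insertion_rate = 0.005,
                       n_linked_genes = c(60, 120),
                       n_noise_genes = 100,
                       accessibility_tau = 1.5,
                       early_midpoint = 22.5,
                       early_tau = 1.5,
                       transient_on = 22.5,
                       transient_off = 31.5,
                       transient_tau = 1,
                       expression_base = 6,
                       expression_amplitude = 3,
                       tf_base = 6,
                       tf_stage_amplitude = 1.2,
                       tf_bump_amplitude = 1.8,
                       tf_bump_sd = 1.5,
                       decoy_tf_level = 4,
                       phenotype_offset = 6.5,
                       phenotype_scale = 2.2) {
  cfg <- as.list(environment())
  if (abs(sum(cluster_proportions) - 1) > 1e-9) {
    stop("sim_config: cluster_proportions must sum to 1")
  }
  if (n_replicates < 2) stop("sim_config: need >= 2 replicates")
  if (baseline_mean <= 0 || nb_dispersion < 0) {
    stop("sim_config: counts/means must be positive")
  }
  rng <- range(timepoints)
  if (onset_day_accessibility < rng[1] || onset_day_accessibility > rng[2] ||
      phenotype_onset_day < rng[1] || phenotype_onset_day > rng[2]) {
    stop("sim_config: onset days must lie inside the timepoint range")
  }
  if (max(motif_length_range) + 220 >= peak_width) {
    stop("sim_config: motifs too long for the peak width")
  }
  class(cfg) <- "sim_config"
  cfg
}

rise_logistic <- function(t, mid, tau) stats::plogis((t - mid) / tau)

cluster_shape <- function(cfg, label, t) {
  switch(label,
    I = 1 - rise_logistic(t, cfg$early_midpoint, cfg$early_tau),
    II = rise_logistic(t, cfg$onset_day_accessibility, cfg$accessibility_tau),
    III = rise_logistic(t, cfg$transient_on, cfg$transient_tau) *
      (1 - rise_logistic(t, cfg$transient_off, cfg$transient_tau)),
    stable = rep(1, length(t))
  )
}

tf_activity <- function(cfg, stage, t) {
  switch(stage,
    early = 1 - rise_logistic(t, cfg$early_midpoint, cfg$early_tau),
    late = rise_logistic(t, cfg$onset_day_accessibility, cfg$accessibility_tau),
    decoy = rep(0, length(t))
  )
}

random_pwm <- function(id, name, len) {
  ## sharply peaked columns keep the fractional score threshold
  ## consensus-equivalent across motif lengths
  consensus <- sample(DNA_BASES, len, replace = TRUE)
  prob <- matrix(0.01, 4, len, dimnames = list(DNA_BASES, NULL))
  prob[cbind(match(consensus, DNA_BASES), seq_len(len))] <- 0.97
  list(id = id, name = name, prob = prob,
       counts = round(prob * 100), consensus = paste(consensus, collapse = ""))
}

#' Generate a synthetic differentiation dataset
#'
#' Builds the full fixture a real analysis would start from: a synthetic
#' genome with peak and promoter chromosomes, peak-by-sample NB counts with
#' planted temporal clusters, TF motifs embedded in cluster-specific peaks
#' and in the promoters of planted regulatory targets, a matched expression
#' matrix whose late program lags accessibility, per-timepoint insertion
#' tracks with footprint protection at bound motifs, and the NK-fraction
#' phenotype trajectory. All randomness derives from `config$seed`; the
#' planted ground truth is returned alongside the data.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_dataset` with elements `config`, `genome`,
#'   `peaks`, `counts`, `tss`, `promoters`, `motifs`, `mapping`,
#'   `expression`, `tracks`, `phenotype`, `truth`.
#' @export
generate_dataset <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  tp <- cfg$timepoints
  n_tp <- length(tp)

  ## ---- peaks and cluster labels -------------------------------------
  n_cl <- round(cfg$n_diff_peaks * cfg$cluster_proportions)
  if (sum(n_cl) != cfg$n_diff_peaks) {
    n_cl[which.max(n_cl)] <- n_cl[which.max(n_cl)] + cfg$n_diff_peaks - sum(n_cl)
  }
  labels <- sample(rep(c("I", "II", "III", "stable"),
                       c(n_cl, cfg$n_stable_peaks)))
  n_peaks <- length(labels)
  w <- cfg$peak_width; gap <- cfg$peak_gap
  starts <- gap + (seq_len(n_peaks) - 1L) * (w + gap)
  peaks <- peak_set("chr1", starts, starts + w,
                    sprintf("peak_%04d", seq_len(n_peaks)),
                    strand = ".", summit_offset = w %/% 2L)
  names(labels) <- peaks$name

  ## ---- per-peak mean trajectories -----------------------------------
  folds <- 2^stats::runif(n_peaks, log2(cfg$fold_range[1]), log2(cfg$fold_range[2]))
  base <- cfg$baseline_mean * exp(stats::rnorm(n_peaks, 0, 0.25))
  base[labels == "stable"] <- 4 * cfg$baseline_mean *
    exp(stats::rnorm(sum(labels == "stable"), 0, 0.25))
  shape <- matrix(0, n_peaks, n_tp, dimnames = list(peaks$name, sprintf("d%d", tp)))
  for (lab in c("I", "II", "III", "stable")) {
    idx <- labels == lab
    shape[idx, ] <- matrix(cluster_shape(cfg, lab, tp), sum(idx), n_tp, byrow = TRUE)
  }
  mu <- base * (1 + (folds - 1) * shape)
  mu[labels == "stable", ] <- base[labels == "stable"]

  ## ---- counts --------------------------------------------------------
  days_vec <- rep(tp, each = cfg$n_replicates)
  sample_names <- sprintf("d%d_R%d", days_vec, rep(seq_len(cfg$n_replicates), n_tp))
  sf <- exp(stats::runif(length(sample_names),
                         log(cfg$size_factor_range[1]), log(cfg$size_factor_range[2])))
  counts <- matrix(0L, n_peaks, length(sample_names),
                   dimnames = list(peaks$name, sample_names))
  size_param <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
  for (s in seq_along(sample_names)) {
    m_s <- sf[s] * mu[, sprintf("d%d", days_vec[s])]
    counts[, s] <- as.integer(if (is.finite(size_param)) {
      stats::rnbinom(n_peaks, mu = m_s, size = size_param)
    } else stats::rpois(n_peaks, m_s))
  }
  cm <- count_matrix(counts, data.frame(sample = sample_names, day = days_vec,
                                        replicate = sprintf("R%d", rep(seq_len(cfg$n_replicates), n_tp)),
                                        stringsAsFactors = FALSE))

  ## ---- TFs, motifs ---------------------------------------------------
  n_active <- cfg$n_tfs - cfg$n_decoy_tfs
  tf_genes <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  tf_stage <- c(rep(c("early", "late"), each = n_active %/% 2),
                rep("decoy", cfg$n_tfs - 2 * (n_active %/% 2)))
  half <- n_tp %/% 2
  peak_day <- rep(NA_integer_, cfg$n_tfs)
  peak_day[tf_stage == "early"] <- rep(tp[seq_len(half)], length.out = sum(tf_stage == "early"))
  peak_day[tf_stage == "late"] <- rep(tp[(half + 1):n_tp], length.out = sum(tf_stage == "late"))
  lens <- sample(seq(cfg$motif_length_range[1], cfg$motif_length_range[2]),
                 cfg$n_tfs + cfg$n_decoy_motifs, replace = TRUE)
  motifs <- vector("list", cfg$n_tfs + cfg$n_decoy_motifs)
  for (i in seq_len(cfg$n_tfs)) {
    motifs[[i]] <- random_pwm(sprintf("M%03d", i), tf_genes[i], lens[i])
  }
  for (i in seq_len(cfg$n_decoy_motifs)) {
    motifs[[cfg$n_tfs + i]] <- random_pwm(sprintf("M%03d", cfg$n_tfs + i),
                                          sprintf("DEC%02d", i), lens[cfg$n_tfs + i])
  }
  ms <- motif_set(motifs)
  mapping <- data.frame(motif_id = sprintf("M%03d", seq_len(cfg$n_tfs)),
                        gene = tf_genes, stringsAsFactors = FALSE)

  ## ---- embed motifs in cluster peaks (non-overlapping 20-bp slots) ---
  ## motif slots sit >= 100 bp from the peak edges so footprint windows
  ## around embedded sites remain inside the peak
  slot_w <- 20L
  edge <- 100L
  n_slots <- (w - 2L * edge - 20L) %/% slot_w
  peak_slots <- lapply(seq_len(n_peaks), function(i) sample(seq_len(n_slots)) - 1L)
  slot_used <- integer(n_peaks)
  genome_chr1 <- sample(DNA_BASES, utils::tail(starts, 1) + w + gap, replace = TRUE)
  planted_peak_hits <- list()
  for (i in which(tf_stage != "decoy")) {
    target_label <- if (tf_stage[i] == "early") "I" else "II"
    eligible <- which(labels == target_label)
    chosen <- sample(eligible, ceiling(cfg$embed_fraction * length(eligible)))
    cons <- ms[[mapping$motif_id[i]]]$consensus
    L <- nchar(cons)
    rows <- vector("list", length(chosen))
    for (k in seq_along(chosen)) {
      p <- chosen[k]
      if (slot_used[p] >= n_slots) next  # peak full; skip this site
      slot_used[p] <- slot_used[p] + 1L
      off <- edge + peak_slots[[p]][slot_used[p]] * slot_w
      g_start <- peaks$start[p] + off
      strand <- sample(c("+", "-"), 1)
      insert <- if (strand == "+") cons else revcomp(cons)
      genome_chr1[(g_start + 1L):(g_start + L)] <- strsplit(insert, "")[[1]]
      rows[[k]] <- data.frame(chrom = "chr1", start = g_start, end = g_start + L,
                              motif_id = mapping$motif_id[i], strand = strand,
                              peak = peaks$name[p], stringsAsFactors = FALSE)
    }
    planted_peak_hits[[mapping$motif_id[i]]] <- do.call(rbind, rows)
  }
  planted_peak_hits <- do.call(rbind, c(planted_peak_hits, list(make.row.names = FALSE)))

  ## ---- TF gene loci and planted regulatory edges ---------------------
  pl <- cfg$promoter_length
  tss_pos <- pl + (seq_len(cfg$n_tfs) - 1L) * (pl + 1000L)
  tss <- peak_set("chr2", tss_pos, tss_pos + 1L, tf_genes, strand = "+")
  genome_chr2 <- sample(DNA_BASES, utils::tail(tss_pos, 1) + 1000L, replace = TRUE)
  active_idx <- which(tf_stage != "decoy")
  within_day <- list()
  for (d in unique(peak_day[active_idx])) {
    grp <- active_idx[!is.na(peak_day[active_idx]) & peak_day[active_idx] == d]
    if (length(grp) >= 2) within_day[[as.character(d)]] <- c(grp[1], grp[2])
  }
  edges <- do.call(rbind, lapply(within_day, function(p) data.frame(s = p[1], t = p[2])))
  if (is.null(edges)) edges <- data.frame(s = integer(), t = integer())
  all_pairs <- expand.grid(s = active_idx, t = active_idx)
  all_pairs <- all_pairs[all_pairs$s != all_pairs$t, ]
  key <- function(df) paste(df$s, df$t)
  pool <- all_pairs[!key(all_pairs) %in% key(edges), ]
  extra_n <- cfg$n_planted_edges - nrow(edges)
  if (extra_n > 0) edges <- rbind(edges, pool[sample(nrow(pool), extra_n), ])
  edges <- edges[seq_len(min(nrow(edges), cfg$n_planted_edges)), ]
  planted_edges <- data.frame(
    source = tf_genes[edges$s], target = tf_genes[edges$t],
    sign = ifelse(tf_stage[edges$s] == tf_stage[edges$t], "positive", "negative"),
    stringsAsFactors = FALSE)
  prom_slots <- lapply(seq_len(cfg$n_tfs), function(i) sample(seq_len((pl - 20L) %/% slot_w)) - 1L)
  prom_used <- integer(cfg$n_tfs)
  planted_prom_hits <- vector("list", nrow(edges))
  for (k in seq_len(nrow(edges))) {
    src <- edges$s[k]; tgt <- edges$t[k]
    cons <- ms[[mapping$motif_id[src]]]$consensus
    L <- nchar(cons)
    prom_used[tgt] <- prom_used[tgt] + 1L
    off <- 10L + prom_slots[[tgt]][prom_used[tgt]] * slot_w
    g_start <- (tss_pos[tgt] - pl) + off
    strand <- sample(c("+", "-"), 1)
    insert <- if (strand == "+") cons else revcomp(cons)
    genome_chr2[(g_start + 1L):(g_start + L)] <- strsplit(insert, "")[[1]]
    planted_prom_hits[[k]] <- data.frame(
      chrom = "chr2", start = g_start, end = g_start + L,
      motif_id = mapping$motif_id[src], strand = strand,
      gene = tf_genes[tgt], stringsAsFactors = FALSE)
  }
  planted_prom_hits <- do.call(rbind, planted_prom_hits)
  genome <- c(chr1 = paste(genome_chr1, collapse = ""),
              chr2 = paste(genome_chr2, collapse = ""))

  ## ---- expression ----------------------------------------------------
  lag_mid <- cfg$onset_day_accessibility + cfg$expression_lag_days
  noise <- function(n) stats::rnorm(n, 0, cfg$expression_noise_sd)
  expr_rows <- list()
  for (i in seq_len(cfg$n_tfs)) {
    prof <- if (tf_stage[i] == "decoy") {
      rep(cfg$decoy_tf_level, n_tp)
    } else {
      act <- if (tf_stage[i] == "early") tf_activity(cfg, "early", tp)
             else rise_logistic(tp, lag_mid, cfg$accessibility_tau)
      cfg$tf_base + cfg$tf_stage_amplitude * act +
        cfg$tf_bump_amplitude * exp(-(tp - peak_day[i])^2 / (2 * cfg$tf_bump_sd^2))
    }
    expr_rows[[tf_genes[i]]] <- prof + noise(n_tp)
  }
  for (j in seq_len(cfg$n_linked_genes[1])) {
    expr_rows[[sprintf("geneI_%03d", j)]] <- cfg$expression_base +
      cfg$expression_amplitude * (1 - rise_logistic(tp, cfg$early_midpoint, cfg$early_tau)) +
      noise(n_tp)
  }
  for (j in seq_len(cfg$n_linked_genes[2])) {
    expr_rows[[sprintf("geneII_%03d", j)]] <- cfg$expression_base +
      cfg$expression_amplitude * rise_logistic(tp, lag_mid, cfg$accessibility_tau) +
      noise(n_tp)
  }
  for (j in seq_len(cfg$n_noise_genes)) {
    expr_rows[[sprintf("noise_%03d", j)]] <- cfg$expression_base +
      stats::runif(1, -1, 1) + noise(n_tp)
  }
  expr <- expr_matrix(do.call(rbind, expr_rows), tp, tf_flags = tf_genes)

  ## ---- insertion tracks ---------------------------------------------
  rel_access <- (1 + (folds - 1) * shape) / (1 + (folds - 1) * apply(shape, 1, max))
  rel_access[labels == "stable", ] <- 1
  chrom_lengths <- c(chr1 = nchar(genome[["chr1"]]), chr2 = nchar(genome[["chr2"]]))
  tf_act_mat <- t(vapply(seq_len(cfg$n_tfs), function(i) {
    tf_activity(cfg, tf_stage[i], tp)
  }, numeric(n_tp)))
  rownames(tf_act_mat) <- mapping$motif_id
  tracks <- vector("list", n_tp)
  names(tracks) <- sprintf("d%d", tp)
  for (ti in seq_len(n_tp)) {
    rate1 <- rep(cfg$background_insertion_rate, chrom_lengths[["chr1"]])
    for (p in seq_len(n_peaks)) {
      rate1[(peaks$start[p] + 1L):peaks$end[p]] <- cfg$insertion_rate * rel_access[p, ti]
    }
    if (nrow(planted_peak_hits)) {
      for (k in seq_len(nrow(planted_peak_hits))) {
        act <- tf_act_mat[planted_peak_hits$motif_id[k], ti]
        idx <- (planted_peak_hits$start[k] + 1L):planted_peak_hits$end[k]
        rate1[idx] <- rate1[idx] * (1 - cfg$footprint_protection * act)
      }
    }
    rate2 <- rep(0.3, chrom_lengths[["chr2"]])
    for (k in seq_len(nrow(planted_prom_hits))) {
      act <- tf_act_mat[planted_prom_hits$motif_id[k], ti]
      idx <- (planted_prom_hits$start[k] + 1L):planted_prom_hits$end[k]
      rate2[idx] <- rate2[idx] * (1 - cfg$footprint_protection * act)
    }
    tracks[[ti]] <- insertion_track(
      list(chr1 = stats::rpois(length(rate1), rate1),
           chr2 = stats::rpois(length(rate2), rate2)),
      label = sprintf("d%d", tp[ti]))
  }

  ## ---- phenotype and truth -------------------------------------------
  phenotype <- stats::setNames(
    rise_logistic(tp, cfg$phenotype_onset_day + cfg$phenotype_offset, cfg$phenotype_scale),
    sprintf("d%d", tp))
  stage_map <- ifelse(tp <= 21, "early", ifelse(tp <= 28, "interim", "late"))
  names(stage_map) <- sprintf("d%d", tp)
  truth <- list(
    cluster_labels = labels,
    folds = stats::setNames(folds, peaks$name),
    size_factors = stats::setNames(sf, sample_names),
    onset_accessibility = cfg$onset_day_accessibility,
    onset_expression = lag_mid,
    expression_lag_days = cfg$expression_lag_days,
    phenotype_onset_day = cfg$phenotype_onset_day,
    stage_map = stage_map,
    tf_table = data.frame(gene = tf_genes, motif_id = mapping$motif_id,
                          stage = tf_stage, peak_day = peak_day,
                          active = tf_stage != "decoy", stringsAsFactors = FALSE),
    edges = planted_edges,
    planted_peak_hits = planted_peak_hits,
    planted_promoter_hits = planted_prom_hits
  )
  structure(list(config = cfg, genome = genome, peaks = peaks, counts = cm,
                 tss = tss,
                 promoters = promoter_regions(tss, pl, chrom_lengths),
                 motifs = ms, mapping = mapping, expression = expr,
                 tracks = tracks, phenotype = phenotype, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0("sim_dataset (seed %d): %d peaks x %d samples, %d motifs, ",
                     "%d genes, %d planted edges\n"),
              x$config$seed, nrow(x$peaks), ncol(x$counts$counts),
              length(x$motifs), nrow(x$expression$values), nrow(x$truth$edges)))
  invisible(x)
}

#' Export a synthetic dataset to a fixture directory
#'
#' Writes every external format the pipeline reads: peaks and TSS BED,
#' genome FASTA, counts and expression TSV, motifs in JASPAR PFM text,
#' per-timepoint bedGraph insertion tracks, the phenotype TSV, the
#' TF-to-motif mapping TSV, and `truth.json` with the planted parameters.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
export_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  paths <- c(
    peaks = file.path(dir, "peaks.bed"),
    tss = file.path(dir, "tss.bed"),
    genome = file.path(dir, "genome.fa"),
    counts = file.path(dir, "counts.tsv"),
    expression = file.path(dir, "expression.tsv"),
    motifs = file.path(dir, "motifs.jaspar"),
    mapping = file.path(dir, "tf_mapping.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_bed(dataset$peaks, paths["peaks"])
  write_bed(dataset$tss, paths["tss"])
  write_genome(dataset$genome, paths["genome"])
  write_matrix(dataset$counts, paths["counts"])
  write_matrix(dataset$expression, paths["expression"])
  write_jaspar(dataset$motifs, paths["motifs"])
  utils::write.table(dataset$mapping, paths["mapping"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(day = names(dataset$phenotype), nk_fraction = dataset$phenotype),
    paths["phenotype"], sep = "\t", quote = FALSE, row.names = FALSE)
  for (tp in names(dataset$tracks)) {
    p <- file.path(dir, "tracks", sprintf("%s.bedGraph", tp))
    write_bedgraph(dataset$tracks[[tp]], p)
    paths[paste0("track_", tp)] <- p
  }
  truth <- dataset$truth
  truth$cluster_labels <- as.list(truth$cluster_labels)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}
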
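#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline with the defaults of
#' the analysis it implements: pairwise significance p < 0.01, |log2 FC| >
#' 5 and FDR < 0.01, intrinsic z > 1, stage fold change > 1.5, candidate
#' enrichment p < 0.05, PCC edge threshold 0.4, PWM hit threshold 0.8 of
#' the maximum score, 2 kb promoters.
#'
#' @param seed RNG seed (drives the simulation stage).
#' @param sim a [sim_config()]; rebuilt from `seed` if `NULL`.
#' @param p,abs_log2_fc,fdr,z differential selection thresholds.
#' @param selection_mode `"union"` or `"intersection"` of pairwise and
#'   intrinsic criteria.
#' @param stage_fc stage-specificity fold change.
#' @param enrich_p candidate-TF enrichment threshold.
#' @param pcc edge-typing correlation threshold.
#' @param threshold_frac PWM scan threshold fraction.
#' @param promoter_length promoter size (bp).
#' @param k_range_peaks,k_range_samples candidate cluster numbers.
#' @param strict_networks strict (stage-specific-only) network nodes.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, sim = NULL, p = 0.01, abs_log2_fc = 5,
                       fdr = 0.01, z = 1, selection_mode = "union",
                       stage_fc = 1.5, enrich_p = 0.05, pcc = 0.4,
                       threshold_frac = 0.8, promoter_length = 2000,
                       k_range_peaks = 2:8, k_range_samples = 2:6,
                       strict_networks = TRUE) {
  stopifnot(p >= 0, p <= 1, fdr >= 0, fdr <= 1, enrich_p >= 0, enrich_p <= 1,
            stage_fc > 1, pcc >= 0, pcc < 1, threshold_frac > 0,
            threshold_frac <= 1, promoter_length > 0)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [run_config()] arguments; a `sim:` block maps to
#' [sim_config()] arguments.
#'
#' @param path YAML file.
#' @param seed overrides the seed in the file when non-`NULL`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  if (!is.null(seed)) y$seed <- seed
  if (!is.null(y$seed) && !is.null(sim_args)) sim_args$seed <- y$seed
  if (!is.null(sim_args)) y$sim <- do.call(sim_config, sim_args)
  do.call(run_config, y)
}

stage_file <- function(dir, ...) file.path(dir, ...)

#' Run the full pipeline
#'
#' Executes simulate, diffpeaks, cluster, motifs, footprint, network and
#' dynamics in dependency order under one output directory, each stage
#' reading the previous stage's files, and writes `manifest.json` recording
#' the seed, the configuration, and per-stage output files with row counts
#' and md5 checksums. Any stage failure aborts with an error naming the
#' stage. Reruns with the same config and seed produce byte-identical
#' outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfgj <- unclass(config)
  cfgj$sim <- unclass(cfgj$sim)
  manifest <- list(package = "atacdyn",
                   version = as.character(utils::packageVersion("atacdyn")),
                   seed = config$seed,
                   config = cfgj,
                   stages = list())
  record <- function(stage, files, info = list()) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- c(list(
      files = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))),
      info)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dirs <- stats::setNames(
    file.path(out_dir, sprintf("%02d_%s", 1:7,
                               c("simulate", "diffpeaks", "cluster", "motifs",
                                 "footprint", "network", "dynamics"))),
    c("simulate", "diffpeaks", "cluster", "motifs", "footprint", "network",
      "dynamics"))
  for (d in dirs) dir.create(d, showWarnings = FALSE, recursive = TRUE)

  ## ---- simulate ------------------------------------------------------
  env <- new.env(parent = emptyenv())
  run_stage("simulate", function() {
    ds <- generate_dataset(config$sim)
    export_dataset(ds, dirs[["simulate"]])
    env$ds <- ds
    record("simulate", list.files(dirs[["simulate"]], full.names = TRUE,
                                  recursive = TRUE),
           list(n_peaks = nrow(ds$peaks), n_samples = ncol(ds$counts$counts)))
  })

  ## ---- diffpeaks -----------------------------------------------------
  run_stage("diffpeaks", function() {
    counts <- read_matrix(stage_file(dirs[["simulate"]], "counts.tsv"), "counts")
    peaks <- read_bed(stage_file(dirs[["simulate"]], "peaks.bed"))
    sf <- estimate_size_factors(counts)
    norm <- normalize_counts(counts, sf)
    res <- all_pairwise_differential(counts, sf)
    intr <- intrinsic_scores(norm)
    sel <- select_differential_peaks(
      res, intr, thresholds = list(p = config$p, abs_log2_fc = config$abs_log2_fc,
                                   fdr = config$fdr, z = config$z),
      mode = config$selection_mode)
    d <- dirs[["diffpeaks"]]
    utils::write.table(data.frame(sample = names(sf), size_factor = sf),
                       stage_file(d, "size_factors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_matrix(norm, stage_file(d, "normalized_log2.tsv"))
    for (nm in names(res)) {
      utils::write.table(res[[nm]], stage_file(d, sprintf("pairwise_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(intr, stage_file(d, "intrinsic.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_bed(peaks[peaks$name %in% sel$selected, ],
              stage_file(d, "selected_peaks.bed"))
    env$norm <- norm; env$sf <- sf; env$sel <- sel; env$counts <- counts
    record("diffpeaks", list.files(d, full.names = TRUE),
           list(n_selected = length(sel$selected),
                counts_per_criterion = as.list(sel$counts)))
  })

  ## ---- cluster -------------------------------------------------------
  run_stage("cluster", function() {
    d <- dirs[["cluster"]]
    sel_names <- env$sel$selected
    m <- env$norm[sel_names, , drop = FALSE]
    pk <- hier_cluster(m, "rows", k_range = config$k_range_peaks)
    pca <- pca_samples(m)
    sm <- cluster_samples(pca$coords, k_range = config$k_range_samples)
    lin <- normalize_linear(env$counts, env$sf)
    stage_of_sample <- sprintf("S%d", sm$labels)
    specific <- stage_specific_elements(lin, stage_of_sample, fc = config$stage_fc)
    conserved <- conservative_elements(lin, stage_of_sample)
    utils::write.table(data.frame(peak = names(pk$labels), cluster = pk$labels),
                       stage_file(d, "peak_clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample = rownames(pca$coords),
                                  stage = stage_of_sample,
                                  round(pca$coords[, 1:2], 6)),
                       stage_file(d, "samples.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(peak = conserved),
                       stage_file(d, "conserved_peaks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    env$peak_clusters <- pk; env$sample_stages <- stage_of_sample
    env$specific <- specific; env$lin <- lin
    record("cluster", list.files(d, full.names = TRUE),
           list(k_peaks = pk$k, k_samples = sm$k))
  })

  ## ---- motifs --------------------------------------------------------
  run_stage("motifs", function() {
    d <- dirs[["motifs"]]
    genome <- read_genome(stage_file(dirs[["simulate"]], "genome.fa"))
    peaks <- read_bed(stage_file(dirs[["simulate"]], "peaks.bed"))
    motifs <- read_jaspar(stage_file(dirs[["simulate"]], "motifs.jaspar"))
    seqs <- interval_sequences(genome, peaks)
    hits <- scan_sequences(seqs, motifs, threshold_frac = config$threshold_frac)
    universe <- peaks$name
    labs <- env$peak_clusters$labels
    enr <- lapply(sort(unique(labs)), function(k) {
      enrich_motifs(names(labs)[labs == k], universe, hits,
                    motif_ids = names(motifs))
    })
    names(enr) <- sprintf("cluster_%d", sort(unique(labs)))
    sample_sets <- stage_specific_elements(env$lin, colnames(env$lin),
                                           fc = config$stage_fc)
    mm <- module_map(sample_sets, hits, universe, motif_ids = names(motifs))
    utils::write.table(
      data.frame(peak = hits$seq_name, motif_id = hits$motif_id,
                 start = hits$start, end = hits$end, strand = hits$strand,
                 score = round(hits$score, 4)),
      stage_file(d, "hits.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(enr)) {
      utils::write.table(enr[[nm]], stage_file(d, sprintf("enrichment_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_matrix(round(mm, 4), stage_file(d, "module_map.tsv"))
    mapping <- utils::read.delim(stage_file(dirs[["simulate"]], "tf_mapping.tsv"),
                                 stringsAsFactors = FALSE)
    expr <- read_matrix(stage_file(dirs[["simulate"]], "expression.tsv"),
                        "expression")
    bubble <- tf_bubble_table(enr[[which.max(vapply(enr, function(e)
      max(e$signed_score), 0))]], expr, mapping)
    utils::write.table(bubble, stage_file(d, "tf_bubble.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    env$hits <- hits; env$enr <- enr; env$motifs <- motifs
    env$genome <- genome; env$peaks <- peaks; env$expr <- expr
    env$mapping <- mapping
    record("motifs", list.files(d, full.names = TRUE),
           list(n_hits = nrow(hits)))
  })

  ## ---- footprint -----------------------------------------------------
  run_stage("footprint", function() {
    d <- dirs[["footprint"]]
    chrom_lengths <- vapply(env$genome, nchar, 0L)
    tracks <- lapply(names(env$ds$tracks), function(tp) {
      read_bedgraph(stage_file(dirs[["simulate"]], "tracks",
                               sprintf("%s.bedGraph", tp)),
                    chrom_lengths, label = tp)
    })
    names(tracks) <- names(env$ds$tracks)
    hit_counts <- table(env$hits$motif_id)
    use <- names(sort(hit_counts[hit_counts >= 30], decreasing = TRUE))
    use <- utils::head(use, 6)
    for (mid in use) {
      h <- env$hits[env$hits$motif_id == mid, , drop = FALSE]
      pk <- env$peaks[match(h$seq_name, env$peaks$name), ]
      gh <- data.frame(chrom = pk$chrom, start = pk$start + h$start,
                       end = pk$start + h$end, strand = h$strand,
                       stringsAsFactors = FALSE)
      tc <- footprint_timecourse(tracks, gh)
      utils::write.table(tc$depths, stage_file(d, sprintf("depths_%s.tsv", mid)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      prof <- sapply(tc$profiles, function(p) round(p$profile, 5))
      utils::write.table(data.frame(position = seq_len(nrow(prof)) - 1L, prof),
                         stage_file(d, sprintf("profile_%s.tsv", mid)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    env$tracks <- tracks
    record("footprint", list.files(d, full.names = TRUE),
           list(motifs_profiled = length(use)))
  })

  ## ---- network -------------------------------------------------------
  run_stage("network", function() {
    d <- dirs[["network"]]
    tss <- read_bed(stage_file(dirs[["simulate"]], "tss.bed"))
    chrom_lengths <- vapply(env$genome, nchar, 0L)
    promoters <- promoter_regions(tss, config$promoter_length, chrom_lengths)
    prom_seqs <- interval_sequences(env$genome, promoters)
    prom_hits <- scan_sequences(prom_seqs, env$motifs,
                                threshold_frac = config$threshold_frac)
    cands <- candidate_tfs(env$enr, env$expr, env$mapping, p = config$enrich_p)
    stfs <- stage_specific_tfs(env$expr, genes = env$mapping$gene,
                               fc = config$stage_fc)
    edges <- classify_edges(infer_edges(cands, prom_hits), env$expr,
                            threshold = config$pcc)
    utils::write.table(edges, stage_file(d, "edges_all.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    nets <- lapply(env$expr$timepoints, function(tpt) {
      net <- build_timepoint_network(tpt, cands, stfs, edges, env$expr,
                                     strict = config$strict_networks)
      write_network(net, stage_file(d, sprintf("network_d%d.tsv", tpt)), "edge_tsv")
      write_network(net, stage_file(d, sprintf("network_d%d.graphml", tpt)), "graphml")
      net
    })
    env$edges <- edges; env$cands <- cands
    record("network", list.files(d, full.names = TRUE),
           list(n_candidates = nrow(cands), n_edges = nrow(edges),
                nodes_per_timepoint = vapply(nets, function(n) nrow(n$nodes), 0L)))
  })

  ## ---- dynamics ------------------------------------------------------
  run_stage("dynamics", function() {
    d <- dirs[["dynamics"]]
    tp <- env$expr$timepoints
    labs <- env$peak_clusters$labels
    ## the opening (late) cluster: mean profile most correlated with time
    sample_days <- parse_sample_names(colnames(env$norm))$day
    prof_cor <- vapply(sort(unique(labs)), function(k) {
      stats::cor(colMeans(env$norm[names(labs)[labs == k], , drop = FALSE]),
                 sample_days)
    }, 0)
    late_cluster <- sort(unique(labs))[which.max(prof_cor)]
    acc <- mean_trajectory(env$norm, names(labs)[labs == late_cluster])
    acc_raw <- attr(acc, "raw")
    gene_cor <- apply(env$expr$values, 1, function(v) stats::cor(v, acc_raw))
    late_genes <- rownames(env$expr$values)[!is.na(gene_cor) & gene_cor >= 0.7]
    exprj <- mean_trajectory(env$expr$values, late_genes)
    pheno_tab <- utils::read.delim(stage_file(dirs[["simulate"]], "phenotype.tsv"),
                                   stringsAsFactors = FALSE)
    pheno <- stats::setNames(pheno_tab$nk_fraction,
                             sub("^d", "", pheno_tab$day))
    onsets <- list(accessibility = onset_changepoint(acc, tp),
                   expression = onset_changepoint(exprj, tp),
                   phenotype = onset_changepoint(pheno, tp))
    grid <- vapply(onsets, `[[`, 0, "onset_day")
    refined <- vapply(onsets, `[[`, 0, "onset_refined")
    lags <- onset_lags(refined)
    traj <- data.frame(day = tp, accessibility = round(as.numeric(acc), 5),
                       expression = round(as.numeric(exprj), 5),
                       phenotype = round(as.numeric(pheno), 5))
    utils::write.table(traj, stage_file(d, "trajectories.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(onset_day = as.list(grid),
                              onset_refined = as.list(refined),
                              lags = lags),
                         stage_file(d, "onsets.json"), auto_unbox = TRUE,
                         digits = 8, dataframe = "rows")
    record("dynamics", list.files(d, full.names = TRUE),
           list(onset_day = as.list(grid)))
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = 8,
                       pretty = TRUE)
  invisible(manifest)
}
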
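# Shared, lazily built synthetic datasets and derived analyses, cached per
# seed so many tests (and the acceptance checks) reuse one generation.

.cache <- new.env(parent = emptyenv())

get_sim <- function(seed = 42) {
  key <- sprintf("sim_%d", seed)
  if (is.null(.cache[[key]])) .cache[[key]] <- generate_dataset(sim_config(seed = seed))
  .cache[[key]]
}

get_diff <- function(seed = 42) {
  key <- sprintf("diff_%d", seed)
  if (is.null(.cache[[key]])) {
    ds <- get_sim(seed)
    sf <- estimate_size_factors(ds$counts)
    norm <- normalize_counts(ds$counts, sf)
    res <- all_pairwise_differential(ds$counts, sf)
    intr <- intrinsic_scores(norm)
    sel <- select_differential_peaks(res, intr)
    .cache[[key]] <- list(sf = sf, norm = norm, res = res, intr = intr, sel = sel)
  }
  .cache[[key]]
}

# PWM hits over all peak sequences of a dataset.
get_peak_hits <- function(seed = 42) {
  key <- sprintf("hits_%d", seed)
  if (is.null(.cache[[key]])) {
    ds <- get_sim(seed)
    seqs <- interval_sequences(ds$genome, ds$peaks)
    .cache[[key]] <- scan_sequences(seqs, ds$motifs)
  }
  .cache[[key]]
}

get_prom_hits <- function(seed = 42) {
  key <- sprintf("prom_%d", seed)
  if (is.null(.cache[[key]])) {
    ds <- get_sim(seed)
    seqs <- interval_sequences(ds$genome, ds$promoters)
    .cache[[key]] <- scan_sequences(seqs, ds$motifs)
  }
  .cache[[key]]
}

# Enrichment of the planted cluster peak sets against the peak universe.
get_cluster_enrichment <- function(seed = 42) {
  key <- sprintf("enr_%d", seed)
  if (is.null(.cache[[key]])) {
    ds <- get_sim(seed)
    hits <- get_peak_hits(seed)
    labs <- ds$truth$cluster_labels
    .cache[[key]] <- lapply(c(I = "I", II = "II"), function(cl) {
      enrich_motifs(names(labs)[labs == cl], ds$peaks$name, hits,
                    motif_ids = names(ds$motifs))
    })
  }
  .cache[[key]]
}
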
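# atacdyn

Temporal analysis of chromatin accessibility during cell
differentiation. The package was built around ATAC-seq time courses of
in vitro NK-cell differentiation (8 timepoints between day 7 and day 35,
two biological replicates each), where the questions are: which
regulatory DNA opens or closes, when; which transcription factors drive
each differentiation stage; how they regulate each other; and in what
order chromatin, transcription and cell phenotype change.

From peak-by-sample fragment counts, a genome, TF motifs, an expression
matrix and a phenotype trajectory, atacdyn provides:

* **Differential accessibility** across the timepoint categories:
  median-of-ratios size factors, a negative-binomial Wald test per peak
  and comparison (log2 FC of normalized group means, method-of-moments
  dispersion with Var = μ + αμ², two-sided normal p, BH FDR), plus an
  intrinsic-variance z-score that favours peaks varying between
  timepoints but not between replicates. Selection at p < 0.01,
  |log2 FC| > 5, FDR < 0.01 and/or z > 1.
* **Clusters and stages**: average-linkage hierarchical clustering under
  1 − Pearson distance with silhouette-selected k; sample PCA and
  k-medoids staging; stage-specific (FC > 1.5 versus every other stage)
  and conserved elements.
* **Motif analysis**: JASPAR PFM parsing, log-odds PWM scanning of both
  strands at 0.8 of the maximum score (verified against an exhaustive
  oracle), hypergeometric enrichment/depletion with signed −log10 p,
  motif-by-sample module maps, and TF expression-by-enrichment tables.
* **Footprints**: aggregated per-base insertion profiles around motif
  occurrences and a flank-minus-core depth statistic, flank-normalized
  for cross-timepoint comparison.
* **Regulatory networks**: 2-kb strand-aware promoters, candidate TFs
  (motif enriched at p < 0.05 and expressed), directed edges A→B when
  A's motif hits B's promoter, edges typed by expression correlation
  (positive PCC > 0.4, negative < −0.4, otherwise none), one network per
  timepoint, exported as edge TSV + GraphML.
* **Chronology**: min–max-scaled mean trajectories, a least-squares
  two-segment change-point estimator with sub-grid (parabolic)
  refinement, and onset lags in days.
* **A seeded synthetic-data generator** reproducing the study design
  (planted temporal clusters, motifs, regulatory edges, footprints,
  lagged expression and phenotype) so the whole pipeline is testable
  end to end against known ground truth.

## Worked example

```r
library(atacdyn)

ds <- generate_dataset(sim_config(seed = 42))
ds
#> sim_dataset (seed 42): 1600 peaks x 16 samples, 40 motifs, 310 genes, 40 planted edges

sf   <- estimate_size_factors(ds$counts)
norm <- normalize_counts(ds$counts, sf)
res  <- all_pairwise_differential(ds$counts, sf)   # 28 comparisons
intr <- intrinsic_scores(norm)
sel  <- select_differential_peaks(res, intr)
sel$counts
#>  pairwise intrinsic  selected
#>       163       425       433

clusters <- hier_cluster(norm[sel$selected, ], "rows", k_range = 2:8)
clusters$k          # silhouette selects three temporal clusters
#> [1] 3
table(clusters$labels)
#>   1   2   3
#> 260  34 139

traj <- mean_trajectory(norm, names(clusters$labels)[clusters$labels == 1])
onset_changepoint(traj, sim_config()$timepoints)[c("onset_day", "onset_refined")]
#> $onset_day
#> [1] 14
#> $onset_refined
#> [1] 14
```

433 of 1600 peaks are called differential; they fall into three
clusters — an opening cluster of 260 peaks, a closing cluster of 139 and
a transient cluster of 34 — and the opening cluster's mean accessibility
trajectory has its change point at day 14: chromatin opens a week before
the NK phenotype appears. `run_pipeline(run_config(seed = 1), "out/")`
chains all stages (simulate → diffpeaks → cluster → motifs → footprint →
network → dynamics) and writes a deterministic `manifest.json`;
`inst/scripts/atacdyn.R` is a command-line wrapper around it.

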
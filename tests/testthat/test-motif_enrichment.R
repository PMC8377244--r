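test_that("log-odds scoring matches its closed form", {
  uni <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(unname(pwm_logodds(uni)), matrix(0, 4, 6), tolerance = 1e-12)
  pwm <- make_pwm("AAAA", p_hi = 1 - 3e-12)
  lo <- pwm_logodds(pwm)
  expect_equal(unname(lo["A", 1]), log2(1.001 / 0.251), tolerance = 1e-6)  # ~2 bits
  expect_equal(pwm_max_score(pwm), sum(apply(lo, 2, max)))
})

test_that("a consensus sequence yields exactly one maximal forward hit", {
  pwm <- make_pwm("AACGTAGG")
  hits <- scan_sequence("AACGTAGG", pwm)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 0L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, pwm_max_score(pwm), tolerance = 1e-12)
})

test_that("palindromic motifs hit both strands at the same position", {
  pwm <- make_pwm("AACGTT")  # reverse complement of AACGTT is AACGTT
  hits <- scan_sequence("AACGTT", pwm)
  expect_equal(nrow(hits), 2)
  expect_equal(sort(hits$strand), c("+", "-"))
  expect_equal(unique(hits$start), 0L)
})

test_that("the scanner agrees with exhaustive window scoring on random sequences", {
  set.seed(31)
  for (i in 1:5) {
    s <- random_seq(50)
    pwm <- make_pwm(random_seq(sample(6:10, 1)), id = "R")
    for (frac in c(0.8, 0.5, -10)) {  # -10: every window reported
      got <- scan_sequence(s, pwm, threshold_frac = frac)
      want <- bf_scan(s, pwm, threshold_frac = frac)
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }
})

test_that("multi-sequence scanning equals per-sequence scanning and skips Ns", {
  set.seed(32)
  seqs <- c(s1 = random_seq(80), s2 = "ACGTNNNACGTACGT", s3 = random_seq(40))
  ms <- motif_set(list(make_pwm("ACGTACG", "M1"), make_pwm("TTGACCA", "M2")))
  all_hits <- scan_sequences(seqs, ms, threshold_frac = 0.5)
  for (nm in names(seqs)) {
    for (mid in names(ms)) {
      got <- all_hits[all_hits$seq_name == nm & all_hits$motif_id == mid, ]
      want <- scan_sequence(seqs[[nm]], ms[[mid]], threshold_frac = 0.5)
      expect_equal(got$start, want$start, label = paste(nm, mid))
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }
  # windows containing N are never reported
  n_hits <- scan_sequences(c(x = "ACGNACG"), motif_set(list(make_pwm("ACG", "M"))),
                           threshold_frac = -10)
  expect_true(all(n_hits$start %in% c(0, 4)))
  # shorter than motif -> empty
  expect_equal(nrow(scan_sequence("ACG", make_pwm("ACGTT"))), 0)
})

test_that("reverse-complementing the genome mirrors hits and swaps strands", {
  set.seed(33)
  s <- paste0(random_seq(30), "AACGTAGG", random_seq(30))
  pwm <- make_pwm("AACGTAGG")
  fwd <- scan_sequence(s, pwm)
  rev <- scan_sequence(atacdyn:::revcomp(s), pwm)
  n <- nchar(s)
  expect_equal(sort(n - rev$end), sort(fwd$start))
  expect_setequal(paste(fwd$start, fwd$strand),
                  paste(n - rev$end, ifelse(rev$strand == "+", "-", "+")))
  expect_equal(sort(fwd$score), sort(rev$score), tolerance = 1e-12)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  hits <- data.frame(seq_name = sprintf("p%d", 1:10), motif_id = "M1")
  universe <- sprintf("p%d", 1:100)
  target <- sprintf("p%d", 1:10)
  e <- enrich_motifs(target, universe, hits)
  expect_equal(e$p_value, 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(e$k_target, 10)
  expect_gt(e$signed_score, 0)
  # direct mass summation across a grid of configurations
  set.seed(34)
  for (i in 1:20) {
    N <- sample(50:200, 1); n <- sample(5:40, 1)
    K <- sample(0:N, 1)
    univ <- sprintf("u%d", seq_len(N))
    with_hit <- sample(univ, K)
    tgt <- sample(univ, n)
    h <- data.frame(seq_name = with_hit, motif_id = "M")
    e <- enrich_motifs(tgt, univ, h)
    k <- length(intersect(tgt, with_hit))
    expect_equal(e$k_target, k)
    if (e$enriched) {
      expect_equal(e$p_value, bf_hyper_upper(k, K, N, n), tolerance = 1e-12)
    } else {
      expect_equal(e$p_value, sum(dhyper(0:k, K, N - K, n)), tolerance = 1e-12)
    }
  }
  expect_error(enrich_motifs(c("zz"), universe, hits), "subset")
})

test_that("matched target and universe hit fractions are not called enriched", {
  universe <- sprintf("p%d", 1:100)
  hits <- data.frame(seq_name = sprintf("p%d", seq(1, 100, 2)), motif_id = "M1")
  target <- sprintf("p%d", 1:20)  # 10/20 with hit = universe fraction 50/100
  e <- enrich_motifs(target, universe, hits)
  expect_lte(abs(e$signed_score), -log10(0.5) + 0.2)
})

test_that("planted cluster motifs dominate enrichment and decoys stay null", {
  for (seed in c(42, 43)) {
    ds <- get_sim(seed)
    enr <- get_cluster_enrichment(seed)
    tf <- ds$truth$tf_table
    late_motifs <- tf$motif_id[tf$stage == "late"]
    early_motifs <- tf$motif_id[tf$stage == "early"]
    decoys <- setdiff(names(ds$motifs), tf$motif_id[tf$active])
    eII <- enr$II
    top <- eII$motif_id[which.max(eII$signed_score)]
    expect_true(top %in% late_motifs)
    expect_true(all(eII$fdr[eII$motif_id %in% late_motifs] < 1e-10))
    expect_true(all(eII$fdr[eII$motif_id %in% decoys] > 0.05))
    eI <- enr$I
    expect_true(all(eI$fdr[eI$motif_id %in% early_motifs] < 1e-10))
    expect_true(all(eI$fdr[eI$motif_id %in% decoys] > 0.05))
  }
})

test_that("module map columns equal per-set enrichment and empty sets are flagged", {
  ds <- get_sim(42)
  hits <- get_peak_hits(42)
  universe <- ds$peaks$name
  labs <- ds$truth$cluster_labels
  sets <- list(a = names(labs)[labs == "I"], b = names(labs)[labs == "I"],
               c = character(0))
  mm <- module_map(sets, hits, universe, motif_ids = names(ds$motifs))
  expect_equal(mm[, "a"], mm[, "b"])
  expect_true(all(mm[, "c"] == 0))
  expect_equal(attr(mm, "empty_sets"), "c")
  e <- enrich_motifs(sets$a, universe, hits, motif_ids = names(ds$motifs))
  expect_equal(unname(mm[e$motif_id, "a"]), e$signed_score)
})

test_that("opposite stage programs show opposite module-map sign patterns", {
  ds <- get_sim(42)
  hits <- get_peak_hits(42)
  labs <- ds$truth$cluster_labels
  mm <- module_map(list(early = names(labs)[labs == "I"],
                        late = names(labs)[labs == "II"]),
                   hits, ds$peaks$name, motif_ids = names(ds$motifs))
  tf <- ds$truth$tf_table
  em <- intersect(tf$motif_id[tf$stage == "early"], rownames(mm))
  lm <- intersect(tf$motif_id[tf$stage == "late"], rownames(mm))
  expect_true(all(mm[em, "early"] > 0))
  expect_true(all(mm[lm, "late"] > 0))
  expect_true(mean(mm[em, "late"] <= 0) > 0.8)
  expect_true(mean(mm[lm, "early"] <= 0) > 0.8)
})

test_that("the TF bubble table joins enrichment with expression verbatim", {
  ds <- get_sim(42)
  enr <- get_cluster_enrichment(42)$II
  mapping <- ds$mapping[1:3, ]
  tab <- tf_bubble_table(enr, ds$expression, mapping)
  expect_equal(nrow(tab), 3 * length(ds$expression$timepoints))
  one <- tab[tab$gene == mapping$gene[1], ]
  expect_equal(one$expression,
               as.numeric(ds$expression$values[mapping$gene[1], ]))
  expect_equal(unique(one$neg_log10_p),
               -log10(max(enr$p_value[enr$motif_id == mapping$motif_id[1]], 1e-300)))
  bad_map <- rbind(mapping, data.frame(motif_id = enr$motif_id[40], gene = "ghost"))
  expect_warning(tf_bubble_table(enr, ds$expression, bad_map), "ghost")
  expect_error(suppressWarnings(
    tf_bubble_table(enr, ds$expression,
                    data.frame(motif_id = "M001", gene = "ghost"))), "empty join")
})
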
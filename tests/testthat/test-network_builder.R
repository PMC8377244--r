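test_that("promoters are the 2 kb strand-aware upstream regions, clipped at edges", {
  tss <- peak_set(c("c1", "c1", "c1"), c(5000, 5000, 500), c(5001, 5001, 501),
                  c("gPlus", "gMinus", "gEdge"), strand = c("+", "-", "+"))
  pr <- promoter_regions(tss, 2000, c(c1 = 10000L))
  expect_equal(pr$start[pr$name == "gPlus"], 3000L)
  expect_equal(pr$end[pr$name == "gPlus"], 5000L)
  expect_equal(pr$start[pr$name == "gMinus"], 5000L)
  expect_equal(pr$end[pr$name == "gMinus"], 7000L)
  expect_equal(pr$start[pr$name == "gEdge"], 0L)
  expect_equal(pr$end[pr$name == "gEdge"], 500L)
  expect_true(pr$clipped[pr$name == "gEdge"])
  expect_false(any(pr$clipped[pr$name != "gEdge"]))
  tss$strand <- "."
  expect_error(promoter_regions(tss), "strand")
})

test_that("candidate TFs need both enrichment and expression", {
  expr <- expr_matrix(rbind(gA = c(8, 8, 8, 8), gB = c(1, 1, 1, 1)),
                      c(7, 14, 21, 35), tf_flags = c("gA", "gB"))
  enr <- data.frame(motif_id = c("mA", "mB"), p_value = c(1e-6, 1e-6),
                    enriched = c(TRUE, TRUE))
  mapping <- data.frame(motif_id = c("mA", "mB"), gene = c("gA", "gB"))
  cands <- candidate_tfs(list(enr), expr, mapping, expressed_threshold = 5)
  expect_equal(cands$gene, "gA")      # gB enriched but never expressed
  enr2 <- transform(enr, p_value = c(0.5, 0.5))
  expect_equal(nrow(candidate_tfs(list(enr2), expr, mapping, expressed_threshold = 5)), 0)
})

test_that("planted regulators are retained and decoy TFs rejected across seeds", {
  kept <- lapply(c(42, 43), function(seed) {
    ds <- get_sim(seed)
    cands <- candidate_tfs(get_cluster_enrichment(seed), ds$expression, ds$mapping)
    tf <- ds$truth$tf_table
    c(active = mean(tf$gene[tf$active] %in% cands$gene),
      decoy_excluded = mean(!tf$gene[!tf$active] %in% cands$gene))
  })
  expect_gte(min(vapply(kept, `[[`, 0, "active")), 0.95)
  expect_gte(min(vapply(kept, `[[`, 0, "decoy_excluded")), 0.8)
})

test_that("timepoint-specific TF sets follow the fold rule and are disjoint", {
  expr <- expr_matrix(rbind(flat = rep(5, 4),
                            spike = c(1, 1, 1, log2(10 * 2))),
                      c(7, 14, 21, 35), tf_flags = c("flat", "spike"))
  sets <- stage_specific_tfs(expr, genes = c("flat", "spike"), fc = 1.5)
  expect_length(sets$d7, 0)
  expect_equal(sets$d35, "spike")
  ds <- get_sim(42)
  sets2 <- stage_specific_tfs(ds$expression, fc = 1.01)
  expect_equal(anyDuplicated(unlist(sets2)), 0)
})

test_that("edges are promoter-defined with high recall and precision on planted truth", {
  pr <- vapply(42:46, function(seed) {
    ds <- get_sim(seed)
    cands <- candidate_tfs(get_cluster_enrichment(seed), ds$expression, ds$mapping)
    edges <- infer_edges(cands, get_prom_hits(seed))
    found <- paste(edges$source, edges$target)
    truth <- paste(ds$truth$edges$source, ds$truth$edges$target)
    recall <- mean(truth %in% found)
    precision <- mean(found %in% truth)
    expect_gte(recall, 0.95)   # guaranteed by construction of the fixture
    expect_gte(precision, 0.7) # chance consensus matches add a few edges
    c(precision, recall)
  }, numeric(2))
  expect_gte(mean(pr[1, ]), 0.8)
  f1 <- 2 * pr[1, ] * pr[2, ] / (pr[1, ] + pr[2, ])
  expect_gte(mean(f1), 0.85)
})

test_that("edge inference handles empty input and flags self-loops", {
  cands <- data.frame(motif_id = c("m1", "m2"), gene = c("g1", "g2"))
  empty <- data.frame(seq_name = character(), motif_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      score = numeric())
  expect_equal(nrow(infer_edges(cands, empty)), 0)
  hits <- data.frame(seq_name = c("g1", "g2"), motif_id = c("m1", "m1"))
  e <- infer_edges(cands, hits)
  expect_equal(nrow(e), 2)
  expect_true(e$self_loop[e$target == "g1"])
  expect_false(e$self_loop[e$target == "g2"])
})

test_that("edge typing uses a strict PCC threshold with a closed none-interval", {
  tp <- c(7, 14, 19, 21, 24, 26, 28, 35)
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expr <- expr_matrix(rbind(g1 = a, g2 = a * 2 + 3, g3 = -a, g4 = rep(2, 8),
                            g5 = c(5, 1, 4, 2, 6, 3, 7, 2)),
                      tp, tf_flags = NULL)
  edges <- data.frame(source = c("g1", "g1", "g1", "g1"),
                      target = c("g2", "g3", "g4", "g5"),
                      source_motif = "m", n_hits = 1L, self_loop = FALSE)
  typed <- classify_edges(edges, expr)
  expect_equal(typed$edge_type, c("positive", "negative", "none", "none"))
  expect_equal(typed$pcc[1], 1)
  expect_equal(typed$pcc[2], -1)
  expect_true(typed$pcc_undefined[3])  # zero-variance profile
  # a PCC exactly at the threshold is typed none (closed interval)
  pcc_15 <- cor(expr$values["g1", ], expr$values["g5", ])
  typed_eq <- classify_edges(edges[4, ], expr, threshold = abs(pcc_15))
  expect_equal(typed_eq$edge_type, "none")
  # direction is promoter-defined: negating a profile flips type, not direction
  expr_neg <- expr
  expr_neg$values["g2", ] <- -expr$values["g2", ]
  retyped <- classify_edges(edges, expr_neg)
  expect_equal(retyped$edge_type[1], "negative")
  expect_equal(retyped[, c("source", "target")], typed[, c("source", "target")])
})

test_that("timepoint networks keep only TFs expressed/specific at that day", {
  ds <- get_sim(42)
  cands <- candidate_tfs(get_cluster_enrichment(42), ds$expression, ds$mapping)
  stfs <- stage_specific_tfs(ds$expression)
  edges <- classify_edges(infer_edges(cands, get_prom_hits(42)), ds$expression)
  all_edges <- nrow(edges)
  tf <- ds$truth$tf_table
  net7 <- build_timepoint_network(7, cands, stfs, edges, ds$expression)
  net35 <- build_timepoint_network(35, cands, stfs, edges, ds$expression)
  expect_lte(nrow(net7$edges), all_edges)
  expect_true(all(net7$edges$source %in% net7$nodes$tf))
  expect_true(all(net7$edges$target %in% net7$nodes$tf))
  # day-7-peaked TFs populate the day-7 network, not the day-35 network
  day7_tfs <- tf$gene[!is.na(tf$peak_day) & tf$peak_day == 7]
  day35_tfs <- tf$gene[!is.na(tf$peak_day) & tf$peak_day == 35]
  expect_gte(length(intersect(day7_tfs, net7$nodes$tf)), 2)
  expect_length(intersect(day7_tfs, net35$nodes$tf), 0)
  expect_gte(length(intersect(day35_tfs, net35$nodes$tf)), 2)
  # the planted within-day edge of day 7 appears in the strict day-7 network
  within7 <- ds$truth$edges[ds$truth$edges$source %in% day7_tfs &
                            ds$truth$edges$target %in% day7_tfs, ]
  expect_gte(nrow(within7), 1)
  expect_true(all(paste(within7$source, within7$target) %in%
                  paste(net7$edges$source, net7$edges$target)))
  # non-strict mode only adds nodes
  loose <- build_timepoint_network(7, cands, stfs, edges, ds$expression,
                                   strict = FALSE)
  expect_true(all(net7$nodes$tf %in% loose$nodes$tf))
})

test_that("network construction is a pure function of its inputs", {
  ds <- get_sim(42)
  cands <- candidate_tfs(get_cluster_enrichment(42), ds$expression, ds$mapping)
  stfs <- stage_specific_tfs(ds$expression)
  edges <- classify_edges(infer_edges(cands, get_prom_hits(42)), ds$expression)
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".graphml")
  write_network(build_timepoint_network(26, cands, stfs, edges, ds$expression), f1,
                "graphml")
  write_network(build_timepoint_network(26, cands, stfs, edges, ds$expression), f2,
                "graphml")
  expect_identical(readLines(f1), readLines(f2))
})
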
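small_config <- function(seed, n_genes = 300, ...) {
  cfg <- simulation_config(seed = seed, n_genes = n_genes, chrom_length = 1e7, ...)
  cfg$tfs$n_peaks <- c(600L, 600L, 600L)
  cfg$n_sequence_peaks <- 400L
  cfg$gene_set_size <- 60L
  cfg
}

test_that("simulated annotations are valid, non-overlapping and strand-mixed", {
  cfg <- small_config(101)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), 300)
  expect_true(all(ann$start < ann$end))
  expect_true(all(table(ann$chrom) > 0))
  by_chrom <- split(ann, ann$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    expect_true(all(g$end[-nrow(g)] <= g$start[-1])) # no overlap
  }
  expect_true(all(c("+", "-") %in% ann$strand))
  expect_true(all(ann$end <= attr(ann, "chrom_sizes")[ann$chrom]))
})

test_that("a single-gene annotation is valid and an overfull genome errors", {
  one <- simulation_config(seed = 5, n_genes = 1, n_chroms = 1)
  expect_equal(nrow(simulate_annotation(one)), 1)
  crowded <- simulation_config(seed = 5, n_genes = 600, n_chroms = 1,
                               chrom_length = 1e6,
                               gene_length_range = c(2e3, 2e3))
  expect_error(simulate_annotation(crowded), "cannot fit")
})

test_that("strand assignment matches the configured probability", {
  frac <- vapply(1:30, function(s) {
    mean(simulate_annotation(small_config(2000 + s))$strand == "+")
  }, numeric(1))
  p_hat <- mean(frac)
  se <- sqrt(0.5 * 0.5 / (30 * 300))
  expect_lt(abs(p_hat - 0.5), 2.58 * se * 3) # generous 99% band
})

test_that("planted fold-changes survive the signal construction exactly", {
  cfg <- small_config(103)
  ann <- simulate_annotation(cfg)
  peaks <- simulate_peaks(cfg, ann)
  fc <- fold_change(peaks$treated_signal, peaks$control_signal,
                    pseudocount = cfg$pseudocount)
  expect_equal(log2(fc), peaks$planted_log2_fc, tolerance = 1e-9)
  ahr <- peaks[peaks$tf == "AhR", ]
  expect_true(all(ahr$control_signal == 0))
  expect_true(all(classify_differential(
    fold_change(ahr$treated_signal, ahr$control_signal, cfg$pseudocount)
  ) != "decreased"))
})

test_that("the planted intragenic flag agrees with the pipeline's region classifier", {
  cfg <- small_config(104)
  ann <- simulate_annotation(cfg)
  peaks <- simulate_peaks(cfg, ann)
  region <- classify_region(peaks, ann, upstream_bp = cfg$upstream_bp)$region
  expect_equal(region == "intragenic", peaks$planted_intragenic)
})

test_that("the expression generator hits the target DEG fraction and plants repression", {
  cfg <- small_config(105, n_genes = 800)
  tab <- simulate_pattern_table(800, null_pattern_freqs, seed = 105)
  expr <- call_degs(simulate_expression(cfg, tab))
  top <- summarize_degs(expr, conditions = "30")
  frac <- top$n_deg / top$n_genes
  ci <- 2.58 * sqrt(0.3 * 0.7 / 800)
  expect_lt(abs(frac - 0.3), ci + 0.01)
  planted_key <- "increased/decreased/increased"
  planted_ids <- tab$gene_id[tab$pattern_key == planted_key]
  top_expr <- expr[expr$condition == "30" & expr$gene_id %in% planted_ids, ]
  expect_lt(median(top_expr$log2_fc), -1)
  expect_gt(mean(top_expr$deg_status == "repressed"), 0.9)
})

test_that("pattern tables reproduce their sampling frequencies", {
  tab <- simulate_pattern_table(5000, null_pattern_freqs, seed = 7)
  freq <- table(tab$pattern_key) / nrow(tab)
  for (key in names(null_pattern_freqs)) {
    expect_lt(abs(freq[[key]] - null_pattern_freqs[[key]]),
              2.58 * sqrt(null_pattern_freqs[[key]] / 5000) + 0.01)
  }
  expect_false(any(tab$bound_AhR[tab$direction_AhR == "unbound"]))
  expect_true(all(tab$differential_COUP_TFII ==
                    (tab$direction_COUP_TFII %in% c("increased", "decreased"))))
})

test_that("enriched target sampling favours the planted pattern", {
  tab <- simulate_pattern_table(3000, null_pattern_freqs, seed = 8)
  target <- sample_enriched_target(tab, "increased/decreased/increased",
                                   odds_ratio = 8, n = 150, seed = 9)
  base <- mean(tab$pattern_key == "increased/decreased/increased")
  hit <- mean(tab$pattern_key[match(target, tab$gene_id)] ==
                "increased/decreased/increased")
  expect_gt(hit, 2 * base)
  expect_error(sample_enriched_target(tab, "x", 8, 4000, seed = 1), "exceeds")
})

test_that("gene sets are planted at the configured size and enrichment", {
  cfg <- small_config(106)
  tab <- simulate_pattern_table(300, null_pattern_freqs, seed = 106)
  sets <- simulate_gene_sets(cfg, tab)
  expect_equal(nrow(sets), cfg$n_gene_sets)
  expect_true(all(lengths(sets$genes) == cfg$gene_set_size))
  expect_equal(sets$name[1], "PLANTED_PATTERN_SET")
  cfg_big <- small_config(106)
  cfg_big$gene_set_size <- 400L
  expect_error(simulate_gene_sets(cfg_big, tab), "exceeds")
})

test_that("motif planting rates differ between differential and stable peaks", {
  cfg <- small_config(107)
  ann <- simulate_annotation(cfg)
  peaks <- simulate_peaks(cfg, ann)
  seqs <- simulate_sequences(cfg, peaks)
  planted <- attr(seqs, "planted")
  differential <- attr(seqs, "differential")
  expect_equal(length(seqs), cfg$n_sequence_peaks)
  expect_true(all(nchar(seqs) == cfg$seq_length))
  r_diff <- mean(planted[differential])
  r_stable <- mean(planted[!differential])
  expect_lt(abs(r_diff - cfg$motif_target_rate), 0.12)
  expect_lt(abs(r_stable - cfg$motif_background_rate), 0.06)
})

test_that("regenerating a study from one config is byte-identical", {
  cfg <- small_config(108)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- simulate_study(cfg, d1)$files
  f2 <- simulate_study(cfg, d2)$files
  for (nm in setdiff(names(f1), "manifest")) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     label = sprintf("file %s", nm))
  }
  # a different seed changes the data
  f3 <- simulate_study(small_config(109), withr::local_tempdir())$files
  expect_false(identical(readLines(f1[["expression"]]),
                         readLines(f3[["expression"]])))
})
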
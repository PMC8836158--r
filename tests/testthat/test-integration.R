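annotated_peak <- function(tf, gene_id, log2_fc, status) {
  tibble::tibble(tf = tf, gene_id = gene_id, log2_fc = log2_fc, status = status)
}

test_that("gene-level directions come from the strongest intragenic peak per factor", {
  peaks <- dplyr::bind_rows(
    annotated_peak("AhR", "g1", 1.2, "increased"),
    annotated_peak("COUP_TFII", "g1", -0.9, "decreased"),
    annotated_peak("COUP_TFII", "g1", 0.1, "no_change"),
    annotated_peak("HNF4A", "g2", 0.2, "no_change")
  )
  tab <- gene_binding_table(peaks, tf_levels = c("AhR", "COUP_TFII", "HNF4A"))
  g1 <- tab[tab$gene_id == "g1", ]
  expect_equal(g1$pattern_key, "increased/decreased/unbound")
  expect_true(g1$any_differential)
  g2 <- tab[tab$gene_id == "g2", ]
  expect_equal(g2$pattern_key, "unbound/unbound/no_change")
  expect_false(g2$any_differential)
})

test_that("the max-|log2FC| rule picks the dominant peak and ties go to increased", {
  peaks <- dplyr::bind_rows(
    annotated_peak("COUP_TFII", "g1", 0.8, "increased"),
    annotated_peak("COUP_TFII", "g1", -1.3, "decreased")
  )
  tab <- gene_binding_table(peaks, tf_levels = "COUP_TFII")
  expect_equal(tab$direction_COUP_TFII, "decreased")
  tie <- dplyr::bind_rows(
    annotated_peak("COUP_TFII", "g1", 1.0, "increased"),
    annotated_peak("COUP_TFII", "g1", -1.0, "decreased")
  )
  expect_equal(gene_binding_table(tie, tf_levels = "COUP_TFII")$direction_COUP_TFII,
               "increased")
})

test_that("unbound annotation genes get all-unbound rows when requested", {
  peaks <- annotated_peak("AhR", "g1", 1, "increased")
  genes <- make_genes(c("g1", "g2"), "chr1", "+", c(0, 5000), c(1000, 6000))
  tab <- gene_binding_table(peaks, genes = genes, tf_levels = "AhR")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$direction_AhR[tab$gene_id == "g2"], "unbound")
})

test_that("intersection counts partition bound genes over exact combinations", {
  peaks <- dplyr::bind_rows(
    annotated_peak("AhR", "g1", 1, "increased"),
    annotated_peak("AhR", "g2", 1, "increased"),
    annotated_peak("HNF4A", "g2", 0.1, "no_change"),
    annotated_peak("AhR", "g3", 0.1, "no_change"),
    annotated_peak("COUP_TFII", "g3", -1, "decreased"),
    annotated_peak("HNF4A", "g3", 0.2, "no_change")
  )
  tab <- gene_binding_table(peaks, tf_levels = c("AhR", "COUP_TFII", "HNF4A"))
  cnt <- intersection_counts(tab)
  expect_equal(nrow(cnt), 7)
  expect_equal(cnt$n_bound[cnt$combination == "AhR"], 1)
  expect_equal(cnt$n_bound[cnt$combination == "AhR+HNF4A"], 1)
  expect_equal(cnt$n_bound[cnt$combination == "AhR+COUP_TFII+HNF4A"], 1)
  expect_equal(sum(cnt$n_bound), nrow(tab)) # combinations partition bound genes
  # g3 is co-bound by all three with one differential member factor
  expect_equal(cnt$n_with_differential[cnt$combination == "AhR+COUP_TFII+HNF4A"], 1)
  # g2 is bound by AhR+HNF4A and AhR is differential there
  expect_equal(cnt$n_with_differential[cnt$combination == "AhR+HNF4A"], 1)
})

test_that("the one-sided Fisher test is the exact hypergeometric upper tail", {
  expect_equal(fisher_exact_greater(4, 4, 5, 10), 5 / choose(10, 4))
  expect_equal(fisher_exact_greater(0, 4, 5, 10), 1)
  expect_equal(fisher_exact_greater(4, 4, 4, 4), 1)
  expect_error(fisher_exact_greater(5, 4, 5, 10), "Inconsistent")
  expect_error(fisher_exact_greater(2, 4, 11, 10), "Inconsistent")
})

test_that("Fisher upper tail matches brute-force enumeration on small universes", {
  withr::with_seed(3, {
    for (i in 1:300) {
      N <- sample(2:30, 1)
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      ks <- max(0, n + K - N):min(n, K)
      k <- sample(ks, 1)
      expect_equal(fisher_exact_greater(k, n, K, N),
                   hyper_tail_bruteforce(k, n, K, N), tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment reproduces the step-up computation and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  withr::with_seed(9, {
    p <- runif(50)
    q <- bh_fdr(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in rank
    # a flat adjusted vector is a fixed point of the step-up procedure
    expect_equal(bh_fdr(rep(0.2, 10)), rep(0.2, 10))
  })
})

test_that("pattern ORA builds consistent contingencies and flags stray targets", {
  tab <- simulate_pattern_table(500, null_pattern_freqs, seed = 4)
  reference <- tab$gene_id
  target <- reference[1:100]
  res <- pattern_ora(tab, target, reference)
  expect_equal(sum(res$K), length(reference)) # patterns partition the universe
  expect_equal(sum(res$k), length(target))
  expect_true(all(res$q_value >= res$p_value))
  expect_true(!is.unsorted(res$p_value))
  # target = reference: every k equals K and every p is 1
  all_res <- pattern_ora(tab, reference, reference)
  expect_equal(all_res$k, all_res$K)
  expect_true(all(all_res$p_value == 1))
  expect_error(pattern_ora(tab, c(target, "ghost"), reference), "ghost")
})

test_that("reference genes missing from the binding table count as unbound", {
  tab <- simulate_pattern_table(50, null_pattern_freqs, seed = 4)
  reference <- c(tab$gene_id, "extraA", "extraB")
  res <- pattern_ora(tab, reference[1:10], reference)
  expect_equal(sum(res$K), length(reference))
  # with collapse_unbound = FALSE the extra genes form an all-unbound pattern
  res2 <- pattern_ora(tab, reference[1:10], reference, collapse_unbound = FALSE)
  expect_true("unbound/unbound/unbound" %in% res2$term)
})

test_that("functional ORA ranks a self-identical term first and keeps empty overlaps", {
  universe <- sprintf("g%03d", 1:200)
  degs <- universe[1:50]
  sets <- tibble::tibble(
    name = c("self", "half", "none"),
    description = "",
    genes = list(degs, universe[26:75], universe[151:200])
  )
  res <- functional_ora(degs, sets, universe)
  expect_equal(res$term[1], "self")
  expect_equal(res$p_value[res$term == "none"], 1)
  expect_equal(res$k[res$term == "none"], 0)
  # term-wise equivalence with the shared Fisher implementation
  half <- res[res$term == "half", ]
  expect_equal(half$p_value,
               fisher_exact_greater(half$k, half$n, half$K, half$N))
  expect_error(functional_ora(c(degs, "zz"), sets, universe), "zz")
  expect_error(functional_ora(degs, sets, character(0)), "empty")
})

test_that("a zero-control factor never yields a decreased gene direction", {
  cfg <- simulation_config(seed = 31, n_genes = 200)
  cfg$tfs$n_peaks <- c(400L, 400L, 400L)
  ann <- simulate_annotation(cfg)
  peaks <- annotate_peaks(simulate_peaks(cfg, ann), ann)
  tab <- gene_binding_table(peaks, genes = ann, tf_levels = cfg$tfs$tf)
  expect_true(all(tab$direction_AhR != "decreased"))
  expect_true(any(tab$direction_COUP_TFII == "decreased"))
})
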
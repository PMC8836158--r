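test_that("fold_change matches its definition and rejects bad input", {
  expect_equal(fold_change(8, 4, pseudocount = 0), 2)
  expect_equal(fold_change(5, 5, pseudocount = 1), 1)
  expect_equal(fold_change(3, 0, pseudocount = 0.5), 7)
  expect_error(fold_change(-1, 2), "nonnegative")
  expect_error(fold_change(1, -2), "nonnegative")
  expect_error(fold_change(1, 0, pseudocount = 0), "positive pseudocount")
})

test_that("differential classification uses inclusive thresholds on both sides", {
  expect_equal(classify_differential(c(1.5, 0.6, 1.0, 2.3, 0.1)),
               c("increased", "decreased", "no_change", "increased", "decreased"))
  expect_error(classify_differential(c(1, -0.5)), "positive")
  peaks <- make_peaks(0, 100) |> peak_fold_change(pseudocount = 0)
  expect_equal(classify_differential(peaks)$status, "increased")
})

test_that("differential status is monotone in fold-change", {
  fc <- sort(c(10^seq(-2, 2, length.out = 200), 0.6, 1.5))
  status <- classify_differential(fc)
  rank <- c(decreased = 1, no_change = 2, increased = 3)[status]
  expect_true(all(diff(rank) >= 0))
})

test_that("region classification follows the strand-aware upstream window", {
  genes <- make_genes("g1", "chr1", "+", 50000, 60001)
  expect_equal(genes$tss, 50000)
  p_in <- make_peaks(41000, 42000)
  p_out <- make_peaks(39000, 39500)
  expect_equal(classify_region(p_in, genes)$region, "intragenic")
  expect_equal(classify_region(p_out, genes)$region, "intergenic")
  # minus-strand gene body 50000-60000: TSS = 59999, upstream extends right
  genes_m <- make_genes("g1", "chr1", "-", 50000, 60000)
  p_m <- make_peaks(65000, 66000)
  expect_equal(classify_region(p_m, genes_m)$region, "intragenic")
  p_m2 <- make_peaks(70000, 71000) # center 70500 > 69999
  expect_equal(classify_region(p_m2, genes_m)$region, "intergenic")
})

test_that("peaks on unannotated chromosomes are kept as intergenic with a warning", {
  genes <- make_genes("g1", "chr1", "+", 0, 1000)
  peaks <- make_peaks(10, 500, chrom = "chrUn")
  expect_warning(out <- classify_region(peaks, genes), "chrUn")
  expect_equal(out$region, "intergenic")
})

test_that("closest-gene assignment minimizes center-TSS distance with documented ties", {
  genes <- make_genes(c("g1", "g2"), "chr1", "+", c(40000, 48000), c(70000, 80000))
  peak <- make_peaks(44800, 45200) # center 45000: |45000-40000| vs |45000-48000|
  expect_equal(assign_closest_gene(peak, genes)$gene_id, "g2")
  # single candidate
  one <- make_peaks(41000, 41400)
  expect_equal(assign_closest_gene(one, make_genes("g1", "chr1", "+", 40000, 70000))$gene_id, "g1")
  # exact tie: TSSs at 40000 and 50000, center 45000 -> lexicographically smaller id
  tied <- make_genes(c("gB", "gA"), "chr1", "+", c(40000, 50000), c(70000, 80000))
  expect_equal(assign_closest_gene(peak, tied)$gene_id, "gA")
  # intergenic peaks get NA
  far <- make_peaks(200000, 200400)
  expect_true(is.na(assign_closest_gene(far, genes)$gene_id))
})

test_that("closest-gene assignment agrees with exhaustive search on random annotations", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      n_genes <- 15
      starts <- sort(sample.int(2e5, n_genes))
      genes <- make_genes(
        gene_id = sprintf("g%02d", sample(n_genes)), chrom = "chr1",
        strand = sample(c("+", "-"), n_genes, TRUE),
        start = starts, end = starts + sample(1000:5000, n_genes, TRUE)
      )
      peaks <- random_peaks(40, chroms = "chr1", max_pos = 2.2e5)
      got <- assign_closest_gene(peaks, genes)
      win <- crossbind:::gene_windows(genes, 10000)
      centers <- floor((peaks$start + peaks$end) / 2)
      for (i in seq_len(nrow(peaks))) {
        cand <- win[win$win_lo <= centers[i] & centers[i] <= win$win_hi, ]
        if (nrow(cand) == 0) {
          expect_true(is.na(got$gene_id[i]))
        } else {
          d <- abs(centers[i] - cand$tss)
          best <- sort(cand$gene_id[d == min(d)])[1]
          expect_equal(got$gene_id[i], best)
        }
      }
    }
  })
})

test_that("every peak lands in exactly one region class and counts partition", {
  withr::with_seed(5, {
    genes <- make_genes(c("g1", "g2"), c("chr1", "chr2"), c("+", "-"),
                        c(20000, 1000), c(30000, 9000))
    peaks <- random_peaks(200)
    out <- classify_region(peaks, genes)
    expect_true(all(out$region %in% c("intragenic", "intergenic")))
    s <- summarize_peaks(
      out |> peak_fold_change() |> classify_differential()
    )
    expect_equal(s$n_intragenic + s$n_intergenic, nrow(peaks))
    expect_equal(s$n_increased + s$n_decreased + s$n_no_change, s$n_peaks)
  })
})

test_that("overlap_summary counts shared-bp overlaps and signed center distances", {
  ref <- make_peaks(100, 200, tf = "A")
  oth <- make_peaks(150, 250, tf = "B")
  out <- overlap_summary(ref, oth)
  expect_equal(out$n_overlapping, 1)
  expect_equal(out$percent, 100)
  hist_tbl <- out$distance_histogram[[1]]
  # centers 150 and 200 -> signed distance +50 in bin [0, bin_width)
  expect_equal(sum(hist_tbl$count), 1)
  expect_equal(hist_tbl$bin_lo[hist_tbl$count == 1], 0)
  disjoint <- overlap_summary(make_peaks(100, 200), make_peaks(300, 400))
  expect_equal(disjoint$n_overlapping, 0)
  expect_equal(disjoint$percent, 0)
  same <- overlap_summary(ref, ref)
  expect_equal(same$percent, 100)
  h <- same$distance_histogram[[1]]
  expect_equal(h$bin_lo[h$count > 0], 0) # zero distances in the [0, w) bin
  expect_error(overlap_summary(ref[0, ], oth), "empty")
})

test_that("overlap counting agrees with the all-pairs intersection oracle", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      ref <- random_peaks(sample(5:100, 1))
      oth <- random_peaks(sample(5:100, 1))
      expect_equal(overlap_summary(ref, oth)$n_overlapping,
                   overlap_bruteforce(ref, oth))
    }
  })
})

test_that("summarize_peaks reports medians by the mean-of-middle-two rule", {
  peaks <- make_peaks(c(0, 100, 200), c(50, 150, 250)) |>
    dplyr::mutate(fold_change = c(2^0.5, 2, 2^1.5),
                  log2_fc = c(0.5, 1, 1.5)) |>
    classify_differential()
  expect_equal(summarize_peaks(peaks)$median_log2_fc, 1)
  even <- peaks[1:2, ]
  expect_equal(summarize_peaks(even)$median_log2_fc, 0.75)
})
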
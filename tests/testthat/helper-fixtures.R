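# fixture builders shared across test files; everything is generated in code

make_genes <- function(gene_id, chrom, strand, start, end, chrom_sizes = NULL) {
  genes <- tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                          start = as.integer(start), end = as.integer(end))
  genes <- crossbind:::add_tss_tes(genes)
  attr(genes, "chrom_sizes") <- chrom_sizes
  genes
}

make_peaks <- function(start, end, chrom = "chr1", tf = "TF1",
                       treated = 10, control = 5) {
  n <- length(start)
  tibble::tibble(
    tf = rep_len(tf, n), chrom = rep_len(chrom, n),
    start = as.integer(start), end = as.integer(end),
    name = sprintf("pk%03d", seq_len(n)),
    treated_signal = rep_len(treated, n),
    control_signal = rep_len(control, n)
  )
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 5e4,
                         width_range = c(50, 500)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  make_peaks(start, start + width, chrom = sample(chroms, n, replace = TRUE))
}

write_gtf_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# independent upper-tail hypergeometric by direct summation of choose() terms
hyper_tail_bruteforce <- function(k, n, K, N) {
  js <- max(0, n + K - N):min(n, K)
  pmf <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  sum(pmf[js >= k])
}

# independent running-sum oracle: explicit position-by-position loop
es_bruteforce <- function(scores, hit, weight = 1) {
  n <- length(scores)
  w <- abs(scores[hit])^weight
  if (sum(w) == 0) w <- rep(1, sum(hit))
  sw <- sum(w)
  miss_step <- if (n > sum(hit)) 1 / (n - sum(hit)) else 0
  running <- numeric(n)
  cur <- 0
  wi <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      wi <- wi + 1
      cur <- cur + w[wi] / sw
    } else {
      cur <- cur - miss_step
    }
    running[i] <- cur
  }
  dev <- c(0, running)
  # positive deviation wins magnitude ties (same documented rule, same
  # tolerance against float error in the rational step sums)
  es <- if (max(dev) >= -min(dev) - 1e-12) max(dev) else min(dev)
  list(es = es, running = running)
}

# all-pairs interval intersection oracle for overlap counting
overlap_bruteforce <- function(reference, other) {
  hits <- vapply(seq_len(nrow(reference)), function(i) {
    same <- other$chrom == reference$chrom[i]
    any(same & other$start < reference$end[i] & reference$start[i] < other$end)
  }, logical(1))
  sum(hits)
}

null_pattern_freqs <- c(
  "no_change/no_change/no_change" = 0.25,
  "increased/no_change/no_change" = 0.20,
  "no_change/decreased/no_change" = 0.20,
  "no_change/no_change/increased" = 0.15,
  "increased/decreased/no_change" = 0.10,
  "increased/decreased/increased" = 0.10
)
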
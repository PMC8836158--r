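#' Run the full integration workflow on a synthetic study
#'
#' One-command demonstration: simulates a study, reads every artifact back
#' through the file-format layer, annotates peaks, summarizes differential
#' enrichment and overlaps, builds the gene binding table and intersection
#' counts, calls DEGs, runs pattern and functional over-representation,
#' preranked GSEA and motif enrichment, and writes every result table plus
#' a JSON manifest (parameters, package version, md5 of each output). The
#' returned recovery report compares planted ground truth with what the
#' pipeline measured.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (required).
#' @param config Optional [simulation_config()]; the default is a
#'   demo-sized configuration (800 genes, 2000 peaks per factor) so the run
#'   completes in seconds.
#' @param n_permutations Permutations for the GSEA stage.
#' @return Invisibly, a list with all result tibbles, the `recovery`
#'   report tibble, and `files`.
#' @export
run_demo <- function(out_dir, seed, config = NULL, n_permutations = 200) {
  if (missing(seed)) abort("run_demo() requires an explicit seed.")
  config <- config %||% demo_config(seed)
  sim_dir <- file.path(out_dir, "simulated")
  sim <- simulate_study(config, sim_dir)
  p <- function(f) file.path(out_dir, f)

  # read everything back through the format layer
  annotation <- read_gtf(sim$files[["annotation"]])
  peaks <- bind_rows(map(config$tfs$tf, function(tf) {
    read_peaks(sim$files[[paste0("peaks_", tf)]], tf_name = tf,
               treated_col = 7, control_col = 8)
  }))
  expr <- read_expression(sim$files[["expression"]])
  sets <- read_gmt(sim$files[["gene_sets"]])

  annotated <- annotate_peaks(peaks, annotation,
                              upstream_bp = config$upstream_bp,
                              pseudocount = config$pseudocount)
  peak_summary <- summarize_peaks(annotated)
  files <- c(peak_summary = write_result_table(peak_summary, p("peak_summary.tsv")))

  tfs <- config$tfs$tf
  pairs <- tidyr::expand_grid(a = tfs, b = tfs) |> filter(.data$a != .data$b)
  overlaps <- bind_rows(map2(pairs$a, pairs$b, function(a, b) {
    overlap_summary(filter(annotated, .data$tf == a),
                    filter(annotated, .data$tf == b))
  }))
  files["overlaps"] <- write_result_table(overlaps, p("overlap_summary.tsv"))

  table <- gene_binding_table(annotated, genes = annotation, tf_levels = tfs)
  combos <- intersection_counts(table)
  files["binding_table"] <- write_result_table(table, p("gene_binding_table.tsv"))
  files["intersections"] <- write_result_table(combos, p("intersection_counts.tsv"))

  expr <- call_degs(expr)
  deg_summary <- summarize_degs(expr)
  files["deg_summary"] <- write_result_table(deg_summary, p("deg_summary.tsv"))

  top_cond <- format(max(config$conditions), trim = TRUE)
  reference <- deg_genes(expr, top_cond)
  target <- intersect(sets$genes[[1]], reference)
  ora <- pattern_ora(table, target, reference)
  files["pattern_ora"] <- write_result_table(ora, p("pattern_ora.tsv"))

  fun_ora <- functional_ora(reference, sets, universe = annotation$gene_id)
  files["functional_ora"] <- write_result_table(fun_ora, p("functional_ora.tsv"))

  ranked <- rank_genes(expr, top_cond)
  gsea <- gsea_preranked(ranked, sets, n_permutations = n_permutations,
                         seed = config$seed + 101L)
  files["gsea"] <- write_result_table(gsea, p("gsea.tsv"))

  seqs <- sim$sequences
  differential <- attr(seqs, "differential")
  motifs <- motif_enrichment(seqs[differential], seqs[!differential],
                             default_pwms())
  files["motif_enrichment"] <- write_result_table(motifs, p("motif_enrichment.tsv"))

  recovery <- recovery_report(config, peak_summary, deg_summary, top_cond,
                              ora, gsea)
  files["recovery"] <- write_result_table(recovery, p("recovery_report.tsv"))

  manifest <- list(
    tool = "crossbind", version = as.character(packageVersion("crossbind")),
    subcommand = "demo", seed = config$seed,
    parameters = list(n_permutations = n_permutations,
                      upstream_bp = config$upstream_bp,
                      pseudocount = config$pseudocount),
    config = config_to_list(config),
    files = file_checksums(files)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files["manifest"] <- p("manifest.json")

  invisible(list(
    annotated_peaks = annotated, peak_summary = peak_summary,
    overlaps = overlaps, binding_table = table, intersections = combos,
    expression = expr, deg_summary = deg_summary, pattern_ora = ora,
    functional_ora = fun_ora, gsea = gsea, motif_enrichment = motifs,
    recovery = recovery, files = files
  ))
}

#' Demo-sized simulation configuration
#'
#' The full study-sized defaults of [simulation_config()] scaled down (800
#' genes, 2000 peaks per factor) for fast end-to-end runs.
#'
#' @param seed Integer seed.
#' @return A `crossbind_sim_config`.
#' @export
demo_config <- function(seed) {
  cfg <- simulation_config(seed = seed, n_genes = 800)
  cfg$tfs$n_peaks <- 2000L
  cfg$n_sequence_peaks <- 1500L
  cfg
}

recovery_report <- function(config, peak_summary, deg_summary, top_cond,
                            ora, gsea) {
  rows <- map(seq_len(nrow(config$tfs)), function(i) {
    tf <- config$tfs$tf[i]
    s <- filter(peak_summary, .data$tf == !!tf)
    tibble(
      quantity = c(sprintf("intragenic_fraction_%s", tf),
                   sprintf("median_log2_fc_%s", tf)),
      planted = c(config$tfs$intragenic_fraction[i],
                  mixture_median(unlist(config$tfs$lfc_means[i]),
                                 unlist(config$tfs$lfc_weights[i]),
                                 config$tfs$zero_control[i])),
      measured = c(s$percent_intragenic / 100, s$median_log2_fc)
    )
  })
  ds <- filter(deg_summary, .data$condition == top_cond)
  planted_key <- planted_pattern_key(config)
  rows <- c(rows, list(
    tibble(quantity = "deg_fraction_top_condition",
           planted = config$deg_fraction,
           measured = ds$n_deg / ds$n_genes),
    tibble(quantity = "planted_pattern_is_top_ora_hit",
           planted = 1,
           measured = as.numeric(ora$term[1] == planted_key)),
    tibble(quantity = "planted_set_nes",
           planted = NA_real_,
           measured = gsea$nes[gsea$set_name == "PLANTED_PATTERN_SET"])
  ))
  bind_rows(rows)
}

# median of the planted mixture; with equal-weight symmetric components the
# component means stand in (exact for the single-component defaults)
mixture_median <- function(means, weights, truncated_at_zero) {
  m <- sum(means * weights / sum(weights))
  if (truncated_at_zero) max(m, 0) else m
}
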
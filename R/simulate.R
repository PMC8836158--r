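#' Simulation configuration with planted ground truth
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study conditions the package is built around: three transcription
#' factors with intragenic binding fractions 0.574 (AhR-like), 0.815
#' (COUP-TFII-like) and 0.764 (HNF4A-like), median log2 fold-changes +0.99,
#' -0.30 and +0.13, a near-zero control signal for the ligand-activated
#' AhR-like factor (so its enrichment is one-sided), an eight-dose
#' expression design, and a planted binding pattern (AhR increased,
#' COUP-TFII decreased, HNF4A increased) coupled to transcriptional
#' repression. One seed governs every draw; identical configs produce
#' byte-identical artifacts.
#'
#' @param seed Integer seed (required; keep below 2^31 - 10, since derived
#'   per-stage seeds add small offsets).
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Number of non-overlapping genes.
#' @param gene_length_range Uniform range of gene lengths (bp).
#' @param strand_prob Probability a gene is on the `+` strand.
#' @param upstream_bp Intragenic upstream window (bp), shared with the
#'   annotation stage of the pipeline.
#' @param pseudocount Pseudocount used when planting signals, matching the
#'   fold-change computation so planted log2 fold-changes are recovered
#'   exactly.
#' @param tfs Tibble with one row per factor: `tf`, `n_peaks`,
#'   `intragenic_fraction`, `lfc_means`, `lfc_sds`, `lfc_weights`
#'   (list-columns describing the log2 fold-change normal mixture) and
#'   `zero_control` (TRUE plants zero control signal and truncates the
#'   mixture at 0).
#' @param peak_width_range Uniform range of peak widths (bp).
#' @param control_signal_range Uniform range of control signal values for
#'   factors with a real control.
#' @param conditions Numeric dose (or time) labels; the last is the
#'   headline condition carrying the full planted effect.
#' @param deg_fraction Target fraction of genes differentially expressed at
#'   the headline condition.
#' @param planted_pattern Named character vector (one per factor, in `tfs`
#'   order) giving the binding pattern coupled to expression.
#' @param planted_effect_mean,planted_effect_sd Normal log2 fold-change
#'   effect for genes carrying the planted pattern (negative = repression).
#' @param random_deg_lfc_rate Rate of the exponential excess above the
#'   1.5-fold threshold for randomly chosen DEGs.
#' @param null_lfc_sd Log2 fold-change spread of unaffected genes.
#' @param p1t_slope,p1t_mid,p1t_noise_sd Logistic model of the posterior
#'   `p1t` as a function of `|log2_fc|`, plus Gaussian noise, clamped to
#'   `[0, 1]`.
#' @param condition_noise_sd Extra log2 fold-change noise at non-headline
#'   conditions.
#' @param n_gene_sets,gene_set_size Number and size of generated gene sets;
#'   the first set is enriched for the planted pattern.
#' @param planted_odds_ratio Sampling odds favouring planted-pattern genes
#'   in the first gene set.
#' @param seq_length Length of generated peak sequences (bp).
#' @param motif_target_rate,motif_background_rate Probability of planting a
#'   motif instance into a differential / non-differential peak sequence.
#' @param n_sequence_peaks Cap on the number of peak sequences generated.
#' @return A list of class `crossbind_sim_config`.
#' @export
simulation_config <- function(
    seed,
    n_chroms = 3, chrom_length = 3e7,
    n_genes = 1500, gene_length_range = c(2e3, 2e4), strand_prob = 0.5,
    upstream_bp = 10000, pseudocount = 1,
    tfs = NULL,
    peak_width_range = c(200, 400),
    control_signal_range = c(10, 100),
    conditions = c(0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30),
    deg_fraction = 0.3,
    planted_pattern = c(AhR = "increased", COUP_TFII = "decreased",
                        HNF4A = "increased"),
    planted_effect_mean = -1.5, planted_effect_sd = 0.4,
    random_deg_lfc_rate = 1 / 0.6, null_lfc_sd = 0.2,
    p1t_slope = 10, p1t_mid = 0.3, p1t_noise_sd = 0.02,
    condition_noise_sd = 0.05,
    n_gene_sets = 5, gene_set_size = 150, planted_odds_ratio = 8,
    seq_length = 200, motif_target_rate = 0.30,
    motif_background_rate = 0.05, n_sequence_peaks = 3000) {
  if (missing(seed)) abort("simulation_config() requires a seed.")
  if (seed >= 2^31 - 10) abort("Use a seed below 2^31 - 10.")
  tfs <- tfs %||% tibble(
    tf = CROSSBIND_TFS,
    n_peaks = 5000L,
    intragenic_fraction = c(0.574, 0.815, 0.764),
    lfc_means = list(0.99, -0.30, 0.13),
    lfc_sds = list(0.35, 0.70, 0.60),
    lfc_weights = list(1, 1, 1),
    zero_control = c(TRUE, FALSE, FALSE)
  )
  if (any(tfs$intragenic_fraction < 0 | tfs$intragenic_fraction > 1)) {
    abort("intragenic_fraction values must lie in [0, 1].")
  }
  if (deg_fraction < 0 || deg_fraction > 1) abort("deg_fraction must lie in [0, 1].")
  if (!identical(sort(names(planted_pattern)), sort(tfs$tf))) {
    abort("planted_pattern must name exactly the configured factors.")
  }
  cfg <- as.list(environment())
  class(cfg) <- "crossbind_sim_config"
  cfg
}

sim_seed <- function(config, stage) {
  offs <- c(annotation = 1L, peaks = 2L, expression = 3L,
            gene_sets = 4L, sequences = 5L)
  as.integer(config$seed) + offs[[stage]]
}

planted_pattern_key <- function(config) {
  paste(unname(config$planted_pattern[config$tfs$tf]), collapse = "/")
}

#' Simulate a gene annotation
#'
#' Places non-overlapping genes with mixed strands on `n_chroms`
#' chromosomes; inter-gene gaps are drawn exponentially and rescaled to fit
#' the chromosome. Deterministic per config seed.
#'
#' @param config A [simulation_config()].
#' @return A gene-model tibble as from [read_gtf()], with a `chrom_sizes`
#'   attribute.
#' @export
simulate_annotation <- function(config) {
  withr::with_seed(sim_seed(config, "annotation"), {
    n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    id_width <- max(4, nchar(as.character(config$n_genes)))
    next_id <- 1L
    out <- map(seq_len(config$n_chroms), function(ci) {
      n <- n_per[ci]
      if (n == 0) return(NULL)
      len <- round(runif(n, config$gene_length_range[1], config$gene_length_range[2]))
      slack <- config$chrom_length - sum(len)
      if (slack < (n + 1) * 100) {
        abort(sprintf("Genes cannot fit on %s: %d bp of gene in %d bp.",
                      chroms[ci], sum(len), config$chrom_length))
      }
      gaps <- rexp(n + 1)
      gaps <- floor(gaps / sum(gaps) * slack)
      starts <- cumsum(gaps[seq_len(n)] + c(0, len[-n]))
      ids <- sprintf(paste0("G%0", id_width, "d"),
                     seq.int(next_id, length.out = n))
      next_id <<- next_id + n
      tibble(
        gene_id = ids, chrom = chroms[ci],
        strand = ifelse(runif(n) < config$strand_prob, "+", "-"),
        start = as.integer(starts), end = as.integer(starts + len)
      )
    })
    genes <- add_tss_tes(bind_rows(out))
    chrom_sizes <- setNames(rep(config$chrom_length, config$n_chroms), chroms)
    validate_annotation(genes, chrom_sizes)
    attr(genes, "chrom_sizes") <- chrom_sizes
    genes
  })
}

rmix_norm <- function(n, means, sds, weights) {
  weights <- weights / sum(weights)
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  rnorm(n, mean = means[comp], sd = sds[comp])
}

#' Simulate peak sets with planted enrichment structure
#'
#' For each configured factor, peak centers are planted inside a random
#' gene's intragenic window with probability `intragenic_fraction` and in
#' intergenic space otherwise (rejection-sampled against all windows), so
#' the realized fraction matches the target up to binomial noise. Log2
#' fold-changes follow the configured normal mixture; treated and control
#' signals are constructed so that `(treated + pc) / (control + pc)`
#' reproduces the planted fold-change exactly. Factors flagged
#' `zero_control` get zero control signal and a mixture truncated at 0, so
#' no peak can classify as decreased.
#'
#' @param config A [simulation_config()].
#' @param annotation Gene models from [simulate_annotation()].
#' @return A peak tibble (all factors combined) with the [read_peaks()]
#'   columns plus `planted_log2_fc` and `planted_intragenic`.
#' @export
simulate_peaks <- function(config, annotation) {
  win <- gene_windows(annotation, config$upstream_bp)
  chrom_sizes <- attr(annotation, "chrom_sizes") %||%
    setNames(rep(config$chrom_length, config$n_chroms),
             sprintf("chr%d", seq_len(config$n_chroms)))
  win_gr <- GenomicRanges::GRanges(win$chrom,
                                   IRanges::IRanges(win$win_lo + 1L, win$win_hi + 1L))
  withr::with_seed(sim_seed(config, "peaks"), {
    all_peaks <- map(seq_len(nrow(config$tfs)), function(ti) {
      row <- config$tfs[ti, ]
      n <- row$n_peaks
      intra <- runif(n) < row$intragenic_fraction
      centers <- integer(n)
      if (any(intra)) {
        gi <- sample.int(nrow(win), sum(intra), replace = TRUE)
        centers[intra] <- as.integer(floor(runif(sum(intra), win$win_lo[gi],
                                                 win$win_hi[gi] + 1)))
        chrom <- character(n)
        chrom[intra] <- win$chrom[gi]
      } else {
        chrom <- character(n)
      }
      n_inter <- sum(!intra)
      if (n_inter > 0) {
        got <- 0L
        inter_chrom <- character(n_inter)
        inter_center <- integer(n_inter)
        while (got < n_inter) {
          m <- (n_inter - got) * 2L + 50L
          cand_chrom <- sample(names(chrom_sizes), m, replace = TRUE,
                               prob = chrom_sizes / sum(chrom_sizes))
          cand_center <- as.integer(floor(runif(m, 0, chrom_sizes[cand_chrom])))
          cand_gr <- GenomicRanges::GRanges(cand_chrom,
                                            IRanges::IRanges(cand_center + 1L, width = 1L))
          ok <- !IRanges::overlapsAny(cand_gr, win_gr)
          keep <- min(sum(ok), n_inter - got)
          if (keep > 0) {
            sel <- which(ok)[seq_len(keep)]
            inter_chrom[got + seq_len(keep)] <- cand_chrom[sel]
            inter_center[got + seq_len(keep)] <- cand_center[sel]
            got <- got + keep
          }
        }
        chrom[!intra] <- inter_chrom
        centers[!intra] <- inter_center
      }
      width <- round(runif(n, config$peak_width_range[1], config$peak_width_range[2]))
      start <- pmax(0L, as.integer(centers - floor(width / 2)))
      end <- as.integer(start + width)

      lfc <- rmix_norm(n, unlist(row$lfc_means), unlist(row$lfc_sds),
                       unlist(row$lfc_weights))
      pc <- config$pseudocount
      if (isTRUE(row$zero_control)) {
        while (any(lfc < 0)) {
          lfc[lfc < 0] <- rmix_norm(sum(lfc < 0), unlist(row$lfc_means),
                                    unlist(row$lfc_sds), unlist(row$lfc_weights))
        }
        control <- rep(0, n)
        treated <- pc * (2^lfc - 1)
      } else {
        control <- runif(n, config$control_signal_range[1],
                         config$control_signal_range[2])
        treated <- pmax(0, (control + pc) * 2^lfc - pc)
      }
      tibble(
        tf = row$tf, chrom = chrom, start = start, end = end,
        name = sprintf("pk_%s_%05d", row$tf, seq_len(n)),
        treated_signal = treated, control_signal = control,
        planted_log2_fc = lfc, planted_intragenic = intra
      )
    })
    bind_rows(all_peaks)
  })
}

direction_columns <- function(pattern, tf_levels) {
  parts <- strsplit(pattern, "/", fixed = TRUE)
  setNames(
    map(seq_along(tf_levels), ~ map_chr(parts, .x)),
    paste0("direction_", tf_levels)
  )
}

#' Simulate a gene binding-pattern table directly
#'
#' Draws one binding pattern per gene from a named frequency vector,
#' bypassing the peak layer — the fast route for calibration and power
#' studies of the pattern over-representation machinery.
#'
#' @param n_genes Number of genes.
#' @param pattern_freqs Named numeric vector: names are `/`-joined
#'   direction keys in `tf_levels` order, values are sampling weights.
#' @param seed Integer seed.
#' @param tf_levels Factor names (defaults to the package's canonical
#'   three).
#' @return A gene binding table in the [gene_binding_table()] layout.
#' @export
simulate_pattern_table <- function(n_genes, pattern_freqs, seed,
                                   tf_levels = CROSSBIND_TFS) {
  if (is.null(names(pattern_freqs)) || any(!nzchar(names(pattern_freqs)))) {
    abort("pattern_freqs must be a named vector of pattern keys.")
  }
  withr::with_seed(seed, {
    key <- sample(names(pattern_freqs), n_genes, replace = TRUE,
                  prob = pattern_freqs / sum(pattern_freqs))
    id_width <- max(4, nchar(as.character(n_genes)))
    tab <- tibble(gene_id = sprintf(paste0("G%0", id_width, "d"), seq_len(n_genes)))
    dirs <- direction_columns(key, tf_levels)
    for (nm in names(dirs)) tab[[nm]] <- dirs[[nm]]
    for (tf in tf_levels) {
      d <- tab[[paste0("direction_", tf)]]
      tab[[paste0("bound_", tf)]] <- d != "unbound"
      tab[[paste0("differential_", tf)]] <- d %in% c("increased", "decreased")
    }
    diff_cols <- paste0("differential_", tf_levels)
    tab$any_differential <- purrr::reduce(map(diff_cols, ~ tab[[.x]]), `|`)
    tab$pattern_key <- key
    attr(tab, "tf_levels") <- tf_levels
    tab
  })
}

#' Sample a target gene set enriched for one pattern
#'
#' Draws `n` genes without replacement, giving genes that carry `pattern`
#' `odds_ratio` times the sampling weight of other genes — the planted
#' enrichment recovered by [pattern_ora()].
#'
#' @param table A gene binding table.
#' @param pattern Pattern key to enrich.
#' @param odds_ratio Sampling odds for pattern carriers (1 = no enrichment).
#' @param n Target size.
#' @param seed Integer seed.
#' @return Character vector of sampled gene ids.
#' @export
sample_enriched_target <- function(table, pattern, odds_ratio, n, seed) {
  if (n > nrow(table)) abort("Target size exceeds the number of genes.")
  w <- ifelse(table$pattern_key == pattern, odds_ratio, 1)
  withr::with_seed(seed, sample(table$gene_id, n, prob = w))
}

p1t_model <- function(lfc, config, noise = TRUE) {
  p <- plogis(config$p1t_slope * (abs(lfc) - config$p1t_mid))
  if (noise && config$p1t_noise_sd > 0) {
    p <- p + rnorm(length(p), 0, config$p1t_noise_sd)
  }
  pmin(pmax(p, 0), 1)
}

#' Simulate a multi-condition expression table
#'
#' Genes carrying the planted binding pattern receive the planted (negative
#' by default) log2 fold-change effect at the headline condition; enough
#' additional random genes are induced or repressed to reach the target DEG
#' fraction; remaining genes get null noise. Effects scale with
#' log-condition toward the headline condition, and `p1t` follows the
#' logistic model of `|log2_fc|`.
#'
#' @param config A [simulation_config()].
#' @param pattern_table A gene binding table (from [gene_binding_table()] on
#'   simulated peaks, or [simulate_pattern_table()]).
#' @return An expression tibble with `gene_id`, `condition`, `fold_change`,
#'   `log2_fc`, `p1t` and the planting indicator `planted_effect`.
#' @export
simulate_expression <- function(config, pattern_table) {
  genes <- pattern_table$gene_id
  n <- length(genes)
  planted <- pattern_table$pattern_key == planted_pattern_key(config)
  withr::with_seed(sim_seed(config, "expression"), {
    target_deg <- round(config$deg_fraction * n)
    extra <- max(0, target_deg - sum(planted))
    candidates <- which(!planted)
    random_deg <- logical(n)
    if (extra > 0 && length(candidates) > 0) {
      random_deg[sample(candidates, min(extra, length(candidates)))] <- TRUE
    }
    lfc_top <- rnorm(n, 0, config$null_lfc_sd)
    lfc_top[planted] <- rnorm(sum(planted), config$planted_effect_mean,
                              config$planted_effect_sd)
    # the DEG thresholds are not reciprocal (1.5 up, 0.6 down), so the
    # minimum magnitude differs by sign
    sign_rd <- sample(c(-1, 1), sum(random_deg), replace = TRUE)
    base_mag <- ifelse(sign_rd > 0, log2(1.5), -log2(0.6))
    lfc_top[random_deg] <- sign_rd *
      (base_mag + rexp(sum(random_deg), rate = config$random_deg_lfc_rate))

    conds <- config$conditions
    mult <- if (length(conds) > 1) {
      lc <- log10(conds / min(conds))
      lc / max(lc)
    } else {
      1
    }
    rows <- map(seq_along(conds), function(ci) {
      top <- ci == length(conds)
      lfc <- lfc_top * mult[ci] +
        if (top) 0 else rnorm(n, 0, config$condition_noise_sd)
      tibble(
        gene_id = genes,
        condition = format(conds[ci], trim = TRUE),
        fold_change = 2^lfc,
        log2_fc = lfc,
        p1t = p1t_model(lfc, config, noise = TRUE),
        planted_effect = planted
      )
    })
    bind_rows(rows)
  })
}

#' Simulate gene-set collections with a planted pattern enrichment
#'
#' The first set oversamples genes carrying the planted binding pattern at
#' the configured odds ratio; the remaining sets are uniform draws.
#'
#' @param config A [simulation_config()].
#' @param pattern_table A gene binding table.
#' @return A gene-set tibble as from [read_gmt()].
#' @export
simulate_gene_sets <- function(config, pattern_table) {
  n <- nrow(pattern_table)
  if (config$gene_set_size > n) {
    abort(sprintf("gene_set_size (%d) exceeds the number of genes (%d).",
                  config$gene_set_size, n))
  }
  key <- planted_pattern_key(config)
  withr::with_seed(sim_seed(config, "gene_sets"), {
    sets <- map(seq_len(config$n_gene_sets), function(si) {
      if (si == 1) {
        w <- ifelse(pattern_table$pattern_key == key, config$planted_odds_ratio, 1)
        tibble(
          name = "PLANTED_PATTERN_SET",
          description = sprintf("odds %g for pattern %s", config$planted_odds_ratio, key),
          genes = list(sort(sample(pattern_table$gene_id, config$gene_set_size,
                                   prob = w)))
        )
      } else {
        tibble(
          name = sprintf("RANDOM_SET_%d", si),
          description = "uniform draw",
          genes = list(sort(sample(pattern_table$gene_id, config$gene_set_size)))
        )
      }
    })
    bind_rows(sets)
  })
}

#' Built-in position weight matrices for the simulator
#'
#' Three near-deterministic motifs (probability 0.97 on the consensus base)
#' in the spirit of the dioxin response element (GCGTG core) and two
#' nuclear-receptor direct repeats; purely synthetic definitions for
#' planting and recovery exercises, not curated biological models.
#'
#' @param threshold_frac Hit threshold as a fraction of the maximal score.
#' @return Named list of `crossbind_pwm` objects.
#' @export
default_pwms <- function(threshold_frac = 0.8) {
  from_consensus <- function(name, consensus, p = 0.97) {
    bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
    mat <- vapply(bases, function(b) {
      if (b == "N") rep(0.25, 4) else {
        col <- rep((1 - p) / 3, 4)
        col[match(b, DNA_BASES)] <- p
        col
      }
    }, numeric(4))
    new_pwm(name, mat, threshold_frac = threshold_frac)
  }
  list(
    DRE_like = from_consensus("DRE_like", "TNGCGTG"),
    DR1_like = from_consensus("DR1_like", "AGGTCAAAGGTCA"),
    COUP_like = from_consensus("COUP_like", "TGACCTTTGACCT")
  )
}

#' Simulate peak sequences with planted motif instances
#'
#' Generates a uniform random sequence per peak (capped at
#' `n_sequence_peaks`, sampled deterministically) and plants one instance
#' of the first default motif's consensus at a random position and strand:
#' with probability `motif_target_rate` into differentially enriched peaks
#' and `motif_background_rate` into the rest. Differential status is
#' derived from the planted signals with the config's pseudocount and the
#' standard thresholds.
#'
#' @param config A [simulation_config()].
#' @param peaks Peak tibble from [simulate_peaks()].
#' @return A named character vector of sequences with attribute
#'   `planted` (logical) and `differential` (logical), names = peak names.
#' @export
simulate_sequences <- function(config, peaks) {
  fc <- fold_change(peaks$treated_signal, peaks$control_signal,
                    config$pseudocount)
  differential <- status_of(fc, 1.5, 0.6) != "no_change"
  withr::with_seed(sim_seed(config, "sequences"), {
    keep <- if (nrow(peaks) > config$n_sequence_peaks) {
      sort(sample.int(nrow(peaks), config$n_sequence_peaks))
    } else {
      seq_len(nrow(peaks))
    }
    differential <- differential[keep]
    n <- length(keep)
    len <- config$seq_length
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    }, character(1))
    rate <- ifelse(differential, config$motif_target_rate,
                   config$motif_background_rate)
    plant <- runif(n) < rate
    motif <- default_pwms()[[1]]
    instance <- motif$consensus
    ns <- gregexpr("N", instance, fixed = TRUE)[[1]]
    for (i in which(plant)) {
      inst <- instance
      if (ns[1] != -1) {
        for (j in ns) substr(inst, j, j) <- sample(DNA_BASES, 1)
      }
      if (runif(1) < 0.5) inst <- revcomp(inst)
      at <- sample.int(len - nchar(inst) + 1, 1)
      substr(seqs[i], at, at + nchar(inst) - 1) <- inst
    }
    structure(setNames(seqs, peaks$name[keep]),
              planted = plant, differential = differential)
  })
}

#' Write a full synthetic study to disk
#'
#' Runs every generator stage and writes GTF annotation, per-factor BED
#' peak files, an expression TSV, a GMT gene-set collection, a FASTA of
#' peak sequences and a JSON manifest recording the seed, configuration
#' and md5 checksum of every artifact. Re-running with the same config
#' produces byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory artifacts (`annotation`,
#'   `peaks`, `pattern_table`, `expression`, `gene_sets`, `sequences`) and
#'   `files`, the named vector of written paths.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  annotation <- simulate_annotation(config)
  peaks <- simulate_peaks(config, annotation)
  write_gtf(annotation, p("annotation.gtf"))
  files <- c(annotation = p("annotation.gtf"))
  for (tf in config$tfs$tf) {
    f <- p(sprintf("peaks_%s.bed", tf))
    write_peaks_bed(filter(peaks, .data$tf == !!tf), f)
    files[paste0("peaks_", tf)] <- f
  }

  annotated <- annotate_peaks(peaks, annotation,
                              upstream_bp = config$upstream_bp,
                              pseudocount = config$pseudocount)
  pattern_table <- gene_binding_table(annotated, genes = annotation,
                                      tf_levels = config$tfs$tf)

  expression <- simulate_expression(config, pattern_table)
  readr::write_tsv(
    select(expression, "gene_id", "condition", "fold_change", "p1t"),
    p("expression.tsv"), progress = FALSE
  )
  files["expression"] <- p("expression.tsv")

  gene_sets <- simulate_gene_sets(config, pattern_table)
  write_gmt(gene_sets, p("gene_sets.gmt"))
  files["gene_sets"] <- p("gene_sets.gmt")

  sequences <- simulate_sequences(config, peaks)
  seq_lines <- as.vector(rbind(paste0(">", names(sequences)),
                               unname(sequences)))
  readr::write_lines(seq_lines, p("sequences.fa"))
  files["sequences"] <- p("sequences.fa")

  manifest <- list(
    tool = "crossbind", version = as.character(packageVersion("crossbind")),
    seed = config$seed,
    config = config_to_list(config),
    files = file_checksums(files)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files["manifest"] <- p("manifest.json")

  invisible(list(
    annotation = annotation, peaks = peaks, annotated_peaks = annotated,
    pattern_table = pattern_table, expression = expression,
    gene_sets = gene_sets, sequences = sequences, files = files
  ))
}

# md5 per artifact, keyed by file name so manifests from different
# directories stay comparable
file_checksums <- function(files) {
  as.list(setNames(unname(tools::md5sum(unname(files))),
                   basename(unname(files))))
}

config_to_list <- function(config) {
  cfg <- unclass(config)
  cfg$tfs <- lapply(seq_len(nrow(cfg$tfs)), function(i) {
    row <- as.list(cfg$tfs[i, ])
    row$lfc_means <- unlist(row$lfc_means)
    row$lfc_sds <- unlist(row$lfc_sds)
    row$lfc_weights <- unlist(row$lfc_weights)
    row
  })
  cfg
}
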
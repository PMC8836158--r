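#' Read gene models from a GTF file
#'
#' Parses an Ensembl-dialect GTF and returns one row per `gene` feature.
#' GTF coordinates are 1-based inclusive; internally every interval is
#' 0-based half-open, so `start = gtf_start - 1` and `end = gtf_end`.
#' The transcription start site (TSS) is the 5' terminus of the gene
#' (`start` on `+`, `end - 1` on `-`) and the TES is the opposite terminus,
#' both as 0-based positions.
#'
#' @param path Path to a GTF file.
#' @param chrom_sizes Optional named numeric vector of chromosome lengths
#'   (bp). When supplied, gene coordinates are validated against it and the
#'   vector is attached as the `chrom_sizes` attribute of the result.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `tes` (all coordinates 0-based half-open points).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines("chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id \"g1\";", gtf)
#' read_gtf(gtf)
#' @export
read_gtf <- function(path, chrom_sizes = NULL) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed GTF line %d in '%s': expected 9 tab-separated fields, found %d.",
      which(keep)[bad[1]], path, lengths(fields)[bad[1]]
    ))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0) abort(sprintf("No 'gene' features found in '%s'.", path))
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    abort(sprintf("GTF '%s' has gene features without a gene_id attribute.", path))
  }
  genes <- tibble(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (any(genes$strand == "*")) {
    abort("GTF gene features must have strand '+' or '-'.")
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0) {
    abort(sprintf(
      "Duplicate gene_id in '%s': %s", path,
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  genes <- add_tss_tes(genes)
  validate_annotation(genes, chrom_sizes)
  attr(genes, "chrom_sizes") <- chrom_sizes
  genes
}

add_tss_tes <- function(genes) {
  genes |>
    mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
      tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
    )
}

validate_annotation <- function(genes, chrom_sizes = NULL) {
  if (any(genes$start >= genes$end)) {
    abort("Gene annotation has start >= end; coordinates must be 0-based half-open.")
  }
  if (any(genes$tss == genes$tes)) {
    abort("Gene annotation has TSS == TES (zero-width transcribed region).")
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
    if (length(unknown) > 0) {
      abort(sprintf("Genes on chromosomes absent from chrom_sizes: %s",
                    paste(unknown, collapse = ", ")))
    }
    over <- genes$end > unname(chrom_sizes[genes$chrom]) | genes$start < 0
    if (any(over)) {
      abort(sprintf("Gene(s) outside chromosome bounds: %s",
                    paste(head(genes$gene_id[over], 5), collapse = ", ")))
    }
  }
  invisible(genes)
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gtf()]: converts internal 0-based half-open coordinates
#' back to 1-based inclusive GTF lines, one `gene` feature per row, sorted by
#' chromosome and start so output is deterministic.
#'
#' @param genes Tibble as returned by [read_gtf()] or [simulate_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  genes <- arrange(genes, .data$chrom, .data$start, .data$gene_id)
  lines <- sprintf(
    "%s\tcrossbind\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand, genes$gene_id
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a peak table (BED6+ / narrowPeak dialect)
#'
#' Reads tab-separated peak intervals with 0-based half-open coordinates (the
#' BED convention, kept unchanged internally). Treated and control signal
#' columns are located by index; the narrowPeak `signalValue` column (7) is
#' the default treated column. Records with `start >= end` are rejected with
#' a warning and counted in the `n_rejected` attribute.
#'
#' @param path Path to a BED-like file (no header).
#' @param tf_name Transcription-factor label stored in the `tf` column.
#' @param treated_col,control_col 1-based column indices of the treated and
#'   control signal. `control_col = NA` leaves control at `NA` (e.g. when a
#'   paired control file is supplied instead).
#' @param control_path Optional paired control peak file in the same dialect;
#'   its `treated_col` column is used as the control signal, matched to the
#'   main file by the BED name column (column 4).
#' @return A tibble with columns `tf`, `chrom`, `start`, `end`, `name`,
#'   `treated_signal`, `control_signal` and attribute `n_rejected`.
#' @export
read_peaks <- function(path, tf_name, treated_col = 7, control_col = 8,
                       control_path = NULL) {
  raw <- read_bedlike(path)
  if (nrow(raw) == 0) {
    out <- tibble(
      tf = character(), chrom = character(), start = integer(),
      end = integer(), name = character(),
      treated_signal = double(), control_signal = double()
    )
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  get_col <- function(df, idx, what) {
    if (is.na(idx)) return(rep(NA_real_, nrow(df)))
    if (idx > ncol(df)) {
      abort(sprintf("'%s' has %d columns; %s column %d requested.",
                    path, ncol(df), what, idx))
    }
    as.numeric(df[[idx]])
  }
  out <- tibble(
    tf = tf_name,
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    name = if (ncol(raw) >= 4) as.character(raw[[4]]) else NA_character_,
    treated_signal = get_col(raw, treated_col, "treated"),
    control_signal = get_col(raw, control_col, "control")
  )
  if (!is.null(control_path)) {
    ctrl <- read_bedlike(control_path)
    if (ncol(ctrl) < max(4, treated_col)) {
      abort(sprintf("Control file '%s' lacks a name or signal column.", control_path))
    }
    ctrl_sig <- setNames(as.numeric(ctrl[[treated_col]]), as.character(ctrl[[4]]))
    out$control_signal <- unname(ctrl_sig[out$name])
  }
  bad <- out$start >= out$end
  if (any(bad)) {
    warn(sprintf("%d record(s) in '%s' with start >= end were rejected.",
                 sum(bad), path))
    out <- out[!bad, , drop = FALSE]
  }
  attr(out, "n_rejected") <- sum(bad)
  out
}

read_bedlike <- function(path) {
  if (file.size(path) == 0) return(tibble())
  readr::read_tsv(path, col_names = FALSE, comment = "#",
                  show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Write peaks as a BED6+2 file
#'
#' Columns: chrom, start, end, name, score (0), strand (.), treated signal,
#' control signal. Rows are sorted by chromosome and start.
#'
#' @param peaks Peak tibble (see [read_peaks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  peaks <- arrange(peaks, .data$chrom, .data$start, .data$end, .data$name)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t%s",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   format_num(peaks$treated_signal),
                   format_num(peaks$control_signal))
  readr::write_lines(lines, path)
  invisible(path)
}

format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 10))
}

#' Read a gene-set collection (GMT)
#'
#' Each GMT line holds a set name, a description, and tab-separated member
#' gene identifiers. Duplicate members within a set are dropped.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `name`, `description` and list-column
#'   `genes` (character vectors of unique members).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("GMT file '%s' is empty.", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d in '%s' has fewer than 3 fields.", short[1], path))
  }
  sets <- tibble(
    name = map_chr(parts, 1),
    description = map_chr(parts, 2),
    genes = map(parts, ~ unique(.x[-(1:2)]))
  )
  if (anyDuplicated(sets$name)) {
    abort(sprintf("Duplicate gene-set name(s) in '%s'.", path))
  }
  if (any(lengths(sets$genes) == 0)) {
    abort(sprintf("Gene set(s) with no members in '%s'.", path))
  }
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Tibble with `name`, `description` (optional) and `genes`
#'   list-column, as from [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- if ("description" %in% names(sets)) sets$description else sets$name
  lines <- map_chr(seq_len(nrow(sets)), function(i) {
    paste(c(sets$name[i], desc[i], sets$genes[[i]]), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a per-gene, per-condition expression table
#'
#' Expects a TSV with columns `gene_id`, `condition`, `fold_change` and
#' `p1t` (the posterior probability of differential expression attached to
#' each gene/condition by the upstream expression analysis). Adds
#' `log2_fc = log2(fold_change)`.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with columns `gene_id`, `condition`, `fold_change`,
#'   `log2_fc`, `p1t`.
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("gene_id", "condition", "fold_change", "p1t")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("Expression table '%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  if (any(tab$fold_change <= 0)) {
    abort(sprintf("Expression table '%s' has nonpositive fold_change values.", path))
  }
  if (any(tab$p1t < 0 | tab$p1t > 1)) {
    abort(sprintf("Expression table '%s' has p1t values outside [0, 1].", path))
  }
  tab |>
    mutate(
      gene_id = as.character(.data$gene_id),
      condition = as.character(.data$condition),
      log2_fc = log2(.data$fold_change)
    ) |>
    select("gene_id", "condition", "fold_change", "log2_fc", "p1t")
}

#' Write a result table deterministically
#'
#' Writes a TSV with a fixed column order (as given) and rows sorted by all
#' non-list columns from left to right, so identical inputs always produce
#' byte-identical files.
#'
#' @param x A data frame; list columns are dropped with a message.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  is_list <- map_lgl(x, is.list)
  if (any(is_list)) {
    inform(sprintf("Dropping list column(s) for TSV output: %s",
                   paste(names(x)[is_list], collapse = ", ")))
    x <- x[!is_list]
  }
  x <- arrange(as_tibble(x), !!!rlang::syms(names(x)))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
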
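#' Compute treated/control fold-change for peaks
#'
#' Fold-change is `(treated + pseudocount) / (control + pseudocount)` on the
#' linear scale; the pseudocount guards against zero control signal. For a
#' ligand-activated factor assayed against an IgG/input control the control
#' signal is near zero, so fold-changes are bounded below by
#' `pseudocount / (control + pseudocount)` and enrichment is effectively
#' one-sided.
#'
#' @param peaks Peak tibble with `treated_signal` and `control_signal`
#'   columns (see [read_peaks()]).
#' @param pseudocount Nonnegative value added to both signals (default 1).
#' @return `peaks` with `fold_change` and `log2_fc` columns added.
#' @export
peak_fold_change <- function(peaks, pseudocount = 1) {
  fc <- fold_change(peaks$treated_signal, peaks$control_signal, pseudocount)
  mutate(peaks, fold_change = fc, log2_fc = log2(fc))
}

#' Fold-change of treated over control signal
#'
#' @param treated,control Nonnegative signal values (vectorized).
#' @param pseudocount Nonnegative value added to both; `control + pseudocount`
#'   must be positive.
#' @return `(treated + pseudocount) / (control + pseudocount)`.
#' @examples
#' fold_change(8, 4, pseudocount = 0) # 2
#' fold_change(3, 0, pseudocount = 0.5) # 7
#' @export
fold_change <- function(treated, control, pseudocount = 1) {
  if (any(is.na(treated)) || any(is.na(control))) {
    abort("Missing signal values; supply both treated and control signal.")
  }
  if (any(treated < 0) || any(control < 0)) {
    abort("Signal values must be nonnegative.")
  }
  if (length(pseudocount) != 1 || pseudocount < 0) {
    abort("pseudocount must be a single nonnegative number.")
  }
  if (any(control + pseudocount == 0)) {
    abort("control + pseudocount is zero; use a positive pseudocount.")
  }
  (treated + pseudocount) / (control + pseudocount)
}

#' Classify peaks as differentially enriched
#'
#' A peak is `increased` when its fold-change is at least `fc_up`,
#' `decreased` when at most `fc_down`, and `no_change` otherwise; both
#' boundaries are inclusive. The defaults (1.5 and 0.6) are reciprocal
#' 1.5-fold cutoffs (1/1.5 rounded to 0.6).
#'
#' @param peaks Peak tibble with a `fold_change` column, or a bare numeric
#'   vector of fold-changes.
#' @param fc_up,fc_down Inclusive thresholds; `fc_down < 1 < fc_up`.
#' @return The tibble with a `status` column added, or (for a numeric input)
#'   a character vector of statuses.
#' @examples
#' classify_differential(c(1.5, 0.6, 1.0))
#' @export
classify_differential <- function(peaks, fc_up = 1.5, fc_down = 0.6) {
  if (!(fc_down < 1 && 1 < fc_up)) abort("Require fc_down < 1 < fc_up.")
  if (is.numeric(peaks)) return(status_of(peaks, fc_up, fc_down))
  mutate(peaks, status = status_of(.data$fold_change, fc_up, fc_down))
}

status_of <- function(fc, fc_up, fc_down) {
  if (any(is.na(fc))) abort("Missing fold-change; run peak_fold_change() first.")
  if (any(fc <= 0)) abort("Fold-changes must be positive.")
  dplyr::case_when(
    fc >= fc_up ~ "increased",
    fc <= fc_down ~ "decreased",
    .default = "no_change"
  )
}

peak_centers <- function(peaks) {
  as.integer(floor((peaks$start + peaks$end) / 2))
}

# Strand-aware intragenic windows as 0-based inclusive point intervals:
# [TSS - upstream, TES] on the genomic axis.
gene_windows <- function(genes, upstream_bp) {
  genes |>
    mutate(
      win_lo = pmax(0L, ifelse(.data$strand == "+",
                               .data$start - as.integer(upstream_bp), .data$start)),
      win_hi = ifelse(.data$strand == "+",
                      .data$end - 1L, .data$end - 1L + as.integer(upstream_bp))
    )
}

# hits of peak centers in gene windows; one row per (peak, gene) pair
window_hits <- function(peaks, genes, upstream_bp) {
  win <- gene_windows(genes, upstream_bp)
  centers <- peak_centers(peaks)
  qry <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(centers + 1L, width = 1L))
  sbj <- GenomicRanges::GRanges(win$chrom,
                                IRanges::IRanges(win$win_lo + 1L, win$win_hi + 1L))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(qry, sbj))
  tibble(
    peak_idx = S4Vectors::queryHits(ov),
    gene_idx = S4Vectors::subjectHits(ov),
    center = centers[S4Vectors::queryHits(ov)],
    gene_id = win$gene_id[S4Vectors::subjectHits(ov)],
    tss = win$tss[S4Vectors::subjectHits(ov)]
  )
}

#' Classify peaks as intragenic or intergenic
#'
#' A peak is intragenic when its center, `floor((start + end) / 2)`, lies
#' within the window from `upstream_bp` upstream of any gene's TSS
#' (strand-aware) to the end of its transcribed region; otherwise it is
#' intergenic. Peaks on chromosomes absent from the annotation are kept and
#' classified intergenic, with a warning.
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble (see [read_gtf()]).
#' @param upstream_bp Upstream window size in bp (default 10000).
#' @return `peaks` with a `region` column (`"intragenic"`/`"intergenic"`).
#' @export
classify_region <- function(peaks, genes, upstream_bp = 10000) {
  unknown <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(unknown) > 0) {
    warn(sprintf("Peaks on chromosome(s) without annotation (kept, intergenic): %s",
                 paste(unknown, collapse = ", ")))
  }
  hits <- window_hits(peaks, genes, upstream_bp)
  mutate(peaks, region = ifelse(seq_len(nrow(peaks)) %in% hits$peak_idx,
                                "intragenic", "intergenic"))
}

#' Assign each intragenic peak to its closest gene
#'
#' Among genes whose intragenic window contains the peak center, the gene
#' with the smallest `|center - TSS|` wins; exact distance ties resolve to
#' the lexicographically smaller `gene_id`. Intergenic peaks get `NA`.
#'
#' @inheritParams classify_region
#' @return `peaks` with a `gene_id` column added (and `region` if absent).
#' @export
assign_closest_gene <- function(peaks, genes, upstream_bp = 10000) {
  if (!"region" %in% names(peaks)) {
    peaks <- classify_region(peaks, genes, upstream_bp)
  }
  hits <- window_hits(peaks, genes, upstream_bp)
  best <- hits |>
    mutate(dist = abs(.data$center - .data$tss)) |>
    arrange(.data$peak_idx, .data$dist, .data$gene_id) |>
    distinct(.data$peak_idx, .keep_all = TRUE)
  assigned <- rep(NA_character_, nrow(peaks))
  assigned[best$peak_idx] <- best$gene_id
  mutate(peaks, gene_id = assigned)
}

#' Annotate a peak table end to end
#'
#' Convenience wrapper: fold-change, differential status, region class and
#' closest-gene assignment in one call.
#'
#' @inheritParams classify_region
#' @inheritParams peak_fold_change
#' @inheritParams classify_differential
#' @return Fully annotated peak tibble.
#' @export
annotate_peaks <- function(peaks, genes, upstream_bp = 10000, pseudocount = 1,
                           fc_up = 1.5, fc_down = 0.6) {
  peaks |>
    peak_fold_change(pseudocount = pseudocount) |>
    classify_differential(fc_up = fc_up, fc_down = fc_down) |>
    assign_closest_gene(genes, upstream_bp = upstream_bp)
}

#' Overlap and center-distance summary between two peak sets
#'
#' A reference peak overlaps when its interval shares at least one bp with
#' any peak of the other set. The histogram bins the signed distance from
#' each reference peak center to the nearest other-set peak center on the
#' same chromosome (positive = other center downstream in genomic
#' coordinates); distances are clamped to `[-max_distance, max_distance]`.
#' When a reference center is equidistant from two other-set centers the
#' positive (downstream) one is taken.
#'
#' @param reference,other Peak tibbles; `reference` must be nonempty.
#' @param max_distance Clamp for center distances, bp.
#' @param bin_width Histogram bin width, bp.
#' @return A one-row tibble of class `crossbind_overlap` with columns
#'   `reference_tf`, `other_tf`, `n_reference`, `n_overlapping`, `percent`
#'   and list-column `distance_histogram` (tibble of `bin_lo`, `bin_hi`,
#'   `count` over center distances).
#' @export
overlap_summary <- function(reference, other, max_distance = 10000,
                            bin_width = 1000) {
  if (nrow(reference) == 0) abort("Reference peak set is empty.")
  if (nrow(other) == 0) abort("Other peak set is empty.")
  ref_gr <- GenomicRanges::GRanges(reference$chrom,
                                   IRanges::IRanges(reference$start + 1L, reference$end))
  oth_gr <- GenomicRanges::GRanges(other$chrom,
                                   IRanges::IRanges(other$start + 1L, other$end))
  n_overlapping <- sum(suppressWarnings(
    IRanges::overlapsAny(ref_gr, oth_gr, type = "any")
  ))

  dist <- nearest_center_distance(reference, other)
  dist <- dist[!is.na(dist)]
  dist <- pmin(pmax(dist, -max_distance), max_distance)
  breaks <- seq(-max_distance, max_distance, by = bin_width)
  if (breaks[length(breaks)] < max_distance) breaks <- c(breaks, max_distance)
  cnt <- graphics::hist(dist, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)$counts
  hist_tbl <- tibble(bin_lo = breaks[-length(breaks)],
                     bin_hi = breaks[-1], count = cnt)

  out <- tibble(
    reference_tf = first_or_na(reference$tf),
    other_tf = first_or_na(other$tf),
    n_reference = nrow(reference),
    n_overlapping = n_overlapping,
    percent = 100 * n_overlapping / nrow(reference),
    distance_histogram = list(hist_tbl)
  )
  class(out) <- c("crossbind_overlap", class(out))
  out
}

first_or_na <- function(x) {
  if (is.null(x) || length(x) == 0) NA_character_ else as.character(x[1])
}

# signed distance (other - reference) to nearest other-set center, same chrom;
# NA when the chromosome has no other-set peak
nearest_center_distance <- function(reference, other) {
  ref <- tibble(chrom = reference$chrom, center = peak_centers(reference),
                idx = seq_len(nrow(reference)))
  oth <- tibble(chrom = other$chrom, center = peak_centers(other))
  out <- rep(NA_real_, nrow(ref))
  for (ch in unique(ref$chrom)) {
    oc <- sort(oth$center[oth$chrom == ch])
    if (length(oc) == 0) next
    rc <- ref[ref$chrom == ch, ]
    pos <- findInterval(rc$center, oc)
    left <- ifelse(pos >= 1, oc[pmax(pos, 1)], NA_real_)
    right <- ifelse(pos < length(oc), oc[pmin(pos + 1, length(oc))], NA_real_)
    d_left <- rc$center - left   # >= 0
    d_right <- right - rc$center # >= 0
    use_right <- is.na(d_left) | (!is.na(d_right) & d_right <= d_left)
    out[rc$idx] <- ifelse(use_right, d_right, -d_left)
  }
  out
}

#' Summarize a peak table
#'
#' Per transcription factor (when a `tf` column is present): peak counts by
#' differential status and by region, the differentially-enriched fraction,
#' and the median log2 fold-change over all peaks (median of an even count
#' is the mean of the middle two).
#'
#' @param peaks Annotated peak tibble with at least `log2_fc` and `status`;
#'   `region` is summarized when present.
#' @return One row per factor with columns `n_peaks`, `n_increased`,
#'   `n_decreased`, `n_no_change`, `n_differential`, `percent_differential`,
#'   `median_log2_fc` and, when available, `n_intragenic`, `n_intergenic`,
#'   `percent_intragenic`.
#' @export
summarize_peaks <- function(peaks) {
  need <- setdiff(c("log2_fc", "status"), names(peaks))
  if (length(need) > 0) {
    abort(sprintf("summarize_peaks() needs column(s): %s",
                  paste(need, collapse = ", ")))
  }
  grouped <- if ("tf" %in% names(peaks)) group_by(peaks, .data$tf) else peaks
  out <- summarise(
    grouped,
    n_peaks = dplyr::n(),
    n_increased = sum(.data$status == "increased"),
    n_decreased = sum(.data$status == "decreased"),
    n_no_change = sum(.data$status == "no_change"),
    n_differential = .data$n_increased + .data$n_decreased,
    percent_differential = 100 * .data$n_differential / .data$n_peaks,
    median_log2_fc = median(.data$log2_fc),
    .groups = "drop"
  )
  if ("region" %in% names(peaks)) {
    reg <- summarise(
      if ("tf" %in% names(peaks)) group_by(peaks, .data$tf) else peaks,
      n_intragenic = sum(.data$region == "intragenic"),
      n_intergenic = sum(.data$region == "intergenic"),
      percent_intragenic = 100 * .data$n_intragenic / dplyr::n(),
      .groups = "drop"
    )
    out <- if ("tf" %in% names(out)) left_join(out, reg, by = "tf") else bind_cols(out, reg)
  }
  out
}
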
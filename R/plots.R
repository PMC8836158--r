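#' Plot an overlap center-distance histogram
#'
#' @param object A one-row [overlap_summary()] result (or several rows
#'   bound together, facetted by factor pair).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.crossbind_overlap <- function(object, ...) {
  hist_tbl <- object |>
    mutate(pair = paste(.data$reference_tf, "vs", .data$other_tf)) |>
    select("pair", "distance_histogram") |>
    tidyr::unnest("distance_histogram")
  ggplot2::ggplot(hist_tbl, ggplot2::aes(
    x = (.data$bin_lo + .data$bin_hi) / 2000, y = .data$count
  )) +
    ggplot2::geom_col(width = diff(range(hist_tbl$bin_lo)) /
                        (1000 * max(1, dplyr::n_distinct(hist_tbl$bin_lo)))) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pair)) +
    ggplot2::labs(x = "Distance between peak centers (kb)", y = "Peaks") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result as ranked bars
#'
#' @param object A `crossbind_enrichment` tibble ([pattern_ora()],
#'   [functional_ora()] or [motif_enrichment()]).
#' @param top Number of top terms to show.
#' @param ... Ignored.
#' @return A ggplot of `-log10(q)` per term.
#' @export
autoplot.crossbind_enrichment <- function(object, top = 15, ...) {
  d <- head(as_tibble(object), top) |>
    mutate(term = factor(.data$term, levels = rev(.data$term)),
           neglog_q = -log10(pmax(.data$q_value, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$neglog_q, y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10](q)), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a GSEA running-sum profile
#'
#' Recomputes the running sum for one gene set of a [gsea_preranked()]
#' result and draws the classic enrichment plot.
#'
#' @param object A `crossbind_gsea` result.
#' @param set_name Gene set to draw (default: the top row).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.crossbind_gsea <- function(object, set_name = NULL, ...) {
  set_name <- set_name %||% object$set_name[1]
  ranked <- attr(object, "ranked")
  sets <- attr(object, "gene_sets")
  weight <- attr(object, "params")$weight
  if (is.null(ranked) || is.null(sets)) {
    abort("This result no longer carries its ranked list.")
  }
  es <- enrichment_score(ranked, sets[[set_name]], weight = weight)
  rs <- es$running_sum
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$position, y = .data$running)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = filter(rs, .data$hit), sides = "b",
                      length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(
      title = set_name,
      subtitle = sprintf("ES = %.3f", es$es),
      x = "Rank in ordered gene list", y = "Running enrichment score"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-factor peak summaries
#'
#' @param summary Output of [summarize_peaks()] with a `tf` column.
#' @return A ggplot of peak counts by differential status per factor.
#' @export
plot_peak_summary <- function(summary) {
  d <- summary |>
    select("tf", "n_increased", "n_decreased", "n_no_change") |>
    tidyr::pivot_longer(-"tf", names_to = "status", values_to = "n") |>
    mutate(status = sub("^n_", "", .data$status))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tf, y = .data$n,
                                  fill = .data$status)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Peaks", fill = "Status") +
    ggplot2::theme_minimal()
}
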
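#' Call differentially expressed genes
#'
#' A gene/condition record is `induced` when `fold_change >= fc_up` and
#' `p1t >= p1t_min`, `repressed` when `fold_change <= fc_down` and
#' `p1t >= p1t_min`, otherwise `not_de`. All inequalities are non-strict.
#' `p1t` is the posterior probability of differential expression carried in
#' the input table; it is consumed as-is, never recomputed.
#'
#' @param expr Expression tibble (see [read_expression()]) with
#'   `fold_change` and `p1t` columns, or a bare numeric fold-change vector
#'   (then `p1t` must be supplied).
#' @param p1t Posterior probabilities, only for the vector form.
#' @param fc_up,fc_down Inclusive fold-change thresholds; `fc_down < 1 < fc_up`.
#' @param p1t_min Inclusive posterior threshold in `[0, 1]`.
#' @return The tibble with a `deg_status` column added, or a character
#'   vector for the vector form.
#' @examples
#' call_degs(c(1.6, 1.6, 0.5), p1t = c(0.9, 0.5, 0.85))
#' @export
call_degs <- function(expr, p1t = NULL, fc_up = 1.5, fc_down = 0.6,
                      p1t_min = 0.8) {
  if (!(fc_down < 1 && 1 < fc_up)) abort("Require fc_down < 1 < fc_up.")
  if (p1t_min < 0 || p1t_min > 1) abort("p1t_min must lie in [0, 1].")
  if (is.numeric(expr)) {
    if (is.null(p1t)) abort("Supply p1t alongside a fold-change vector.")
    return(deg_status_of(expr, p1t, fc_up, fc_down, p1t_min))
  }
  mutate(expr, deg_status = deg_status_of(.data$fold_change, .data$p1t,
                                          fc_up, fc_down, p1t_min))
}

deg_status_of <- function(fc, p1t, fc_up, fc_down, p1t_min) {
  if (any(fc <= 0)) abort("Fold-changes must be positive.")
  if (any(p1t < 0 | p1t > 1)) abort("p1t values must lie in [0, 1].")
  dplyr::case_when(
    fc >= fc_up & p1t >= p1t_min ~ "induced",
    fc <= fc_down & p1t >= p1t_min ~ "repressed",
    .default = "not_de"
  )
}

#' Summarize DEG calls per condition
#'
#' @param expr Expression tibble with `deg_status` (see [call_degs()]).
#' @param conditions Optional subset of conditions to report.
#' @return One row per condition: `n_genes`, `n_induced`, `n_repressed`,
#'   `n_deg` and `median_log2_fc_deg` (median log2 fold-change over DEGs
#'   only; `NA` when a condition has no DEG).
#' @export
summarize_degs <- function(expr, conditions = NULL) {
  if (!"deg_status" %in% names(expr)) {
    abort("Run call_degs() before summarize_degs().")
  }
  if (!is.null(conditions)) {
    missing <- setdiff(conditions, unique(expr$condition))
    if (length(missing) > 0) {
      abort(sprintf("No records for condition(s): %s",
                    paste(missing, collapse = ", ")))
    }
    expr <- filter(expr, .data$condition %in% conditions)
  }
  expr |>
    group_by(.data$condition) |>
    summarise(
      n_genes = dplyr::n(),
      n_induced = sum(.data$deg_status == "induced"),
      n_repressed = sum(.data$deg_status == "repressed"),
      n_deg = .data$n_induced + .data$n_repressed,
      median_log2_fc_deg = if (any(.data$deg_status != "not_de")) {
        median(.data$log2_fc[.data$deg_status != "not_de"])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}

#' Extract the DEG identifiers for one condition
#'
#' Genes absent at the condition are treated as not differentially
#' expressed rather than as an error, since expression tables are
#' condition-sparse.
#'
#' @param expr Expression tibble with `deg_status`.
#' @param condition Condition label to extract.
#' @return Character vector of DEG `gene_id`s (unique, sorted).
#' @export
deg_genes <- function(expr, condition) {
  cond <- condition
  sort(unique(expr$gene_id[expr$condition == cond & expr$deg_status != "not_de"]))
}
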
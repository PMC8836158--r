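#' Tidy a GSEA result
#'
#' @param x A `crossbind_gsea` result.
#' @param ... Ignored.
#' @return A plain tibble of the per-set statistics with `n_leading_edge`
#'   in place of the leading-edge list.
#' @export
tidy.crossbind_gsea <- function(x, ...) {
  as_tibble(x) |>
    mutate(n_leading_edge = lengths(.data$leading_edge)) |>
    select("set_name", "size", "es", "nes", "nominal_p", "q_value",
           "n_leading_edge")
}

#' One-row summary of a GSEA run
#'
#' @param x A `crossbind_gsea` result.
#' @param alpha Significance threshold on `q_value`.
#' @param ... Ignored.
#' @return A one-row tibble: number of sets, permutations, seed, and the
#'   number of sets at `q_value <= alpha`.
#' @export
glance.crossbind_gsea <- function(x, alpha = 0.05, ...) {
  params <- attr(x, "params")
  tibble(
    n_sets = nrow(x),
    n_permutations = params$n_permutations,
    seed = params$seed,
    weight = params$weight,
    n_significant = sum(x$q_value <= alpha)
  )
}

#' Tidy an enrichment result
#'
#' @param x A `crossbind_enrichment` tibble.
#' @param ... Ignored.
#' @return The underlying tibble, class attributes dropped.
#' @export
tidy.crossbind_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of an enrichment analysis
#'
#' @param x A `crossbind_enrichment` tibble.
#' @param alpha Significance threshold on `q_value`.
#' @param ... Ignored.
#' @return A one-row tibble with term counts and the top term.
#' @export
glance.crossbind_enrichment <- function(x, alpha = 0.05, ...) {
  tibble(
    n_terms = nrow(x),
    n_significant = sum(x$q_value <= alpha),
    top_term = x$term[1],
    top_q = x$q_value[1]
  )
}
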
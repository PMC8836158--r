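#' Gene-level binding table across transcription factors
#'
#' For every gene and factor: `bound` is TRUE when the gene has at least one
#' intragenic peak of that factor; `direction` is the differential status of
#' the gene's intragenic peak with the largest `|log2_fc|` for that factor
#' (`unbound` when there is no peak), with exact `|log2_fc|` ties resolving
#' to `increased`; `differential` is TRUE when at least one of the gene's
#' intragenic peaks for that factor is differentially enriched. The
#' `pattern_key` joins the per-factor directions with `/` in `tf_levels`
#' order.
#'
#' @param peaks Annotated peak tibble (see [annotate_peaks()]) for all
#'   factors, with `tf`, `gene_id`, `status`, `log2_fc` columns; intergenic
#'   peaks (`gene_id` `NA`) are ignored.
#' @param genes Optional gene-model tibble; when given, every annotated gene
#'   gets a row (all-`unbound` when nothing binds it).
#' @param tf_levels Factor order for the pattern key; defaults to the sorted
#'   factors observed in `peaks`.
#' @return A tibble with one row per gene: `gene_id`, `bound_<tf>`,
#'   `direction_<tf>`, `differential_<tf>` for each factor, plus
#'   `any_differential` and `pattern_key`.
#' @export
gene_binding_table <- function(peaks, genes = NULL, tf_levels = NULL) {
  need <- setdiff(c("tf", "gene_id", "status", "log2_fc"), names(peaks))
  if (length(need) > 0) {
    abort(sprintf("gene_binding_table() needs peak column(s): %s",
                  paste(need, collapse = ", ")))
  }
  tf_levels <- tf_levels %||% sort(unique(peaks$tf))
  bound <- peaks |>
    filter(!is.na(.data$gene_id), .data$tf %in% tf_levels) |>
    mutate(status = factor(.data$status, levels = STATUS_LEVELS)) |>
    group_by(.data$gene_id, .data$tf) |>
    arrange(desc(abs(.data$log2_fc)), .data$status, .by_group = TRUE) |>
    summarise(
      direction = as.character(first(.data$status)),
      differential = any(.data$status != "no_change"),
      .groups = "drop"
    )
  gene_ids <- sort(unique(c(bound$gene_id, if (!is.null(genes)) genes$gene_id)))
  grid <- tidyr::expand_grid(gene_id = gene_ids, tf = tf_levels)
  long <- grid |>
    left_join(bound, by = c("gene_id", "tf")) |>
    mutate(
      bound = !is.na(.data$direction),
      direction = ifelse(.data$bound, .data$direction, "unbound"),
      differential = ifelse(.data$bound, .data$differential, FALSE)
    )
  wide <- long |>
    tidyr::pivot_wider(
      id_cols = "gene_id", names_from = "tf",
      values_from = c("bound", "direction", "differential"),
      names_glue = "{.value}_{tf}"
    )
  dir_cols <- paste0("direction_", tf_levels)
  diff_cols <- paste0("differential_", tf_levels)
  wide |>
    mutate(
      any_differential = purrr::reduce(map(diff_cols, ~ wide[[.x]]), `|`),
      pattern_key = purrr::pmap_chr(wide[dir_cols], ~ paste(..., sep = "/"))
    ) |>
    structure(tf_levels = tf_levels)
}

table_tf_levels <- function(table) {
  lv <- attr(table, "tf_levels")
  lv %||% sub("^direction_", "", grep("^direction_", names(table), value = TRUE))
}

#' Gene counts per transcription-factor combination
#'
#' For each nonempty combination of factors (7 for three factors), counts
#' genes bound by exactly that combination, and among them the genes where
#' at least one member factor has a differentially enriched peak — the
#' co-regulation rule under which a change in binding of a single factor
#' suffices.
#'
#' @param table Gene binding table from [gene_binding_table()].
#' @return A tibble with one row per combination: `combination` (factor
#'   names joined by `+`), `n_tfs`, `n_bound`, `n_with_differential`.
#' @export
intersection_counts <- function(table) {
  if (nrow(table) == 0) abort("Gene binding table is empty.")
  tfs <- table_tf_levels(table)
  bound_mat <- as.matrix(table[paste0("bound_", tfs)])
  diff_mat <- as.matrix(table[paste0("differential_", tfs)])
  combos <- tidyr::expand_grid(!!!setNames(rep(list(c(TRUE, FALSE)), length(tfs)), tfs)) |>
    filter(rowSums(across(everything())) > 0)
  out <- map(seq_len(nrow(combos)), function(i) {
    member <- unlist(combos[i, ])
    exact <- rowSums(bound_mat == matrix(member, nrow(table), length(tfs),
                                         byrow = TRUE)) == length(tfs)
    any_diff <- rowSums(diff_mat[, member, drop = FALSE]) > 0
    tibble(
      combination = paste(tfs[member], collapse = "+"),
      n_tfs = sum(member),
      n_bound = sum(exact),
      n_with_differential = sum(exact & any_diff)
    )
  })
  bind_rows(out) |> arrange(.data$n_tfs, .data$combination)
}

#' One-sided Fisher's exact test for over-representation
#'
#' The upper hypergeometric tail `P(X >= k)` where `X` counts category
#' members in a sample of `n` from a universe of `N` containing `K`
#' category members. Exact (via the hypergeometric distribution), not
#' approximated. Vectorized over its arguments.
#'
#' @param k Observed overlap count.
#' @param n Sample (target set) size.
#' @param K Category size in the universe.
#' @param N Universe size.
#' @return The p-value(s) `P(X >= k)`.
#' @examples
#' fisher_exact_greater(4, 4, 5, 10) # 5 / choose(10, 4)
#' @export
fisher_exact_greater <- function(k, n, K, N) {
  args <- vctrs_recycle(k = k, n = n, K = K, N = N)
  with(args, {
    if (any(c(k, n, K, N) < 0) || any(k > pmin(n, K)) || any(n > N) || any(K > N)) {
      abort("Inconsistent contingency counts: need k <= min(n, K), n <= N, K <= N.")
    }
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  })
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  bad <- lengths(xs) != n & lengths(xs) != 1
  if (any(bad)) abort("Arguments must have length 1 or a common length.")
  lapply(xs, rep_len, n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, mapped back to input order.
#'
#' @param p P-values in `(0, 1]`.
#' @return Adjusted p-values (q-values), same order as the input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Binding-pattern over-representation analysis
#'
#' Tests whether each observed binding pattern is over-represented in a
#' target gene set relative to a reference universe, using the one-sided
#' Fisher's exact test with Benjamini-Hochberg correction across all tested
#' patterns. For each pattern: `k` = target genes with the pattern, `K` =
#' reference genes with it, `n` = target size, `N` = reference size.
#' Reference genes missing from the binding table count as unbound for
#' every factor.
#'
#' @param table Gene binding table from [gene_binding_table()].
#' @param target_genes Character vector of target gene ids (e.g. the DEGs of
#'   one gene set); must be a subset of `reference_genes`.
#' @param reference_genes Character vector, the reference universe (e.g. all
#'   DEGs at the tested condition).
#' @param collapse_unbound When TRUE (default), `unbound` collapses into
#'   `no_change` so patterns range over increased/decreased/no-change only;
#'   when FALSE, unbound is kept as its own level.
#' @return A tibble of class `crossbind_enrichment`, sorted by p-value then
#'   pattern, with columns `term`, `k`, `n`, `K`, `N`, `odds_ratio`,
#'   `p_value`, `q_value`.
#' @export
pattern_ora <- function(table, target_genes, reference_genes,
                        collapse_unbound = TRUE) {
  target_genes <- unique(as.character(target_genes))
  reference_genes <- unique(as.character(reference_genes))
  stray <- setdiff(target_genes, reference_genes)
  if (length(stray) > 0) {
    abort(sprintf(
      "Target genes absent from the reference universe (%d): %s",
      length(stray), paste(head(stray, 10), collapse = ", ")
    ))
  }
  patterns <- gene_patterns(table, reference_genes, collapse_unbound)
  run_ora(patterns$pattern[match(target_genes, patterns$gene_id)],
          patterns$pattern)
}

gene_patterns <- function(table, reference_genes, collapse_unbound) {
  tfs <- table_tf_levels(table)
  idx <- match(reference_genes, table$gene_id)
  dirs <- map(paste0("direction_", tfs), function(col) {
    d <- rep("unbound", length(reference_genes))
    hit <- !is.na(idx)
    d[hit] <- table[[col]][idx[hit]]
    if (collapse_unbound) d[d == "unbound"] <- "no_change"
    d
  })
  tibble(gene_id = reference_genes,
         pattern = do.call(paste, c(dirs, sep = "/")))
}

run_ora <- function(target_terms, reference_terms) {
  n <- length(target_terms)
  N <- length(reference_terms)
  K_tab <- table(reference_terms)
  k_tab <- table(factor(target_terms, levels = names(K_tab)))
  res <- tibble(
    term = names(K_tab),
    k = as.integer(k_tab),
    n = n,
    K = as.integer(K_tab),
    N = N
  ) |>
    mutate(
      odds_ratio = (.data$k * (.data$N - .data$K - .data$n + .data$k)) /
        ((.data$n - .data$k) * (.data$K - .data$k)),
      p_value = fisher_exact_greater(.data$k, .data$n, .data$K, .data$N),
      q_value = bh_fdr(.data$p_value)
    ) |>
    arrange(.data$p_value, .data$term)
  class(res) <- c("crossbind_enrichment", class(res))
  res
}

#' Functional over-representation of a gene list against gene sets
#'
#' Hypergeometric over-representation (one-sided Fisher) of a DEG list in
#' each gene set of a collection, against a reference universe, with
#' Benjamini-Hochberg correction across terms. Terms with zero overlap are
#' retained with `p = 1`. Set members outside the universe are ignored.
#'
#' @param degs Character vector of differentially expressed gene ids; must
#'   be a subset of `universe`.
#' @param gene_sets Gene-set tibble from [read_gmt()] (columns `name`,
#'   `genes`), or a named list of character vectors.
#' @param universe Character vector, the reference gene universe.
#' @return A `crossbind_enrichment` tibble as in [pattern_ora()].
#' @export
functional_ora <- function(degs, gene_sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("The reference universe is empty.")
  degs <- unique(as.character(degs))
  stray <- setdiff(degs, universe)
  if (length(stray) > 0) {
    abort(sprintf("DEGs absent from the universe (%d): %s",
                  length(stray), paste(head(stray, 10), collapse = ", ")))
  }
  sets <- as_gene_set_list(gene_sets)
  res <- imap(sets, function(members, nm) {
    members <- intersect(unique(members), universe)
    tibble(term = nm, k = length(intersect(members, degs)),
           n = length(degs), K = length(members), N = length(universe))
  }) |>
    bind_rows() |>
    mutate(
      odds_ratio = (.data$k * (.data$N - .data$K - .data$n + .data$k)) /
        ((.data$n - .data$k) * (.data$K - .data$k)),
      p_value = fisher_exact_greater(.data$k, .data$n, .data$K, .data$N),
      q_value = bh_fdr(.data$p_value)
    ) |>
    arrange(.data$p_value, .data$term)
  class(res) <- c("crossbind_enrichment", class(res))
  res
}

as_gene_set_list <- function(gene_sets) {
  if (is.data.frame(gene_sets)) {
    sets <- setNames(gene_sets$genes, gene_sets$name)
  } else if (is.list(gene_sets)) {
    sets <- gene_sets
  } else {
    abort("gene_sets must be a tibble from read_gmt() or a named list.")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("Every gene set needs a name.")
  }
  sets
}
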
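#' Build a ranked gene list from an expression table
#'
#' Orders genes by decreasing log2 fold-change (induction to repression) for
#' one condition. Ties in the score keep their input order (stable sort) and
#' are reported with a message, since tie order affects the running sum.
#'
#' @param expr Expression tibble (see [read_expression()]).
#' @param condition Condition label to rank; `NULL` uses the whole table
#'   (which must then contain one record per gene).
#' @return A tibble with `gene_id` and `score`, sorted by decreasing score.
#' @export
rank_genes <- function(expr, condition = NULL) {
  if (!is.null(condition)) {
    cond <- condition
    expr <- filter(expr, .data$condition == cond)
  }
  if (anyDuplicated(expr$gene_id)) {
    abort("Ranked list would contain duplicate gene ids; filter to one condition.")
  }
  if (nrow(expr) == 0) abort("No expression records to rank.")
  ranked <- expr |>
    mutate(score = .data$log2_fc) |>
    arrange(desc(.data$score)) |>
    select("gene_id", "score")
  n_tied <- sum(duplicated(ranked$score))
  if (n_tied > 0) {
    inform(sprintf("%d tied ranking score(s); ties keep stable input order.", n_tied))
  }
  ranked
}

validate_ranked <- function(ranked) {
  if (!all(c("gene_id", "score") %in% names(ranked))) {
    abort("A ranked list needs columns gene_id and score.")
  }
  if (anyDuplicated(ranked$gene_id)) abort("Ranked list has duplicate gene ids.")
  if (any(!is.finite(ranked$score))) abort("Ranking scores must be finite.")
  if (is.unsorted(rev(ranked$score))) {
    abort("Ranked list must be sorted by decreasing score.")
  }
  invisible(ranked)
}

# Core running-sum statistic. pos: sorted 1-based hit positions in the
# ranked list; w: weights |score|^weight at those positions. The sum gains
# w_i / sum(w) at each hit and loses 1 / (N - Nh) at each miss; the ES is
# the deviation of largest magnitude (positive wins exact magnitude ties).
es_stat <- function(n, pos, w) {
  k <- length(pos)
  if (k == 0) abort("No gene-set member present in the ranked list.")
  sw <- sum(w)
  if (sw == 0) { w <- rep(1, k); sw <- k } # all-zero scores fall back to hit counts
  hit_cum <- cumsum(w) / sw
  if (k == n) {
    return(list(es = 1, peak = n, tops = hit_cum, bottoms = c(0, hit_cum[-k])))
  }
  miss <- 1 / (n - k)
  drop <- (pos - seq_len(k)) * miss
  tops <- hit_cum - drop        # value just after each hit
  bottoms <- c(0, hit_cum[-k]) - drop # value just before each hit
  i_top <- which.max(tops)
  i_bot <- which.min(bottoms)
  # positive deviation wins magnitude ties (tolerance absorbs float error in
  # the rational step sums)
  if (tops[i_top] >= -bottoms[i_bot] - 1e-12) {
    list(es = tops[i_top], peak = pos[i_top], tops = tops, bottoms = bottoms)
  } else {
    list(es = bottoms[i_bot], peak = pos[i_bot] - 1L, tops = tops, bottoms = bottoms)
  }
}

#' Weighted running-sum enrichment score
#'
#' The running sum walks the ranked list from top to bottom, stepping up by
#' `|score|^weight / sum(|score_hits|^weight)` at gene-set members and down
#' by `1 / (N - Nh)` at non-members; the enrichment score (ES) is the signed
#' deviation of largest magnitude. With `weight = 0` this is the classic
#' Kolmogorov-Smirnov running-sum statistic.
#'
#' @param ranked Ranked list tibble (see [rank_genes()]).
#' @param gene_set Character vector of member gene ids (or a one-row slice
#'   of a [read_gmt()] tibble).
#' @param weight Exponent on `|score|` for hit increments (default 1, the
#'   weighted form).
#' @return A list of class `crossbind_es` with elements `es`, `peak` (the
#'   1-based position of the extreme deviation) and `running_sum`, a tibble
#'   with one row per list position (`position`, `gene_id`, `hit`,
#'   `running`).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  validate_ranked(ranked)
  members <- gene_set_members(gene_set)
  n <- nrow(ranked)
  if (length(members) > n) {
    abort("Gene set is larger than the ranked list.")
  }
  pos <- sort(which(ranked$gene_id %in% members))
  stat <- es_stat(n, pos, abs(ranked$score[pos])^weight)
  hit <- seq_len(n) %in% pos
  steps <- rep(if (n > length(pos)) -1 / (n - length(pos)) else 0, n)
  w <- abs(ranked$score[pos])^weight
  if (sum(w) == 0) w <- rep(1, length(pos))
  steps[pos] <- w / sum(w)
  out <- list(
    es = stat$es,
    peak = stat$peak,
    running_sum = tibble(
      position = seq_len(n), gene_id = ranked$gene_id,
      hit = hit, running = cumsum(steps)
    )
  )
  class(out) <- "crossbind_es"
  out
}

gene_set_members <- function(gene_set) {
  if (is.data.frame(gene_set)) {
    if (nrow(gene_set) != 1) abort("Pass a single gene set (one row).")
    gene_set <- gene_set$genes[[1]]
  }
  unique(as.character(gene_set))
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted running-sum enrichment score for each gene set,
#' builds a null by gene-label permutation (random member positions of the
#' same set size), and reports the normalized enrichment score
#' `NES = ES / mean(|null ES| of matching sign)`, the nominal p-value (the
#' fraction of same-sign null ES at least as extreme), and a sign-stratified
#' FDR q-value computed on the pooled normalized null. Results are
#' deterministic given the seed.
#'
#' @param ranked Ranked list tibble (see [rank_genes()]).
#' @param gene_sets Gene-set tibble from [read_gmt()] or a named list of
#'   character vectors. Members absent from the ranked list are ignored;
#'   sets with no member present, or more members than the list holds, are
#'   an error.
#' @param n_permutations Number of permutations (at least 100; default 1000).
#' @param seed Integer seed; required, so runs are reproducible.
#' @param weight Running-sum exponent, as in [enrichment_score()].
#' @return A tibble of class `crossbind_gsea`, sorted by `q_value` then
#'   `nominal_p`, with columns `set_name`, `size`, `es`, `nes`, `nominal_p`,
#'   `q_value` and list-column `leading_edge` (members at or before the ES
#'   peak for positive ES, at or after it for negative ES). Attributes keep
#'   the call parameters and the ranked list for plotting.
#' @export
gsea_preranked <- function(ranked, gene_sets, n_permutations = 1000, seed,
                           weight = 1) {
  validate_ranked(ranked)
  if (missing(seed)) abort("gsea_preranked() requires an explicit seed.")
  if (n_permutations < 100) abort("Use at least 100 permutations.")
  sets <- as_gene_set_list(gene_sets)
  n <- nrow(ranked)
  too_big <- names(sets)[lengths(map(sets, unique)) > n]
  if (length(too_big) > 0) {
    abort(sprintf("Gene set(s) larger than the ranked list: %s",
                  paste(too_big, collapse = ", ")))
  }
  pos_list <- map(sets, ~ sort(which(ranked$gene_id %in% .x)))
  absent <- names(sets)[lengths(pos_list) == 0]
  if (length(absent) > 0) {
    abort(sprintf("Gene set(s) with no member in the ranked list: %s",
                  paste(absent, collapse = ", ")))
  }
  aw <- abs(ranked$score)^weight

  obs <- map(pos_list, ~ es_stat(n, .x, aw[.x]))
  sizes <- lengths(pos_list)

  null_es <- withr::with_seed(seed, {
    map(sort(unique(sizes)), function(k) {
      vapply(seq_len(n_permutations), function(b) {
        p <- sort(sample.int(n, k))
        es_stat(n, p, aw[p])$es
      }, numeric(1))
    }) |> setNames(as.character(sort(unique(sizes))))
  })

  per_set <- imap(sets, function(members, nm) {
    stat <- obs[[nm]]
    nulls <- null_es[[as.character(sizes[[nm]])]]
    mean_pos <- mean(nulls[nulls > 0])
    mean_neg <- mean(abs(nulls[nulls < 0]))
    nes <- if (stat$es >= 0) stat$es / mean_pos else stat$es / mean_neg
    same <- if (stat$es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    nominal_p <- if (length(same) == 0) 1 else mean(abs(same) >= abs(stat$es))
    null_nes <- ifelse(nulls >= 0, nulls / mean_pos, nulls / mean_neg)
    pos <- pos_list[[nm]]
    lead <- if (stat$es >= 0) pos[pos <= stat$peak] else pos[pos > stat$peak]
    tibble(
      set_name = nm, size = sizes[[nm]], es = stat$es, nes = nes,
      nominal_p = nominal_p,
      leading_edge = list(ranked$gene_id[lead]),
      null_nes = list(null_nes)
    )
  }) |> bind_rows()

  res <- mutate(per_set, q_value = gsea_fdr(.data$nes, per_set$null_nes)) |>
    select("set_name", "size", "es", "nes", "nominal_p", "q_value",
           "leading_edge") |>
    arrange(.data$q_value, .data$nominal_p, .data$set_name)
  attr(res, "ranked") <- ranked
  attr(res, "gene_sets") <- sets
  attr(res, "params") <- list(n_permutations = n_permutations, seed = seed,
                              weight = weight)
  class(res) <- c("crossbind_gsea", class(res))
  res
}

# Sign-stratified FDR on normalized scores: for each observed NES, the
# fraction of pooled same-sign null NES at least as extreme divided by the
# fraction of observed same-sign NES at least as extreme, capped at 1 and
# made monotone in |NES| within each sign.
gsea_fdr <- function(obs_nes, null_nes_list) {
  pool <- unlist(null_nes_list)
  q <- vapply(obs_nes, function(x) {
    if (x >= 0) {
      null_frac <- safe_frac(sum(pool >= x), sum(pool >= 0))
      obs_frac <- safe_frac(sum(obs_nes >= x), sum(obs_nes >= 0))
    } else {
      null_frac <- safe_frac(sum(pool <= x), sum(pool < 0))
      obs_frac <- safe_frac(sum(obs_nes <= x), sum(obs_nes < 0))
    }
    if (obs_frac == 0) return(1)
    min(1, null_frac / obs_frac)
  }, numeric(1))
  # enforce monotonicity: a more extreme NES never gets a larger q
  for (sgn in c(1, -1)) {
    idx <- which(if (sgn > 0) obs_nes >= 0 else obs_nes < 0)
    if (length(idx) > 1) {
      ord <- idx[order(abs(obs_nes[idx]), decreasing = TRUE)]
      q[ord] <- cummax(q[ord])
    }
  }
  q
}

safe_frac <- function(num, den) if (den == 0) 0 else num / den
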
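DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Columns are motif positions; rows are A, C, G, T. Counts or frequencies
#' are normalized so each position sums to 1. Scores are log2-odds against
#' the background base frequencies, with probabilities floored at 1e-4
#' before taking logs so absent bases score finitely. The default hit
#' threshold is `threshold_frac` times the maximal achievable log-odds
#' score.
#'
#' @param name Motif name.
#' @param matrix Numeric 4 x W matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param background Background base frequencies (length 4, summing to 1).
#' @param threshold_frac Fraction of the maximal score used as the hit
#'   threshold (default 0.8).
#' @return An object of class `crossbind_pwm` with elements `name`, `prob`,
#'   `log_odds`, `background`, `width`, `max_score`, `score_threshold`,
#'   `consensus`.
#' @export
new_pwm <- function(name, matrix, background = rep(0.25, 4),
                    threshold_frac = 0.8) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) abort("A PWM needs 4 rows (A, C, G, T).")
  if (any(matrix < 0)) abort("PWM entries must be nonnegative.")
  if (any(colSums(matrix) == 0)) abort("Every PWM position needs mass.")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    abort("background must be 4 positive frequencies summing to 1.")
  }
  prob <- sweep(matrix, 2, colSums(matrix), "/")
  rownames(prob) <- DNA_BASES
  if (max(abs(colSums(prob) - 1)) > 1e-9) abort("PWM columns failed to normalize.")
  log_odds <- log2(pmax(prob, 1e-4) / background)
  max_score <- sum(apply(log_odds, 2, max))
  structure(
    list(
      name = name, prob = prob, log_odds = log_odds,
      background = setNames(background, DNA_BASES),
      width = ncol(prob), max_score = max_score,
      score_threshold = threshold_frac * max_score,
      consensus = paste(DNA_BASES[apply(prob, 2, which.max)], collapse = "")
    ),
    class = "crossbind_pwm"
  )
}

#' Read JASPAR-style plain-text PWMs
#'
#' Accepts the JASPAR matrix format: a `>name` header line followed by four
#' rows (A, C, G, T) of counts, with or without the `A [ ... ]` decoration.
#'
#' @param path Path to a motif file.
#' @param background,threshold_frac Passed to [new_pwm()].
#' @return A list of `crossbind_pwm` objects, named by motif.
#' @export
read_pwms <- function(path, background = rep(0.25, 4), threshold_frac = 0.8) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort(sprintf("No '>' motif headers in '%s'.", path))
  ends <- c(starts[-1] - 1, length(lines))
  pwms <- map2(starts, ends, function(s, e) {
    name <- sub("^>\\s*", "", lines[s])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[(s + 1):e]
    if (length(body) != 4) {
      abort(sprintf("Motif '%s' in '%s' needs exactly 4 matrix rows.", name, path))
    }
    rows <- map(body, function(ln) {
      ln <- gsub("[][ACGTacgt]", " ", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(sprintf("Motif '%s' has rows of unequal width.", name))
    }
    new_pwm(name, do.call(rbind, rows), background, threshold_frac)
  })
  setNames(pwms, map_chr(pwms, "name"))
}

encode_dna <- function(seq) {
  code <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
                c(DNA_BASES, "N"))
  if (anyNA(code)) abort("Sequence contains characters outside {A, C, G, T, N}.")
  code[code == 5L] <- NA_integer_ # N: zero log-odds contribution
  code
}

revcomp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

scan_strand <- function(code, log_odds) {
  w <- ncol(log_odds)
  n_win <- length(code) - w + 1
  scores <- numeric(n_win)
  for (i in seq_len(w)) {
    contrib <- log_odds[cbind(code[i:(i + n_win - 1)], i)]
    contrib[is.na(contrib)] <- 0
    scores <- scores + contrib
  }
  scores
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window of motif width is scored as the sum of per-position log2
#' odds `log2(p(base) / background(base))`; `N` bases contribute 0. A window
#' is a hit when its score reaches the PWM's `score_threshold`. Reverse
#' complement windows are reported with `strand = "-"` at their forward
#' coordinates.
#'
#' @param seq A single DNA string over A, C, G, T, N.
#' @param pwm A `crossbind_pwm` object.
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @return A list with `best_score`, `n_hits` and `hits`, a tibble of
#'   `position` (1-based forward start), `strand`, `score` for windows at or
#'   above threshold.
#' @export
scan_pwm <- function(seq, pwm, both_strands = TRUE) {
  if (!inherits(pwm, "crossbind_pwm")) abort("pwm must be a crossbind_pwm.")
  if (length(seq) != 1) abort("scan_pwm() scans one sequence at a time.")
  seq <- as.character(seq)
  w <- pwm$width
  if (nchar(seq) < w) {
    abort(sprintf("Sequence length %d is shorter than motif width %d.",
                  nchar(seq), w))
  }
  fwd <- scan_strand(encode_dna(seq), pwm$log_odds)
  hits <- tibble(position = seq_along(fwd), strand = "+", score = fwd)
  if (both_strands) {
    rev_scores <- scan_strand(encode_dna(revcomp(seq)), pwm$log_odds)
    # window starting at position p on the reverse strand covers forward
    # positions (L - w + 2 - p) .. (L - p + 1)
    hits <- bind_rows(hits, tibble(
      position = nchar(seq) - w + 2L - seq_along(rev_scores),
      strand = "-", score = rev_scores
    ))
  }
  best <- max(hits$score)
  hits <- hits |>
    filter(.data$score >= pwm$score_threshold) |>
    arrange(.data$position, .data$strand)
  list(best_score = best, n_hits = nrow(hits), hits = hits)
}

# encode equal-length sequences as an n x L base-index matrix (N -> NA)
encode_many <- function(seqs) {
  chars <- strsplit(toupper(seqs), "", fixed = TRUE)
  m <- matrix(match(unlist(chars), c(DNA_BASES, "N")),
              nrow = length(seqs), byrow = TRUE)
  if (anyNA(m)) {
    abort("Sequence contains characters outside {A, C, G, T, N}.")
  }
  m[m == 5L] <- NA_integer_
  m
}

# best per-sequence score of one strand for an n x L code matrix
scan_matrix_best <- function(code, log_odds) {
  w <- ncol(log_odds)
  n_win <- ncol(code) - w + 1
  total <- matrix(0, nrow(code), n_win)
  for (i in seq_len(w)) {
    contrib <- matrix(log_odds[cbind(as.vector(code[, i:(i + n_win - 1), drop = FALSE]), i)],
                      nrow(code))
    contrib[is.na(contrib)] <- 0
    total <- total + contrib
  }
  total[cbind(seq_len(nrow(total)), max.col(total, ties.method = "first"))]
}

# vectorized sequence-level presence/absence: TRUE when a sequence has >= 1
# window at or above the PWM threshold on either requested strand
pwm_hit_any <- function(seqs, pwm, both_strands = TRUE) {
  out <- logical(length(seqs))
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (L < pwm$width) next
    code <- encode_many(seqs[idx])
    best <- scan_matrix_best(code, pwm$log_odds)
    if (both_strands) {
      code_rc <- (5L - code)[, ncol(code):1, drop = FALSE]
      best <- pmax(best, scan_matrix_best(code_rc, pwm$log_odds))
    }
    out[idx] <- best >= pwm$score_threshold
  }
  out
}

#' Known-motif enrichment in target versus background sequences
#'
#' Counts, per motif, the sequences with at least one hit (sequence-level
#' presence, as in reporting the percentage of sequences possessing a
#' motif), then tests over-representation of hits among target sequences
#' with the one-sided Fisher's exact test (universe = targets plus
#' background) and Benjamini-Hochberg correction across motifs.
#'
#' @param target_seqs,background_seqs Character vectors of DNA sequences, a
#'   `Biostrings::DNAStringSet`, or paths to FASTA files. Both must be
#'   nonempty.
#' @param pwms A list of `crossbind_pwm` objects (see [read_pwms()]).
#' @param threshold_frac Optional override of each PWM's hit threshold.
#' @param both_strands Scan both strands (default TRUE).
#' @return A tibble of class `crossbind_enrichment`, ranked by p-value,
#'   with columns `term`, `n_target_hit`, `n_target`, `n_background_hit`,
#'   `n_background`, `percent_targets`, `percent_background`, `p_value`,
#'   `q_value`.
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwms,
                             threshold_frac = NULL, both_strands = TRUE) {
  targets <- as_sequences(target_seqs)
  background <- as_sequences(background_seqs)
  if (length(targets) == 0 || length(background) == 0) {
    abort("Both target and background sequence sets must be nonempty.")
  }
  if (inherits(pwms, "crossbind_pwm")) pwms <- list(pwms)
  res <- map(pwms, function(pwm) {
    if (!is.null(threshold_frac)) {
      pwm$score_threshold <- threshold_frac * pwm$max_score
    }
    t_hit <- sum(pwm_hit_any(targets, pwm, both_strands))
    b_hit <- sum(pwm_hit_any(background, pwm, both_strands))
    tibble(
      term = pwm$name,
      n_target_hit = t_hit, n_target = length(targets),
      n_background_hit = b_hit, n_background = length(background),
      percent_targets = 100 * t_hit / length(targets),
      percent_background = 100 * b_hit / length(background),
      p_value = fisher_exact_greater(
        k = t_hit, n = length(targets), K = t_hit + b_hit,
        N = length(targets) + length(background)
      )
    )
  }) |> bind_rows()
  res <- res |>
    mutate(q_value = bh_fdr(.data$p_value)) |>
    arrange(.data$p_value, .data$term)
  class(res) <- c("crossbind_enrichment", class(res))
  res
}

as_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    return(as.character(Biostrings::readDNAStringSet(x)))
  }
  as.character(x)
}
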
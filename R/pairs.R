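#' Binary within-patient gene-pair score
#'
#' The score of an ordered pair is 1 when the first gene is expressed
#' strictly higher than the second within the same sample, otherwise 0.
#' Ties score 0: the rule demands the first gene be genuinely higher, and on
#' continuous expression ties are measure-zero. Because the comparison is
#' within-sample, the score is invariant to any strictly increasing
#' per-sample transform of expression — no normalization or cross-sample
#' scaling is ever needed.
#'
#' @param expr_hi,expr_lo Finite numeric vectors (recycled like `ifelse`).
#' @return Integer vector of 0/1 scores.
#' @export
pair_score <- function(expr_hi, expr_lo) {
  if (any(!is.finite(expr_hi)) || any(!is.finite(expr_lo))) {
    abort_domain("pair_score: inputs must be finite")
  }
  as.integer(expr_hi > expr_lo)
}

#' Score all gene pairs in every sample
#'
#' Enumerates each unordered combination of `genes` exactly once, ordered as
#' (gene_i, gene_j) with i < j in gene-list order, and computes the binary
#' within-patient score for every sample. The reversed pair is redundant: on
#' tie-free data score(a, b) = 1 - score(b, a).
#'
#' @param expr Expression tibble (see [as_expression()]).
#' @param genes Character vector of >= 2 gene symbols, all present in `expr`.
#' @return A `pair_matrix` tibble: columns `gene_hi`, `gene_lo`, `pair`
#'   (canonical `"HI|LO"` id), then one 0/1 column per sample.
#' @export
build_pair_matrix <- function(expr, genes) {
  expr <- as_expression(expr)
  genes <- toupper(genes)
  if (length(genes) < 2) abort_config("need at least 2 genes to form pairs")
  if (anyDuplicated(genes)) abort_config("duplicate genes in pair list")
  m <- expression_matrix(expr)
  missing_genes <- setdiff(genes, rownames(m))
  if (length(missing_genes) > 0) {
    abort_lookup(paste0("gene(s) missing from expression matrix: ",
                        paste(missing_genes, collapse = ", ")))
  }
  m <- m[genes, , drop = FALSE]
  idx <- utils::combn(length(genes), 2)
  hi <- idx[1, ]
  lo <- idx[2, ]
  scores <- (m[hi, , drop = FALSE] > m[lo, , drop = FALSE]) * 1L
  out <- dplyr::bind_cols(
    tibble(gene_hi = genes[hi], gene_lo = genes[lo],
           pair = paste(genes[hi], genes[lo], sep = "|")),
    as_tibble(scores)
  )
  class(out) <- c("pair_matrix", class(out))
  out
}

# pairs x samples 0/1 matrix view (rownames = canonical pair ids)
pair_score_matrix <- function(pairs) {
  meta <- intersect(c("gene_hi", "gene_lo", "pair"), names(pairs))
  m <- as.matrix(pairs[, setdiff(names(pairs), meta), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- pairs$pair
  m
}

pair_sample_ids <- function(pairs) {
  setdiff(names(pairs), c("gene_hi", "gene_lo", "pair"))
}

#' Keep informative pairs shared by two cohorts
#'
#' A pair whose score is (almost) constant in a cohort carries no prognostic
#' contrast. This keeps pairs whose score-1 frequency lies inside
#' `[min_freq, max_freq]` (both endpoints inclusive) in *both* cohorts —
#' the conventional 20-80% band of the relative-ordering literature —
#' preserving pair order.
#'
#' @param pairs1,pairs2 `pair_matrix` tibbles over the same pair list.
#' @param min_freq,max_freq Frequency band (defaults 0.2 and 0.8).
#' @return The filtered `pair_matrix` rows of `pairs1` and `pairs2`, as a
#'   list with elements `pairs1`, `pairs2`, and `pair` (retained pair ids).
#' @export
select_candidate_pairs <- function(pairs1, pairs2, min_freq = 0.2, max_freq = 0.8) {
  if (!(min_freq >= 0 && min_freq < max_freq && max_freq <= 1)) {
    abort_config("need 0 <= min_freq < max_freq <= 1")
  }
  if (!identical(pairs1$pair, pairs2$pair)) {
    abort_alignment("pair lists of the two cohorts differ")
  }
  f1 <- rowMeans(pair_score_matrix(pairs1))
  f2 <- rowMeans(pair_score_matrix(pairs2))
  keep <- f1 >= min_freq & f1 <= max_freq & f2 >= min_freq & f2 <= max_freq
  list(
    pairs1 = pairs1[keep, , drop = FALSE],
    pairs2 = pairs2[keep, , drop = FALSE],
    pair = pairs1$pair[keep],
    freq_cohort1 = f1,
    freq_cohort2 = f2
  )
}
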
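#' Read a cell-type signature (reference) matrix
#'
#' TSV/CSV with gene symbols in the first column and one non-negative
#' column per cell type.
#'
#' @param path Path to the reference file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Validated reference tibble (`gene` + cell-type columns).
#' @export
read_reference <- function(path, dialect = c("tsv", "csv")) {
  as_reference(read_expression(path, dialect))
}

#' Validate a cell-type reference tibble
#' @param reference Data frame: gene column + non-negative cell-type columns.
#' @export
as_reference <- function(reference) {
  reference <- as_expression(reference)
  m <- expression_matrix(reference)
  if (any(m < 0)) abort_domain("reference profiles must be non-negative")
  if (any(colSums(m) == 0)) abort_domain("every reference cell type needs a non-zero profile")
  reference
}

#' Generate a synthetic cell-type reference matrix
#'
#' Each cell type receives a disjoint block of marker genes with strongly
#' elevated expression over a shared low baseline, giving a well-conditioned
#' reference for testing reference-based deconvolution. This is a synthetic
#' stand-in for curated immune signature matrices such as LM22, which is not
#' redistributed.
#'
#' @param n_genes Number of reference genes (default 60).
#' @param cell_types Cell-type names (default six immune-like labels).
#' @param seed RNG seed.
#' @param gene_ids Optional gene symbols (length `n_genes`).
#' @return Reference tibble (`gene` + one column per cell type).
#' @export
simulate_reference <- function(n_genes = 60,
                               cell_types = c("B_cells", "T_cells_CD4",
                                              "T_cells_CD8", "NK_cells",
                                              "Macrophages", "Monocytes"),
                               seed = 1L, gene_ids = NULL) {
  if (n_genes < 2 * length(cell_types)) {
    abort_config("simulate_reference: need at least 2 marker genes per cell type")
  }
  set.seed(seed)
  genes <- toupper(gene_ids %||% sprintf("RG%03d", seq_len(n_genes)))
  k <- length(cell_types)
  m <- matrix(runif(n_genes * k, 0.1, 1), nrow = n_genes,
              dimnames = list(genes, cell_types))
  block <- split(seq_len(n_genes), rep_len(seq_len(k), n_genes))
  for (j in seq_len(k)) m[block[[j]], j] <- runif(length(block[[j]]), 6, 12)
  as_reference(dplyr::bind_cols(tibble(gene = genes), as_tibble(m)))
}

nnls_fractions <- function(R, b) {
  fit <- pracma::lsqnonneg(R, b)
  x <- fit$x
  fitted <- drop(R %*% x)
  r <- if (stats::sd(fitted) == 0 || stats::sd(b) == 0) NA_real_ else cor(fitted, b)
  list(x = x, fit_correlation = r)
}

#' Reference-based cell-type deconvolution with permutation p-values
#'
#' For every sample, regresses the bulk expression vector (restricted to
#' genes shared with the reference, matched by symbol) on the reference
#' profiles by non-negative least squares and rescales the solution to the
#' unit simplex, yielding relative cell-type fractions. Significance is
#' assessed per sample by a Monte-Carlo permutation test: the bulk vector's
#' gene labels are permuted `n_perm` times and the p-value is the add-one
#' fraction of permutations whose reconstruction correlation reaches the
#' observed one (so `perm_p` is always > 0). An all-zero NNLS solution is
#' reported as uniform fractions with `flagged = TRUE`.
#'
#' @param bulk Expression tibble (genes x samples).
#' @param reference Reference tibble (see [as_reference()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return A `deconv_result` tibble: `sample_id`, one fraction column per
#'   cell type (each row sums to 1), `fit_correlation`, `perm_p`, `flagged`.
#' @export
deconvolve <- function(bulk, reference, n_perm = 1000, seed = 1L) {
  bulk <- as_expression(bulk)
  reference <- as_reference(reference)
  B <- expression_matrix(bulk)
  R <- expression_matrix(reference)
  shared <- intersect(rownames(B), rownames(R))
  if (length(shared) < 2) {
    abort_alignment("fewer than 2 genes shared between bulk and reference")
  }
  B <- B[shared, , drop = FALSE]
  R <- R[shared, , drop = FALSE]
  k <- ncol(R)
  set.seed(seed)
  rows <- purrr::map(seq_len(ncol(B)), function(j) {
    b <- B[, j]
    obs <- nnls_fractions(R, b)
    total <- sum(obs$x)
    flagged <- total == 0
    frac <- if (flagged) rep(1 / k, k) else obs$x / total
    hits <- 0L
    if (!is.na(obs$fit_correlation)) {
      for (p in seq_len(n_perm)) {
        rp <- nnls_fractions(R, b[sample.int(length(b))])$fit_correlation
        if (!is.na(rp) && rp >= obs$fit_correlation) hits <- hits + 1L
      }
    } else {
      hits <- n_perm
    }
    dplyr::bind_cols(
      tibble(sample_id = colnames(B)[j]),
      as_tibble(as.list(setNames(frac, colnames(R)))),
      tibble(fit_correlation = obs$fit_correlation,
             perm_p = (1 + hits) / (1 + n_perm),
             flagged = flagged)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("deconv_result", class(out))
  attr(out, "cell_types") <- colnames(R)
  out
}

deconv_cell_types <- function(results) {
  attr(results, "cell_types") %||%
    setdiff(names(results), c("sample_id", "fit_correlation", "perm_p", "flagged"))
}

#' Compare cell-type fractions between risk groups
#'
#' Welch two-sample t-test of each cell type's fraction, high-risk versus
#' low-risk. No multiplicity correction is applied to the headline p-values
#' (mirroring common starred-p reporting); a Benjamini-Hochberg adjusted
#' column is emitted alongside.
#'
#' @param results A `deconv_result` tibble.
#' @param profiles A `risk_profile` tibble with `group` set.
#' @return Tibble sorted by p ascending: `cell_type`, `mean_high`,
#'   `mean_low`, `t_statistic`, `p_value`, `p_bh`.
#' @export
compare_groups <- function(results, profiles) {
  dat <- dplyr::inner_join(results, profiles, by = "sample_id")
  if (sum(dat$group == "high") < 2 || sum(dat$group == "low") < 2) {
    abort_domain("compare_groups needs at least 2 samples per risk group")
  }
  cts <- deconv_cell_types(results)
  rows <- purrr::map(cts, function(ct) {
    hi <- dat[[ct]][dat$group == "high"]
    lo <- dat[[ct]][dat$group == "low"]
    tt <- tryCatch(stats::t.test(hi, lo), error = function(e) NULL)
    tibble(cell_type = ct,
           mean_high = mean(hi), mean_low = mean(lo),
           t_statistic = if (is.null(tt)) 0 else unname(tt$statistic),
           p_value = if (is.null(tt)) 1 else tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value)
}

#' Correlate cell-type fractions with the risk score
#'
#' @inheritParams compare_groups
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble: `cell_type`, `r`, `p_value`, `note` (non-empty when the
#'   correlation is undefined, e.g. a constant fraction vector).
#' @export
correlate_with_score <- function(results, profiles,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  dat <- dplyr::inner_join(results, profiles, by = "sample_id")
  if (nrow(dat) < 3) abort_domain("correlate_with_score needs at least 3 paired samples")
  cts <- deconv_cell_types(results)
  rows <- purrr::map(cts, function(ct) {
    x <- dat[[ct]]
    if (stats::sd(x) == 0 || stats::sd(dat$risk_score) == 0) {
      return(tibble(cell_type = ct, r = NA_real_, p_value = NA_real_,
                    note = "correlation undefined: constant vector"))
    }
    ct_test <- suppressWarnings(stats::cor.test(x, dat$risk_score, method = method))
    tibble(cell_type = ct, r = unname(ct_test$estimate),
           p_value = ct_test$p.value, note = "")
  })
  dplyr::bind_rows(rows)
}
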
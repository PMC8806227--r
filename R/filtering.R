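#' Unscaled median absolute deviation
#'
#' `median(|x - median(x)|)` with no consistency factor: the filter threshold
#' is a bare spread in expression units, not a robust standard-deviation
#' estimate, so the 1.4826 normal-consistency constant is deliberately
#' omitted (it is available through `constant`). Even-length medians use the
#' midpoint.
#'
#' @param x Numeric vector, finite, length >= 1.
#' @param constant Multiplier applied to the raw MAD (default 1).
#' @return Non-negative scalar.
#' @export
mad_value <- function(x, constant = 1) {
  if (length(x) == 0) abort_domain("mad_value: empty vector")
  if (any(!is.finite(x))) abort_domain("mad_value: non-finite values")
  stats::mad(x, constant = constant)
}

#' Filter candidate genes by presence and robust variability in two cohorts
#'
#' A candidate gene is retained iff it is present in both expression tables
#' and its unscaled MAD is at least `mad_threshold` in each cohort
#' separately; genes with MAD below the threshold ("uneven distribution,
#' relatively small change") are removed. Retained genes keep candidate-list
#' order. To filter against a single cohort, pass the same table twice.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param cohort1,cohort2 Expression tibbles (see [as_expression()]).
#' @param mad_threshold Keep genes with per-cohort MAD >= this value
#'   (default 0.5); the comparison is on expression values as supplied.
#' @return A `filter_report` object: a list with `report` (one row per
#'   candidate: gene, presence and MAD per cohort, status) and `retained`
#'   (character vector).
#' @export
filter_genes <- function(candidates, cohort1, cohort2, mad_threshold = 0.5) {
  if (mad_threshold < 0) abort_config("mad_threshold must be >= 0")
  candidates <- unique(toupper(candidates))
  if (length(candidates) == 0) abort_config("empty candidate gene list")
  m1 <- expression_matrix(as_expression(cohort1))
  m2 <- expression_matrix(as_expression(cohort2))

  mad_of <- function(m, g) {
    if (!g %in% rownames(m)) return(NA_real_)
    mad_value(m[g, ])
  }
  report <- tibble(
    gene = candidates,
    present_cohort1 = candidates %in% rownames(m1),
    present_cohort2 = candidates %in% rownames(m2),
    mad_cohort1 = vapply(candidates, mad_of, numeric(1), m = m1),
    mad_cohort2 = vapply(candidates, mad_of, numeric(1), m = m2)
  )
  report$status <- dplyr::case_when(
    !report$present_cohort1 ~ "absent_in_cohort1",
    !report$present_cohort2 ~ "absent_in_cohort2",
    report$mad_cohort1 < mad_threshold ~ "low_mad_in_cohort1",
    report$mad_cohort2 < mad_threshold ~ "low_mad_in_cohort2",
    TRUE ~ "retained"
  )
  retained <- report$gene[report$status == "retained"]
  if (length(retained) == 0) {
    abort_no_signal("no genes survive filtering; the pipeline cannot proceed")
  }
  structure(
    list(
      report = report,
      retained = retained,
      input_count = length(candidates),
      mad_threshold = mad_threshold,
      absent_in_cohort1 = report$gene[report$status == "absent_in_cohort1"],
      absent_in_cohort2 = report$gene[report$status == "absent_in_cohort2"],
      low_mad_in_cohort1 = report$gene[report$status == "low_mad_in_cohort1"],
      low_mad_in_cohort2 = report$gene[report$status == "low_mad_in_cohort2"]
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Gene filter report: %d candidates -> %d retained (MAD >= %g in both cohorts)\n",
              x$input_count, length(x$retained), x$mad_threshold))
  cat(sprintf("  absent: %d (cohort 1), %d (cohort 2); low MAD: %d (cohort 1), %d (cohort 2)\n",
              length(x$absent_in_cohort1), length(x$absent_in_cohort2),
              length(x$low_mad_in_cohort1), length(x$low_mad_in_cohort2)))
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) x$report
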
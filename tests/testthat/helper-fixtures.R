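# Shared fixture builders: everything is generated in code at test time.

write_expr_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small expression tibble straight from a genes x samples matrix
expr_from_matrix <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)), tibble::as_tibble(m))
}

# clinical tibble with continuous (tie-free) times
make_clinical <- function(times, events, ids = sprintf("S%03d", seq_along(times))) {
  tibble::tibble(sample_id = ids, os_time = times, os_event = as.integer(events))
}

# random strictly increasing per-sample transform (for rank-invariance tests)
random_monotone <- function(rng_draw = stats::runif(3)) {
  a <- 0.2 + 2 * rng_draw[1]
  b <- 5 * rng_draw[2] - 2
  c3 <- 0.05 * rng_draw[3]
  function(x) a * x + b + c3 * x^3
}

apply_per_sample <- function(expr, fns) {
  m <- as.matrix(expr[, -1])
  for (j in seq_len(ncol(m))) m[, j] <- fns[[j]](m[, j])
  dplyr::bind_cols(tibble::tibble(gene = expr$gene), tibble::as_tibble(m))
}

# write a simulated cohort pair to disk as pipeline inputs
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    cohort1_expression = file.path(dir, "expr1.tsv"),
    cohort1_clinical = file.path(dir, "clin1.tsv"),
    cohort2_expression = file.path(dir, "expr2.tsv"),
    cohort2_clinical = file.path(dir, "clin2.tsv"),
    gene_list = file.path(dir, "genes.txt"))
  pairhazard::write_expression(sim$cohort1$expression, paths$cohort1_expression)
  pairhazard::write_clinical(sim$cohort1$clinical, paths$cohort1_clinical)
  pairhazard::write_expression(sim$cohort2$expression, paths$cohort2_expression)
  pairhazard::write_clinical(sim$cohort2$clinical, paths$cohort2_clinical)
  pairhazard::write_gene_list(sim$cohort1$expression$gene, paths$gene_list)
  paths
}

# textbook two-group log-rank statistic: sum over event times of O - E with
# hypergeometric variance (independent oracle for logrank_test)
logrank_by_hand <- function(times, events, group) {
  g1 <- unique(group)[1]
  evt <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in evt) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# brute-force pairwise concordance (Mann-Whitney with 0.5 for ties)
concordance_by_hand <- function(marker_cases, marker_controls) {
  s <- 0
  for (x in marker_cases) {
    for (y in marker_controls) {
      s <- s + (x > y) + 0.5 * (x == y)
    }
  }
  s / (length(marker_cases) * length(marker_controls))
}
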
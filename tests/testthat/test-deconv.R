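ref <- read_reference(system.file("extdata", "synthetic_reference.tsv",
                                  package = "pairhazard"))
R <- as.matrix(ref[, -1])
rownames(R) <- ref$gene

test_that("noiseless two-component mixtures are recovered exactly", {
  mix <- 0.6 * R[, 1] + 0.4 * R[, 2]
  bulk <- expr_from_matrix(matrix(mix, ncol = 1,
                                  dimnames = list(ref$gene, "M1")))
  res <- deconvolve(bulk, ref, n_perm = 50, seed = 1)
  expect_equal(res[[names(ref)[2]]], 0.6, tolerance = 1e-6)
  expect_equal(res[[names(ref)[3]]], 0.4, tolerance = 1e-6)
  cts <- setdiff(names(ref)[-1], names(ref)[2:3])
  expect_true(all(abs(unlist(res[, cts])) < 1e-6))
  expect_lt(res$perm_p, 0.05)
  expect_false(res$flagged)
})

test_that("fractions live on the unit simplex and scale out of the bulk", {
  set.seed(12)
  m <- matrix(rexp(nrow(R) * 4, 0.2), ncol = 4,
              dimnames = list(ref$gene, sprintf("S%d", 1:4)))
  bulk <- expr_from_matrix(m)
  res <- deconvolve(bulk, ref, n_perm = 20, seed = 3)
  fr <- as.matrix(res[, names(ref)[-1]])
  expect_true(all(fr >= 0))
  expect_equal(unname(rowSums(fr)), rep(1, 4), tolerance = 1e-9)

  scaled <- expr_from_matrix(sweep(m, 2, c(2, 0.5, 10, 1), "*"))
  res2 <- deconvolve(scaled, ref, n_perm = 20, seed = 3)
  expect_equal(as.matrix(res2[, names(ref)[-1]]), fr, tolerance = 1e-9)
})

test_that("gene matching is by symbol, not row position", {
  mix <- 0.3 * R[, 2] + 0.7 * R[, 5]
  perm <- sample(nrow(R))
  bulk <- expr_from_matrix(matrix(mix[perm], ncol = 1,
                                  dimnames = list(ref$gene[perm], "M1")))
  res <- deconvolve(bulk, ref, n_perm = 20, seed = 9)
  expect_equal(res[[names(ref)[3]]], 0.3, tolerance = 1e-6)
  expect_equal(res[[names(ref)[6]]], 0.7, tolerance = 1e-6)

  alien <- expr_from_matrix(matrix(1:3, ncol = 1,
                                   dimnames = list(c("X1", "X2", "X3"), "M")))
  expect_error(deconvolve(alien, ref), class = "ph_alignment_error")
})

test_that("permutation p-values are reproducible and calibrated on noise", {
  set.seed(77)
  bulk1 <- expr_from_matrix(matrix(rexp(nrow(R), 0.2), ncol = 1,
                                   dimnames = list(ref$gene, "N1")))
  a <- deconvolve(bulk1, ref, n_perm = 100, seed = 5)
  b <- deconvolve(bulk1, ref, n_perm = 100, seed = 5)
  expect_identical(a$perm_p, b$perm_p)
  expect_gt(a$perm_p, 0)
})

test_that("group comparison detects a planted shift and is label-antisymmetric", {
  set.seed(41)
  n <- 50
  cts <- names(ref)[-1]
  frac <- matrix(abs(rnorm(2 * n * 6, 0.15, 0.05)), ncol = 6,
                 dimnames = list(NULL, cts))
  frac[1:n, 3] <- frac[1:n, 3] + 0.2  # planted shift in the high group
  frac <- frac / rowSums(frac)
  res <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%03d", 1:(2 * n))),
    tibble::as_tibble(frac),
    tibble::tibble(fit_correlation = 0.9, perm_p = 0.01, flagged = FALSE))
  class(res) <- c("deconv_result", class(res))
  profiles <- tibble::tibble(sample_id = res$sample_id,
                             risk_score = rnorm(2 * n),
                             group = rep(c("high", "low"), each = n))
  cmp <- compare_groups(res, profiles)
  expect_equal(cmp$cell_type[1], cts[3])
  expect_lt(cmp$p_value[1], 0.001)
  expect_gt(cmp$mean_high[1], cmp$mean_low[1])

  flipped <- dplyr::mutate(profiles, group = ifelse(group == "high", "low", "high"))
  cmp2 <- compare_groups(res, flipped)
  expect_equal(cmp2$t_statistic, -cmp$t_statistic, tolerance = 1e-12)
  expect_equal(cmp2$p_value, cmp$p_value, tolerance = 1e-12)

  # identical fractions in both groups: t = 0, p = 1
  same <- res
  same[, cts] <- res[rep(1:n, 2), cts]
  cmp3 <- compare_groups(same, profiles)
  expect_equal(cmp3$t_statistic, rep(0, 6), tolerance = 1e-12)
  expect_equal(cmp3$p_value, rep(1, 6), tolerance = 1e-12)

  expect_error(compare_groups(res, profiles[c(1, n + 1), ]),
               class = "ph_domain_error")
})

test_that("score correlations behave for linear, monotone, and constant inputs", {
  n <- 40
  cts <- names(ref)[-1]
  score <- seq(-1, 1, length.out = n)
  frac <- matrix(0.1, nrow = n, ncol = 6, dimnames = list(NULL, cts))
  frac[, 1] <- 0.05 + 0.01 * (score + 2)   # affine increasing in score
  res <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%03d", 1:n)),
    tibble::as_tibble(frac),
    tibble::tibble(fit_correlation = 0.9, perm_p = 0.01, flagged = FALSE))
  class(res) <- c("deconv_result", class(res))
  profiles <- tibble::tibble(sample_id = res$sample_id, risk_score = score)

  out <- correlate_with_score(res, profiles)
  expect_equal(out$r[out$cell_type == cts[1]], 1, tolerance = 1e-12)
  expect_match(out$note[out$cell_type == cts[2]], "constant")
  expect_true(is.na(out$r[out$cell_type == cts[2]]))

  # spearman is invariant under a monotone transform of the score
  sp1 <- correlate_with_score(res, profiles, method = "spearman")
  sp2 <- correlate_with_score(res, dplyr::mutate(profiles, risk_score = exp(3 * risk_score)),
                              method = "spearman")
  expect_equal(sp1$r, sp2$r, tolerance = 1e-12)
})
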
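# one moderate two-cohort simulation shared across the blocks below
sim <- simulate_cohort_pair(sim_config(n_genes = 20, n_samples_per_cohort = 300,
                                       n_planted_pairs = 3, planted_log_hazard = 1.5,
                                       seed = 101))
genes <- sim$cohort1$expression$gene
pm1 <- build_pair_matrix(sim$cohort1$expression, genes)
pm2 <- build_pair_matrix(sim$cohort2$expression, genes)
cand <- select_candidate_pairs(pm1, pm2)

test_that("the univariate screen finds planted pairs and flags degenerate ones", {
  screen <- univariate_screen(cand$pairs1, sim$cohort1$clinical)
  expect_equal(screen$pair, cand$pair)  # input order preserved
  planted_rows <- screen[screen$pair %in% sim$truth$pairs$pair, ]
  expect_true(all(planted_rows$passed))

  # a constant-score pair is degenerate, never passed
  const <- cand$pairs1[1, ]
  const[1, -(1:3)] <- as.list(rep(1L, ncol(const) - 3))
  const$pair <- "CONST|PAIR"
  with_const <- dplyr::bind_rows(cand$pairs1, const)
  screen2 <- univariate_screen(with_const, sim$cohort1$clinical)
  expect_true(screen2$degenerate[screen2$pair == "CONST|PAIR"])
  expect_false(screen2$passed[screen2$pair == "CONST|PAIR"])

  # an impossible alpha empties the screen explicitly
  expect_error(univariate_screen(cand$pairs1, sim$cohort1$clinical, alpha = 1e-300),
               class = "ph_no_signal_error", regexp = "empty screen")
})

test_that("LASSO shrinks fully at large lambda and matches coxph at lambda 0", {
  two <- cand$pairs1[match(sim$truth$pairs$pair[1:2], cand$pair), ]
  expect_error(lasso_cox(two, sim$cohort1$clinical, lambda = 50),
               class = "ph_no_signal_error")

  model0 <- lasso_cox(two, sim$cohort1$clinical, lambda = 0)
  al <- list(scores = t(as.matrix(two[, -(1:3)])))
  clin <- sim$cohort1$clinical
  ref <- cox_fit(clin$os_time, clin$os_event,
                 as.data.frame(al$scores, col.names = two$pair))
  expect_equal(sort(model0$pairs$coefficient), sort(ref$coefficients$estimate),
               tolerance = 1e-4)
})

test_that("risk scores are the coefficient dot product and survive serialization", {
  model <- pair_signature(tibble::tibble(
    gene_hi = c("A", "B", "C"), gene_lo = c("X", "Y", "Z"),
    coefficient = c(0.5, -0.2, 0.3)))
  pm <- dplyr::bind_cols(
    tibble::tibble(gene_hi = c("A", "B", "C"), gene_lo = c("X", "Y", "Z"),
                   pair = c("A|X", "B|Y", "C|Z")),
    tibble::as_tibble(matrix(c(1, 0, 1, 0, 0, 0), nrow = 3,
                             dimnames = list(NULL, c("S1", "S2")))))
  rs <- risk_scores(model, pm)
  expect_equal(rs$risk_score, c(0.8, 0.0))

  path <- tempfile(fileext = ".json")
  write_signature(model, path)
  rs2 <- risk_scores(read_signature(path), pm)
  expect_equal(rs2$risk_score, rs$risk_score, tolerance = 1e-12)

  bad <- pair_signature(tibble::tibble(gene_hi = "Q", gene_lo = "R", coefficient = 1))
  expect_error(risk_scores(bad, pm), class = "ph_lookup_error", regexp = "Q\\|R")
})

trained <- train_signature(cand$pairs1, sim$cohort1$clinical, seed = 101, horizon = 1)

test_that("every signature pair passed the screen and the cutoff is Youden-optimal", {
  expect_true(all(trained$model$pairs$pair %in% trained$screen$pair[trained$screen$passed]))

  roc <- attr(trained$model, "roc")
  finite <- roc$curve[is.finite(roc$curve$threshold), ]
  expect_equal(max(finite$tpr - finite$fpr),
               with(finite, (tpr - fpr)[threshold == trained$model$cutoff]),
               tolerance = 1e-12)

  # the calibrated cutoff splits the training cohort into two non-empty groups
  grp <- trained$profile$group
  expect_true(all(c("high", "low") %in% grp))
})

test_that("frozen-cutoff validation separates risk groups in the second cohort", {
  val <- validate_signature(trained$model, cand$pairs2, sim$cohort2$clinical)
  expect_true(all(val$group_sizes > 0))
  expect_gt(val$cox$coefficients$hazard_ratio, 1)
  expect_lt(val$logrank$p_value, 0.05)
  expect_true(all(val$auc$auc >= 0 & val$auc$auc <= 1, na.rm = TRUE))

  # monotone re-distortion of the validation expression changes nothing
  set.seed(33)
  distorted <- distort_samples(sim$cohort2$expression, "monotone-cubic")
  pm2_d <- build_pair_matrix(distorted, genes)
  cand_d <- select_candidate_pairs(pm1, pm2_d)
  expect_identical(cand_d$pairs2$pair, cand$pairs2$pair)
  val_d <- validate_signature(trained$model, cand_d$pairs2, sim$cohort2$clinical)
  expect_identical(val_d$profile, val$profile)
})

test_that("shuffled validation survival mostly yields HR intervals covering 1", {
  clin2 <- sim$cohort2$clinical
  set.seed(202)
  covers <- replicate(50, {
    idx <- sample(nrow(clin2))
    shuffled <- dplyr::mutate(clin2, os_time = os_time[idx], os_event = os_event[idx])
    v <- validate_signature(trained$model, cand$pairs2, shuffled)
    v$cox$coefficients$conf_low <= 1 && v$cox$coefficients$conf_high >= 1
  })
  expect_gte(mean(covers), 0.9)
})

test_that("subgroup analysis partitions events and skips degenerate strata", {
  val <- validate_signature(trained$model, cand$pairs2, sim$cohort2$clinical)
  clin2 <- sim$cohort2$clinical
  sub <- subgroup_km(val$profile, clin2, "stage")
  expect_equal(sum(sub$n_events), sum(clin2$os_event))
  expect_equal(sum(sub$n), nrow(clin2))

  # stage assigned independently of risk: per-stratum CIs overlap the global HR
  glob <- cox_fit(clin2$os_time, clin2$os_event,
                  data.frame(high = as.integer(val$profile$group == "high")))
  done <- sub[!sub$skipped, ]
  expect_true(all(done$conf_low <= glob$coefficients$hazard_ratio &
                  done$conf_high >= glob$coefficients$hazard_ratio))

  # a stratum with a single risk group is skipped with a note
  clin_one <- clin2
  clin_one$stage <- ifelse(clin2$sample_id %in%
                             val$profile$sample_id[val$profile$group == "high"][1:5], 9L, 1L)
  sub_one <- subgroup_km(val$profile, clin_one, "stage")
  expect_true(sub_one$skipped[sub_one$stratum == "9"])
  expect_match(sub_one$note[sub_one$stratum == "9"], "skipped")
})

test_that("the signature stays prognostic after clinical adjustment", {
  val <- validate_signature(trained$model, cand$pairs2, sim$cohort2$clinical)
  cc <- clinical_cox(val$profile, sim$cohort2$clinical)
  expect_true(all(c("age", "gender", "grade", "stage", "risk_score") %in%
                  cc$univariate$term))
  multi <- cc$multivariate$coefficients
  expect_lt(multi$p_value[multi$term == "risk_score"], 0.05)

  expect_error(clinical_cox(val$profile, sim$cohort2$clinical, covariates = "bmi"),
               class = "ph_config_error")
})

test_that("independent covariates give hazard-ratio intervals covering 1", {
  set.seed(303)
  covered <- replicate(50, {
    n <- 150
    tm <- rexp(n, 0.2); cs <- rexp(n, 0.1)
    age <- rnorm(n, 60, 10)
    fit <- cox_fit(pmin(tm, cs), as.integer(tm <= cs), data.frame(age = age))
    fit$coefficients$conf_low <= 1 && fit$coefficients$conf_high >= 1
  })
  expect_gte(mean(covered), 0.9)
})
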
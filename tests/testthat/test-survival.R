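test_that("Kaplan-Meier matches the hand-computed product-limit fixture", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$survival, c(2/3, 1/3, 1/3))  # (2/3) * (1/2), censor adds no drop

  all_cens <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))

  # ratio-based estimator: doubling every record changes nothing
  t2 <- rep(c(1, 2, 3), 2); e2 <- rep(c(1, 1, 0), 2)
  expect_equal(km_estimate(t2, e2)$survival, km$survival)

  # record order is irrelevant
  o <- c(3, 1, 2)
  expect_equal(km_estimate(c(1, 2, 3)[o], c(1, 1, 0)[o]), km)
})

test_that("log-rank matches the textbook O-E/V computation and its symmetries", {
  # tie-free 6-subject, 4-event fixture
  times <- c(1, 2.5, 3, 4.5, 6, 7)
  events <- c(1, 1, 0, 1, 1, 0)
  group <- c("a", "b", "a", "b", "a", "b")
  got <- logrank_test(times, events, group)
  expect_equal(got$chi_square, logrank_by_hand(times, events, group), tolerance = 1e-12)
  expect_equal(got$df, 1)
  expect_equal(got$p_value, pchisq(got$chi_square, 1, lower.tail = FALSE))

  # swapping the labels leaves the statistic unchanged
  swapped <- logrank_test(times, events, ifelse(group == "a", "b", "a"))
  expect_equal(swapped$chi_square, got$chi_square)

  # identical survival copied into both groups: no separation at all
  same <- logrank_test(rep(times, 2), rep(events, 2), rep(c("a", "b"), each = 6))
  expect_equal(same$chi_square, 0, tolerance = 1e-9)
  expect_equal(same$p_value, 1, tolerance = 1e-6)

  expect_error(logrank_test(times, events, rep("a", 6)), class = "ph_domain_error")
})

test_that("Cox score test equals the log-rank chi-square for one binary covariate", {
  set.seed(71)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = 0.1 * exp(0.8 * x))
  t_cens <- rexp(n, rate = 0.05)
  times <- pmin(t_event, t_cens)          # continuous, tie-free
  events <- as.integer(t_event <= t_cens)
  fit <- cox_fit(times, events, data.frame(x = x))
  lr <- logrank_test(times, events, x)
  expect_equal(fit$score_chisq, lr$chi_square, tolerance = 1e-6)
  # Breslow and Efron coincide exactly without ties
  fit_b <- cox_fit(times, events, data.frame(x = x), ties = "breslow")
  expect_equal(fit$coefficients$estimate, fit_b$coefficients$estimate, tolerance = 1e-10)
  # hazard_ratio = exp(coef), CI ordered
  expect_equal(fit$coefficients$hazard_ratio, exp(fit$coefficients$estimate))
  expect_true(fit$coefficients$conf_low < fit$coefficients$conf_high)
})

test_that("Cox recovers a planted log-hazard within 3 standard errors", {
  sim <- simulate_cohort_pair(sim_config(n_genes = 4, n_samples_per_cohort = 500,
                                         n_planted_pairs = 1, planted_log_hazard = 1,
                                         seed = 55))
  z <- sim$truth$z_cohort1[, 1]
  clin <- sim$cohort1$clinical
  fit <- cox_fit(clin$os_time, clin$os_event, data.frame(z = z))
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients$estimate - 1), 3 * fit$coefficients$std_error)
})

test_that("degenerate Cox problems are flagged, never thrown", {
  # no events at all
  f0 <- cox_fit(c(1, 2, 3, 4), c(0, 0, 0, 0), data.frame(x = c(0, 1, 0, 1)))
  expect_false(f0$converged)
  expect_true(all(is.na(f0$coefficients$estimate)))
  # duplicated (collinear) covariate
  set.seed(72)
  x <- rbinom(30, 1, 0.5)
  tm <- rexp(30, exp(x))
  fd <- cox_fit(tm, rep(1, 30), data.frame(a = x, b = x))
  expect_false(fd$converged)
})

test_that("IPCW ROC equals brute-force concordance when censoring-free", {
  set.seed(73)
  times <- c(runif(10, 0.1, 0.9), runif(10, 1.1, 3))  # 10 cases, 10 controls at t = 1
  events <- rep(1, 20)
  marker <- rnorm(20, mean = rep(c(1, 0), each = 10))
  roc <- td_roc(times, events, marker, horizon = 1)
  expect_equal(roc$auc, concordance_by_hand(marker[1:10], marker[11:20]),
               tolerance = 1e-12)
  expect_equal(roc$n_cases, 10)
  expect_equal(roc$n_controls, 10)

  # perfectly separating marker
  perfect <- td_roc(times, events, rep(c(5, -5), each = 10), horizon = 1)
  expect_equal(perfect$auc, 1)

  # positive affine transforms change neither the curve nor the AUC
  roc2 <- td_roc(times, events, 3.7 * marker + 11, horizon = 1)
  expect_equal(roc2$auc, roc$auc, tolerance = 1e-12)
  expect_equal(roc2$curve$tpr, roc$curve$tpr)

  expect_error(td_roc(times, events, marker, horizon = 5),
               class = "ph_domain_error", regexp = "5")
})

test_that("an uninformative marker gives AUC near one half", {
  set.seed(74)
  n <- 400
  times <- rexp(n, 0.5)
  events <- as.integer(runif(n) > 0.2)
  marker <- rnorm(n)
  roc <- td_roc(times, events, marker, horizon = 1)
  expect_gt(roc$auc, 0.42)
  expect_lt(roc$auc, 0.58)
  expect_true(roc$auc >= 0 && roc$auc <= 1)
})

test_that("the Youden-optimal cutoff matches an exhaustive search", {
  # engineered so the unique J-maximizing midpoint threshold is exactly 0.35
  marker <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  times <- c(2, 2, 2, 0.5, 0.5, 0.5, 0.5, 0.5)  # cases are the five high markers
  events <- rep(1, 8)
  roc <- td_roc(times, events, marker, horizon = 1)
  finite <- roc$curve[is.finite(roc$curve$threshold), ]
  brute <- finite$threshold[which.max(finite$tpr - finite$fpr)]
  expect_equal(optimal_cutoff(roc), brute)
  expect_equal(optimal_cutoff(roc), 0.35)

  # perfectly separating marker: the cutoff falls in the class gap
  sep <- td_roc(c(rep(0.5, 5), rep(2, 5)), rep(1, 10),
                c(rep(3, 5), rep(-3, 5)), horizon = 1)
  expect_gt(optimal_cutoff(sep), -3)
  expect_lt(optimal_cutoff(sep), 3)
})
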
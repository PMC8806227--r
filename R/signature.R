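#' Construct a gene-pair signature model
#'
#' @param pairs Tibble with columns `gene_hi`, `gene_lo`, `coefficient`
#'   (all coefficients nonzero).
#' @param cutoff Risk-score threshold (`NA` until calibrated).
#' @param horizon ROC evaluation time used for calibration (`NA` until set).
#' @param provenance Free-form list of training metadata (seed, lambda,
#'   screen threshold, ...).
#' @return A `pair_signature` object.
#' @export
pair_signature <- function(pairs, cutoff = NA_real_, horizon = NA_real_,
                           provenance = list()) {
  pairs <- as_tibble(pairs)
  model <- structure(list(
    pairs = dplyr::mutate(pairs,
                          pair = paste(.data$gene_hi, .data$gene_lo, sep = "|"),
                          .before = 1),
    cutoff = as.numeric(cutoff),
    horizon = as.numeric(horizon),
    provenance = provenance
  ), class = "pair_signature")
  validate_pair_signature(model)
  model
}

validate_pair_signature <- function(model) {
  p <- model$pairs
  if (nrow(p) < 1) abort_domain("a signature needs at least one gene pair")
  if (!all(c("gene_hi", "gene_lo", "coefficient") %in% names(p))) {
    abort_format("signature pairs need gene_hi, gene_lo, coefficient")
  }
  if (any(p$gene_hi == p$gene_lo)) abort_domain("a pair cannot repeat one gene")
  if (any(!is.finite(p$coefficient)) || any(p$coefficient == 0)) {
    abort_domain("signature coefficients must be finite and nonzero")
  }
  if (!is.na(model$cutoff) && !is.finite(model$cutoff)) {
    abort_domain("cutoff must be finite")
  }
  invisible(model)
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("Gene-pair signature: %d pair(s); cutoff = %s; horizon = %s\n",
              nrow(x$pairs),
              ifelse(is.na(x$cutoff), "<uncalibrated>", format(x$cutoff)),
              ifelse(is.na(x$horizon), "<unset>", format(x$horizon))))
  print(x$pairs)
  invisible(x)
}

#' @export
tidy.pair_signature <- function(x, ...) x$pairs

#' @export
glance.pair_signature <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs),
         n_unique_genes = length(unique(c(x$pairs$gene_hi, x$pairs$gene_lo))),
         cutoff = x$cutoff, horizon = x$horizon)
}

# intersection of pair-matrix samples and clinical rows, in pair-matrix order
align_pairs_clinical <- function(pairs, clinical) {
  ids <- pair_sample_ids(pairs)
  common <- ids[ids %in% clinical$sample_id]
  if (length(common) == 0) abort_alignment("no shared samples between pair matrix and clinical table")
  scores <- pair_score_matrix(pairs)[, common, drop = FALSE]
  clin <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  list(scores = scores, clinical = clin, sample_ids = common)
}

#' Univariate prognostic screen of gene pairs
#'
#' Fits a single-covariate Cox model to each pair's binary score and keeps
#' pairs with Wald p below `alpha`. For a binary covariate the Cox score
#' test coincides with the log-rank test, so this is the Cox-regression
#' reading of a Kaplan-Meier/log-rank screen. Pairs whose score is constant
#' across samples are skipped as degenerate (`passed = FALSE`).
#'
#' @param pairs A `pair_matrix` tibble.
#' @param clinical Clinical tibble (joined to the pair matrix on the
#'   intersection of sample ids).
#' @param alpha Wald p-value threshold (default 0.05).
#' @return A `screen_result` tibble in input pair order: `pair`, `gene_hi`,
#'   `gene_lo`, `hazard_ratio`, `p_value`, `degenerate`, `passed`.
#' @export
univariate_screen <- function(pairs, clinical, alpha = 0.05) {
  al <- align_pairs_clinical(pairs, clinical)
  y <- survival::Surv(al$clinical$os_time, al$clinical$os_event)
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 50)
  one <- function(x) {
    if (length(unique(x)) < 2) {
      return(c(NA_real_, NA_real_, TRUE))
    }
    fit <- tryCatch(
      suppressWarnings(survival::coxph.fit(
        x = matrix(x, ncol = 1), y = y, strata = NULL, offset = NULL,
        init = 0, control = ctrl, weights = NULL, method = "efron",
        rownames = NULL)),
      error = function(e) NULL)
    if (is.null(fit) || is.na(fit$coefficients[1])) return(c(NA_real_, NA_real_, TRUE))
    beta <- fit$coefficients[1]
    se <- sqrt(fit$var[1, 1])
    c(exp(beta), 2 * stats::pnorm(-abs(beta / se)), FALSE)
  }
  res <- t(apply(al$scores, 1, one))
  out <- tibble(
    pair = pairs$pair,
    gene_hi = pairs$gene_hi,
    gene_lo = pairs$gene_lo,
    hazard_ratio = res[, 1],
    p_value = res[, 2],
    degenerate = as.logical(res[, 3])
  )
  out$passed <- !out$degenerate & !is.na(out$p_value) & out$p_value < alpha
  if (!any(out$passed)) {
    abort_no_signal("empty screen: no gene pair is associated with survival at the chosen alpha")
  }
  class(out) <- c("screen_result", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' LASSO-penalized Cox selection of gene pairs
#'
#' L1-penalized Cox regression over the screened pairs' binary scores on a
#' descending lambda grid; lambda is chosen by `n_folds`-fold cross-validated
#' partial-likelihood deviance at its minimum (`rule = "lambda.min"`, the
#' default) or the one-standard-error rule. Pairs with a zero coefficient at
#' the chosen lambda are dropped. Fold assignment is drawn deterministically
#' from `seed`.
#'
#' @inheritParams univariate_screen
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param rule `"lambda.min"` or `"lambda.1se"`.
#' @param lambda Optional fixed penalty; when supplied, cross-validation is
#'   skipped and coefficients are taken at this lambda (0 = unpenalized).
#' @return An uncalibrated `pair_signature` (no cutoff yet).
#' @export
lasso_cox <- function(pairs, clinical, n_folds = 10, seed = 1L,
                      rule = c("lambda.min", "lambda.1se"), lambda = NULL) {
  rule <- match.arg(rule)
  al <- align_pairs_clinical(pairs, clinical)
  if (nrow(al$scores) < 2) abort_config("lasso_cox needs at least 2 pairs")
  x <- t(al$scores)
  y <- survival::Surv(al$clinical$os_time, al$clinical$os_event)

  if (!is.null(lambda)) {
    grid <- sort(unique(c(exp(seq(log(10), log(1e-3), length.out = 30)), lambda)),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "cox", lambda = grid, thresh = 1e-14,
                          standardize = FALSE)
    beta <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y))
    chosen <- lambda
  } else {
    if (sum(al$clinical$os_event) < n_folds) {
      abort_config("lasso_cox: need at least n_folds events for cross-validation")
    }
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(n_folds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                            standardize = FALSE)
    chosen <- if (rule == "lambda.min") cv$lambda.min else cv$lambda.1se
    beta <- as.numeric(stats::coef(cv, s = chosen))
  }
  keep <- which(beta != 0)
  if (length(keep) == 0) {
    abort_no_signal("no signal: every LASSO coefficient is zero at the chosen lambda")
  }
  pair_signature(
    tibble(gene_hi = pairs$gene_hi[keep],
           gene_lo = pairs$gene_lo[keep],
           coefficient = beta[keep]),
    provenance = list(seed = seed, lambda = chosen, rule = rule,
                      n_folds = n_folds, n_input_pairs = nrow(pairs))
  )
}

#' Per-sample prognostic risk scores
#'
#' The risk score is the dot product of a sample's binary pair scores with
#' the signature coefficients. When the model carries a calibrated cutoff,
#' samples are grouped: score strictly above the cutoff is `"high"`,
#' at-or-below is `"low"`.
#'
#' @param model A `pair_signature`.
#' @param pairs A `pair_matrix` built with the same pair definitions.
#' @return A `risk_profile` tibble: `sample_id`, `risk_score` (and `group`
#'   when the model is calibrated).
#' @export
risk_scores <- function(model, pairs) {
  stopifnot(inherits(model, "pair_signature"))
  m <- pair_score_matrix(pairs)
  missing_pairs <- setdiff(model$pairs$pair, rownames(m))
  if (length(missing_pairs) > 0) {
    abort_lookup(paste0("pair(s) missing from score matrix: ",
                        paste(missing_pairs, collapse = ", ")))
  }
  s <- drop(crossprod(m[model$pairs$pair, , drop = FALSE],
                      model$pairs$coefficient))
  out <- tibble(sample_id = colnames(m), risk_score = unname(s))
  if (!is.na(model$cutoff)) {
    out$group <- ifelse(out$risk_score > model$cutoff, "high", "low")
  }
  class(out) <- c("risk_profile", class(out))
  out
}

#' Calibrate the risk-score cutoff by time-dependent ROC
#'
#' Computes training-cohort risk scores, builds the IPCW cumulative/dynamic
#' ROC at `horizon`, and stores the Youden-optimal threshold in the model.
#' `horizon` must be in the clinical table's time unit.
#'
#' @inheritParams risk_scores
#' @param clinical Clinical tibble for the training cohort.
#' @param horizon ROC evaluation time (e.g. 1 for 1-year survival when times
#'   are in years).
#' @return The model with `cutoff` and `horizon` set; the training ROC is
#'   attached as attribute `"roc"`.
#' @export
calibrate_cutoff <- function(model, pairs, clinical, horizon) {
  al <- align_pairs_clinical(pairs, clinical)
  profile <- risk_scores(model, pairs)
  profile <- profile[match(al$sample_ids, profile$sample_id), , drop = FALSE]
  roc <- td_roc(al$clinical$os_time, al$clinical$os_event,
                profile$risk_score, horizon)
  model$cutoff <- optimal_cutoff(roc)
  model$horizon <- horizon
  model$provenance$training_auc <- roc$auc
  attr(model, "roc") <- roc
  validate_pair_signature(model)
  model
}

#' Train a gene-pair signature end to end
#'
#' Convenience wrapper: univariate screen, LASSO-Cox selection over the
#' passing pairs, then ROC cutoff calibration at `horizon`.
#'
#' @inheritParams univariate_screen
#' @inheritParams lasso_cox
#' @inheritParams calibrate_cutoff
#' @return A list: `model` (calibrated `pair_signature`), `screen`
#'   (screen table), `profile` (training risk profile).
#' @export
train_signature <- function(pairs, clinical, alpha = 0.05, n_folds = 10,
                            seed = 1L, horizon = 1,
                            rule = c("lambda.min", "lambda.1se")) {
  rule <- match.arg(rule)
  screen <- univariate_screen(pairs, clinical, alpha = alpha)
  passed <- pairs[screen$passed, , drop = FALSE]
  if (nrow(passed) < 2) abort_no_signal("fewer than 2 pairs pass the screen; cannot run LASSO")
  model <- lasso_cox(passed, clinical, n_folds = n_folds, seed = seed, rule = rule)
  model$provenance$screen_alpha <- alpha
  model$provenance$n_screened <- sum(screen$passed)
  model <- calibrate_cutoff(model, pairs, clinical, horizon = horizon)
  list(model = model, screen = screen, profile = risk_scores(model, pairs))
}

#' Frozen-cutoff validation in an external cohort
#'
#' Applies the trained signature to a validation cohort: risk scores from
#' the same pair definitions, groups by the *frozen* training cutoff (never
#' re-calibrated), then log-rank test, Cox hazard ratio of high vs low, and
#' IPCW ROC AUCs at `horizons` (default 1x, 3x, 5x the model horizon).
#'
#' @param model Calibrated `pair_signature`.
#' @param pairs2 `pair_matrix` of the validation cohort (same pair list).
#' @param clinical2 Validation clinical tibble.
#' @param horizons AUC evaluation times.
#' @return A `signature_validation` list: `profile`, `group_sizes`,
#'   `logrank`, `cox` (high-vs-low `cox_fit`, `NULL` if a group is empty),
#'   `km` (grouped curve), `auc` tibble, `notes`.
#' @export
validate_signature <- function(model, pairs2, clinical2, horizons = NULL) {
  stopifnot(inherits(model, "pair_signature"))
  if (is.na(model$cutoff)) abort_config("validate_signature: model has no calibrated cutoff")
  horizons <- horizons %||% (model$horizon * c(1, 3, 5))
  al <- align_pairs_clinical(pairs2, clinical2)
  profile <- risk_scores(model, pairs2)
  profile <- profile[match(al$sample_ids, profile$sample_id), , drop = FALSE]
  grp <- profile$group
  sizes <- c(high = sum(grp == "high"), low = sum(grp == "low"))
  notes <- character(0)

  if (any(sizes == 0)) {
    notes <- c(notes, sprintf("group '%s' is empty under the frozen cutoff %g; HR and log-rank omitted",
                              names(sizes)[sizes == 0][1], model$cutoff))
    lr <- NULL; cx <- NULL; km <- km_estimate(al$clinical$os_time, al$clinical$os_event)
  } else {
    lr <- logrank_test(al$clinical$os_time, al$clinical$os_event, grp)
    cx <- cox_fit(al$clinical$os_time, al$clinical$os_event,
                  data.frame(high_risk = as.integer(grp == "high")))
    km <- km_estimate(al$clinical$os_time, al$clinical$os_event, grp)
  }
  auc <- purrr::map_dbl(horizons, function(h) {
    tryCatch(td_roc(al$clinical$os_time, al$clinical$os_event,
                    profile$risk_score, h)$auc,
             error = function(e) NA_real_)
  })
  structure(list(
    profile = profile,
    group_sizes = sizes,
    logrank = lr,
    cox = cx,
    km = km,
    auc = tibble(horizon = horizons, auc = auc),
    cutoff = model$cutoff,
    notes = notes
  ), class = "signature_validation")
}

#' @export
print.signature_validation <- function(x, ...) {
  cat(sprintf("Frozen-cutoff validation (cutoff %g): %d high / %d low\n",
              x$cutoff, x$group_sizes["high"], x$group_sizes["low"]))
  if (!is.null(x$logrank)) {
    hr <- x$cox$coefficients
    cat(sprintf("  log-rank p = %.3g; HR(high vs low) = %.2f (%.2f, %.2f)\n",
                x$logrank$p_value, hr$hazard_ratio, hr$conf_low, hr$conf_high))
  }
  for (i in seq_len(nrow(x$auc))) {
    cat(sprintf("  AUC at %g: %.3f\n", x$auc$horizon[i], x$auc$auc[i]))
  }
  for (nte in x$notes) cat("  note:", nte, "\n")
  invisible(x)
}

#' @export
glance.signature_validation <- function(x, ...) {
  tibble(
    n_high = unname(x$group_sizes["high"]),
    n_low = unname(x$group_sizes["low"]),
    logrank_p = if (is.null(x$logrank)) NA_real_ else x$logrank$p_value,
    hazard_ratio = if (is.null(x$cox)) NA_real_ else x$cox$coefficients$hazard_ratio,
    conf_low = if (is.null(x$cox)) NA_real_ else x$cox$coefficients$conf_low,
    conf_high = if (is.null(x$cox)) NA_real_ else x$cox$coefficients$conf_high,
    auc_1x = x$auc$auc[1]
  )
}

#' Risk-group survival analysis within clinical strata
#'
#' Runs the log-rank test and a high-vs-low Cox fit separately inside each
#' level of a clinical stratifier (stage or grade). Strata with fewer than
#' two samples in either risk group are skipped with a note, never an error.
#'
#' @param profiles `risk_profile` tibble with `group` set.
#' @param clinical Clinical tibble containing the stratifying column.
#' @param stratify_by Column name, `"stage"` or `"grade"` (any ordinal
#'   column present in `clinical` works).
#' @return Tibble: one row per stratum with group sizes, event count,
#'   log-rank statistic/p, HR with CI, and a `note` for skipped strata.
#' @export
subgroup_km <- function(profiles, clinical, stratify_by = c("stage", "grade")) {
  stratify_by <- if (length(stratify_by) > 1) stratify_by[1] else stratify_by
  if (!stratify_by %in% names(clinical)) {
    abort_config(paste0("stratifying column not in clinical table: ", stratify_by))
  }
  dat <- dplyr::inner_join(profiles, clinical, by = "sample_id")
  dat <- dat[!is.na(dat[[stratify_by]]), , drop = FALSE]
  strata <- sort(unique(dat[[stratify_by]]))
  rows <- purrr::map(strata, function(s) {
    d <- dat[dat[[stratify_by]] == s, , drop = FALSE]
    n_high <- sum(d$group == "high"); n_low <- sum(d$group == "low")
    base <- tibble(stratum = as.character(s), n = nrow(d),
                   n_high = n_high, n_low = n_low, n_events = sum(d$os_event),
                   chi_square = NA_real_, p_value = NA_real_,
                   hazard_ratio = NA_real_, conf_low = NA_real_,
                   conf_high = NA_real_, skipped = TRUE, note = "")
    if (n_high < 2 || n_low < 2) {
      base$note <- "skipped: fewer than 2 samples in a risk group"
      return(base)
    }
    lr <- logrank_test(d$os_time, d$os_event, d$group)
    cx <- cox_fit(d$os_time, d$os_event,
                  data.frame(high_risk = as.integer(d$group == "high")))
    base$chi_square <- lr$chi_square
    base$p_value <- lr$p_value
    base$hazard_ratio <- cx$coefficients$hazard_ratio
    base$conf_low <- cx$coefficients$conf_low
    base$conf_high <- cx$coefficients$conf_high
    base$skipped <- FALSE
    base
  })
  dplyr::bind_rows(rows)
}

#' Univariate and multivariable Cox adjustment for clinical covariates
#'
#' Fits one univariate Cox model per requested covariate and for the risk
#' score, then a single multivariable model containing all of them, to ask
#' whether the signature remains prognostic after clinical adjustment.
#' Ordinal stage/grade are used as numeric 1-4; gender is coded male = 1.
#'
#' @param profiles `risk_profile` tibble.
#' @param clinical Clinical tibble with the requested covariates.
#' @param covariates Subset of `c("age", "gender", "grade", "stage")`.
#' @return A list: `univariate` (tibble, one row per term) and
#'   `multivariate` (a `cox_fit`).
#' @export
clinical_cox <- function(profiles, clinical,
                         covariates = c("age", "gender", "grade", "stage")) {
  missing_cov <- setdiff(covariates, names(clinical))
  if (length(missing_cov) > 0) {
    abort_config(paste0("covariate(s) not in clinical table: ",
                        paste(missing_cov, collapse = ", ")))
  }
  dat <- dplyr::inner_join(profiles, clinical, by = "sample_id")
  design <- tibble(.rows = nrow(dat))
  for (cv in covariates) {
    design[[cv]] <- if (cv == "gender") {
      as.integer(tolower(as.character(dat$gender)) %in% c("male", "m", "1"))
    } else {
      as.numeric(dat[[cv]])
    }
  }
  design$risk_score <- dat$risk_score
  keep <- stats::complete.cases(design)
  dat <- dat[keep, , drop = FALSE]
  design <- design[keep, , drop = FALSE]

  uni <- purrr::map(names(design), function(term) {
    fit <- cox_fit(dat$os_time, dat$os_event, design[, term, drop = FALSE])
    dplyr::mutate(fit$coefficients, converged = fit$converged)
  })
  multi <- cox_fit(dat$os_time, dat$os_event, design)
  list(univariate = dplyr::bind_rows(uni), multivariate = multi)
}
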
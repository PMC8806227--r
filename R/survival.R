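check_surv_input <- function(times, events) {
  if (length(times) == 0) abort_domain("empty survival input")
  if (length(times) != length(events)) abort_domain("times and events lengths differ")
  if (any(!is.finite(times)) || any(times <= 0)) abort_domain("times must be finite and > 0")
  if (!all(events %in% c(0, 1))) abort_domain("events must be 0/1")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators (1 = death).
#' @param group Optional grouping vector; when given, one curve per group.
#' @return A `km_curve` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (and `group` when stratified). Censored-only times shrink
#'   the risk set but add no drop in survival.
#' @export
km_estimate <- function(times, events, group = NULL) {
  check_surv_input(times, events)
  if (!is.null(group)) {
    if (length(group) != length(times)) abort_domain("group length differs")
    parts <- split(seq_along(times), group)
    out <- purrr::imap(parts, function(idx, g) {
      dplyr::mutate(km_estimate(times[idx], events[idx]), group = g, .before = 1)
    })
    out <- dplyr::bind_rows(out)
    class(out) <- c("km_curve", class(out))
    return(out)
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Log-rank test between survival groups
#'
#' One-degree-of-freedom (for two groups) chi-square from observed-minus-
#' expected event counts over the shared event times with hypergeometric
#' variance.
#'
#' @inheritParams km_estimate
#' @param group Group labels; at least two non-empty groups.
#' @return One-row tibble: `chi_square`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  check_surv_input(times, events)
  group <- as.character(group)
  if (length(group) != length(times)) abort_domain("group length differs")
  if (length(unique(group)) < 2) abort_domain("log-rank test needs at least two groups")
  d <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(d$n) - 1
  tibble(
    chi_square = unname(d$chisq),
    df = df,
    p_value = stats::pchisq(unname(d$chisq), df = df, lower.tail = FALSE)
  )
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Efron tie handling by default,
#' Breslow available; the two coincide exactly on tie-free data). Hazard
#' ratios are exponentiated coefficients with Wald 95% intervals
#' (coef +/- 1.96 SE). Degenerate problems — no events, collinear or
#' constant covariates, monotone likelihood — are flagged via
#' `converged = FALSE` rather than raised.
#'
#' @inheritParams km_estimate
#' @param covariates Numeric matrix or data frame, samples x covariates.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit` object; see [tidy()] and [glance()] methods.
#' @export
cox_fit <- function(times, events, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_surv_input(times, events)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(times)) abort_domain("covariate rows must match times")
  if (ncol(covariates) == 0) abort_domain("no covariates supplied")
  if (length(times) <= ncol(covariates)) abort_domain("need more samples than covariates")
  terms <- names(covariates)

  degenerate <- function(reason) {
    structure(list(
      coefficients = tibble(
        term = terms, estimate = NA_real_, std_error = NA_real_,
        hazard_ratio = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
        p_value = NA_real_),
      loglik = NA_real_, score_chisq = NA_real_,
      n = length(times), n_events = sum(events),
      ties = ties, converged = FALSE, note = reason, fit = NULL
    ), class = "cox_fit")
  }
  if (sum(events) == 0) return(degenerate("no events: partial likelihood carries no information"))

  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", terms), collapse = " + ")))
  warned <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      survival::coxph(fml, data = dat, ties = ties,
                      control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
      error = function(e) conditionMessage(e)
    ),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (is.character(fit)) return(degenerate(fit))

  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  converged <- !any(is.na(beta)) &&
    !any(grepl("converge|singular|infinite|beta may be infinite", warned, ignore.case = TRUE))
  structure(list(
    coefficients = tibble(
      term = terms,
      estimate = unname(beta),
      std_error = unname(se),
      hazard_ratio = exp(unname(beta)),
      conf_low = exp(unname(beta) - 1.96 * unname(se)),
      conf_high = exp(unname(beta) + 1.96 * unname(se)),
      p_value = 2 * stats::pnorm(-abs(unname(beta) / unname(se)))
    ),
    loglik = fit$loglik[2],
    score_chisq = unname(fit$score),
    n = length(times), n_events = sum(events),
    ties = ties, converged = converged,
    note = if (length(warned)) paste(warned, collapse = "; ") else NA_character_,
    fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n = %d, events = %d, converged = %s\n",
              x$ties, x$n, x$n_events, x$converged))
  print(x$coefficients)
  invisible(x)
}

#' @importFrom stats pnorm
#' @export
tidy.cox_fit <- function(x, ...) x$coefficients

#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, log_partial_likelihood = x$loglik,
         score_chisq = x$score_chisq, ties = x$ties, converged = x$converged)
}

# censoring-survival step function G(t) = P(C > t) and its left limit
censor_survival <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  list(
    at = function(t) {
      idx <- findInterval(t, fit$time)
      ifelse(idx == 0, 1, fit$surv[pmax(idx, 1)])
    },
    left = function(t) {
      # value just before t: last drop strictly below t
      idx <- findInterval(t - .Machine$double.eps^0.5 * pmax(t, 1), fit$time)
      ifelse(idx == 0, 1, fit$surv[pmax(idx, 1)])
    }
  )
}

#' Time-dependent ROC (cumulative/dynamic, IPCW)
#'
#' Cases are subjects with an observed event by `horizon`; controls are
#' subjects still under observation beyond `horizon`. Censoring before the
#' horizon is corrected by inverse-probability-of-censoring weights taken
#' from the Kaplan-Meier estimate of the censoring distribution: a case
#' observed at time t gets weight 1/G(t-), controls weight 1/G(horizon).
#' A sample is called high-risk at threshold c when marker > c; thresholds
#' are midpoints between consecutive distinct marker values (plus the two
#' extremes). AUC is the trapezoid under the (FPR, TPR) polyline.
#'
#' @inheritParams km_estimate
#' @param marker Numeric risk marker (higher = worse prognosis).
#' @param horizon Evaluation time, same unit as `times`.
#' @return A `td_roc` object with `curve` (threshold, tpr, fpr), `auc`,
#'   `horizon`, case/control counts.
#' @export
td_roc <- function(times, events, marker, horizon) {
  check_surv_input(times, events)
  if (length(marker) != length(times)) abort_domain("marker length differs")
  if (any(!is.finite(marker))) abort_domain("marker must be finite")
  if (!is.finite(horizon) || horizon <= 0) abort_domain("horizon must be positive")

  is_case <- times <= horizon & events == 1
  is_control <- times > horizon
  if (!any(is_case) || !any(is_control)) {
    abort_domain(sprintf(
      "time-dependent ROC at horizon %g needs at least one case and one control", horizon))
  }
  G <- censor_survival(times, events)
  w_case <- 1 / pmax(G$left(times[is_case]), .Machine$double.eps)
  w_control <- rep(1 / pmax(G$at(horizon), .Machine$double.eps), sum(is_control))

  mk_case <- marker[is_case]
  mk_control <- marker[is_control]
  uv <- sort(unique(marker))
  mids <- if (length(uv) > 1) (uv[-1] + uv[-length(uv)]) / 2 else uv
  thresholds <- c(Inf, rev(mids), -Inf)
  tpr <- vapply(thresholds, function(c) sum(w_case[mk_case > c]) / sum(w_case), numeric(1))
  fpr <- vapply(thresholds, function(c) sum(w_control[mk_control > c]) / sum(w_control), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)

  structure(list(
    curve = tibble(threshold = thresholds, tpr = tpr, fpr = fpr),
    auc = auc,
    horizon = horizon,
    n_cases = sum(is_case),
    n_controls = sum(is_control),
    marker_median = stats::median(marker),
    variant = "cumulative/dynamic, IPCW"
  ), class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("Time-dependent ROC (%s) at horizon %g: AUC = %.3f (%d cases, %d controls)\n",
              x$variant, x$horizon, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' @export
tidy.td_roc <- function(x, ...) x$curve

#' @export
glance.td_roc <- function(x, ...) {
  tibble(horizon = x$horizon, auc = x$auc,
         n_cases = x$n_cases, n_controls = x$n_controls)
}

#' Youden-optimal threshold of a time-dependent ROC
#'
#' Maximizes J = TPR - FPR over the finite thresholds of the curve; exact
#' ties are broken toward the threshold closest to the marker median.
#'
#' @param roc A [td_roc()] object.
#' @return The selected threshold (scalar).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "td_roc"))
  curve <- roc$curve[is.finite(roc$curve$threshold), , drop = FALSE]
  if (nrow(curve) == 0) return(roc$marker_median)
  j <- curve$tpr - curve$fpr
  best <- which(j > max(j) - 1e-12)
  if (length(best) > 1) {
    best <- best[which.min(abs(curve$threshold[best] - roc$marker_median))]
  }
  curve$threshold[best]
}
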
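#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_point
#'   geom_abline geom_vline geom_boxplot labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  # prepend S(0) = 1 so the step starts at the origin
  pad <- if ("group" %in% names(object)) {
    dplyr::distinct(dplyr::mutate(object[, "group", drop = FALSE],
                                  time = 0, survival = 1))
  } else {
    tibble(time = 0, survival = 1)
  }
  dat <- dplyr::bind_rows(pad, as_tibble(object))
  p <- if ("group" %in% names(dat)) {
    ggplot(dat, aes(x = .data$time, y = .data$survival, colour = .data$group))
  } else {
    ggplot(dat, aes(x = .data$time, y = .data$survival))
  }
  p + geom_step() +
    labs(x = "Time", y = "Survival probability") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    theme_minimal()
}

#' Plot a time-dependent ROC curve
#'
#' @param object A `td_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.td_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("t = %g, AUC = %.3f", object$horizon, object$auc)) +
    theme_minimal()
}

#' Plot the risk-score distribution with the group cutoff
#'
#' @param profiles A `risk_profile` tibble.
#' @param cutoff Optional cutoff to draw as a vertical line.
#' @return A ggplot.
#' @export
plot_risk_distribution <- function(profiles, cutoff = NULL) {
  dat <- dplyr::arrange(as_tibble(profiles), .data$risk_score)
  dat$rank <- seq_len(nrow(dat))
  p <- if ("group" %in% names(dat)) {
    ggplot(dat, aes(x = .data$rank, y = .data$risk_score, colour = .data$group))
  } else {
    ggplot(dat, aes(x = .data$rank, y = .data$risk_score))
  }
  p <- p + geom_point(size = 0.8) +
    labs(x = "Samples (ranked)", y = "Risk score") +
    theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' Plot cell-type fractions by risk group
#'
#' @param results A `deconv_result` tibble.
#' @param profiles A `risk_profile` tibble with `group` set.
#' @return A ggplot (one box per cell type and risk group).
#' @export
plot_deconvolution <- function(results, profiles) {
  cts <- deconv_cell_types(results)
  dat <- dplyr::inner_join(as_tibble(results), as_tibble(profiles), by = "sample_id")
  long <- tidyr::pivot_longer(dat, cols = dplyr::all_of(cts),
                              names_to = "cell_type", values_to = "fraction")
  ggplot(long, aes(x = .data$cell_type, y = .data$fraction, fill = .data$group)) +
    geom_boxplot(outlier.size = 0.5) +
    labs(x = NULL, y = "Estimated fraction") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
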
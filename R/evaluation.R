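#' Pearson correlation with two-sided p value
#'
#' Sample Pearson r with the two-sided p value from the t transform at
#' `n - 2` degrees of freedom. Zero-variance inputs are reported as
#' undefined (`r = NA`, `defined = FALSE`) rather than propagating NaN.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List: `r`, `p`, `n`, `defined`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) < .Machine$double.eps || stats::sd(y) < .Machine$double.eps) {
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, defined = TRUE)
}

correlation_report <- function(feature_tab, ci_tab, approach, alpha = 0.01) {
  merged <- merge(ci_tab[, c("trial_id", "ci")], feature_tab, by = "trial_id")
  dropped <- setdiff(ci_tab$trial_id, merged$trial_id)
  if (length(dropped) > 0L) {
    message(approach, ": ", length(dropped),
            " trial(s) without features excluded listwise")
  }
  feat_cols <- setdiff(colnames(feature_tab), c("trial_id", "condition"))
  rows <- lapply(feat_cols, function(fc) {
    res <- pearson_or_undefined(merged[[fc]], merged$ci)
    data.frame(approach = approach, feature = fc, r = res$r, p = res$p,
               n = res$n, defined = res$defined)
  })
  rep <- do.call(rbind, rows)
  rep$p_bonferroni <- pmin(rep$p * nrow(rep), 1)
  rep$significant <- !is.na(rep$p) & rep$p < alpha
  attr(rep, "alpha") <- alpha
  rep
}

pearson_or_undefined <- function(x, y) {
  if (stats::sd(x, na.rm = TRUE) < .Machine$double.eps ||
      stats::sd(y, na.rm = TRUE) < .Machine$double.eps) {
    return(list(r = NA_real_, p = NA_real_, n = sum(is.finite(x) & is.finite(y)),
                defined = FALSE))
  }
  pearson(x, y)
}

#' Correlate per-trial ERD values with the coupling index
#'
#' One uncorrected Pearson correlation per channel x band (18 for the
#' default montage), plus a Bonferroni-adjusted column. Undefined
#' correlations (zero-variance features) are flagged, not dropped.
#'
#' @param erd_table data.frame with `trial_id` and one column per
#'   channel.band ERD value (as from [spectral_features()]).
#' @param ci_tab data.frame with `trial_id` and `ci`.
#' @param alpha significance threshold (default 0.01, uncorrected).
#' @return Correlation report data.frame: `approach`, `feature`, `r`, `p`,
#'   `n`, `defined`, `p_bonferroni`, `significant`.
#' @export
correlate_erd <- function(erd_table, ci_tab, alpha = 0.01) {
  correlation_report(erd_table, ci_tab, "erd", alpha)
}

#' Correlate per-trial coherence values with the coupling index
#'
#' As [correlate_erd()], over the 6 group x band coherence values.
#'
#' @param coh_table data.frame with `trial_id` and the `group.band`
#'   coherence columns (as from [coherence_table()]).
#' @inheritParams correlate_erd
#' @return Correlation report data.frame.
#' @export
correlate_coherence <- function(coh_table, ci_tab, alpha = 0.01) {
  correlation_report(coh_table, ci_tab, "coherence", alpha)
}

#' Correlate network-predicted with actual coupling index
#'
#' The single multivariate correlation: averaged test-set predictions
#' against the behavioural coupling index across all trials.
#'
#' @param predictions prediction table from [iterate_splits()]
#'   (`trial_id`, `predicted_ci`, ...).
#' @param ci_tab data.frame with `trial_id` and `ci`.
#' @param alpha significance threshold.
#' @return Correlation report with one row (`feature = "predicted_ci"`).
#' @export
evaluate_ann <- function(predictions, ci_tab, alpha = 0.01) {
  merged <- merge(ci_tab[, c("trial_id", "ci")], predictions, by = "trial_id")
  if (nrow(merged) < nrow(ci_tab) || anyNA(merged$predicted_ci)) {
    stop("every trial must have an averaged prediction", call. = FALSE)
  }
  correlation_report(merged[, c("trial_id", "predicted_ci")],
                     ci_tab, "ann", alpha)
}

#' Scatter plot of predicted vs actual coupling index
#'
#' @param predictions prediction table from [iterate_splits()].
#' @param main plot title.
#' @return Invisibly, the fitted regression line coefficients.
#' @export
plot_ann_fit <- function(predictions, main = "ANN-estimated vs actual CI") {
  graphics::plot(predictions$ci, predictions$predicted_ci,
                 xlab = "actual CI", ylab = "estimated CI",
                 pch = 16, col = "grey30", main = main)
  fit <- stats::lm(predicted_ci ~ ci, data = predictions)
  graphics::abline(fit, col = "red", lwd = 2)
  invisible(stats::coef(fit))
}

#' Compare the univariate, coherence and multivariate approaches
#'
#' Descriptive summary per approach: maximum absolute correlation, number
#' of (uncorrected) significant features, and whether the network's single
#' r exceeds the best absolute correlation of every other approach.
#'
#' @param reports list of correlation reports (at least 2), e.g. from
#'   [correlate_erd()], [correlate_coherence()], [evaluate_ann()].
#' @return data.frame: `approach`, `n_features`, `max_abs_r`,
#'   `n_significant`, `ann_beats_this` (for non-ann rows).
#' @export
compare_approaches <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports", call. = FALSE)
  tab <- do.call(rbind, lapply(reports, function(rep) {
    data.frame(approach = rep$approach[1],
               n_features = nrow(rep),
               max_abs_r = suppressWarnings(max(abs(rep$r), na.rm = TRUE)),
               n_significant = sum(rep$significant, na.rm = TRUE))
  }))
  rownames(tab) <- NULL
  ann_r <- tab$max_abs_r[tab$approach == "ann"]
  tab$ann_beats_this <- if (length(ann_r) == 1L) {
    ifelse(tab$approach == "ann", NA, ann_r > tab$max_abs_r)
  } else {
    NA
  }
  tab
}

#' Permutation null bound for the maximum absolute correlation
#'
#' The 95th (or requested) percentile of the null distribution of
#' `max_j |cor(feature_j, ci)|` over all features, obtained by permuting
#' the coupling index across trials. Controls the familywise rate for the
#' "does any univariate feature correlate?" question.
#'
#' @param feature_mat trials x features numeric matrix.
#' @param ci per-trial coupling index.
#' @param n_perm number of permutations.
#' @param prob percentile (default 0.95).
#' @param seed optional RNG seed.
#' @return Scalar bound on `max |r|` under the null.
#' @export
perm_null_max_abs_r <- function(feature_mat, ci, n_perm = 2000, prob = 0.95,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- scale(as.matrix(feature_mat))
  keep <- apply(X, 2, function(col) all(is.finite(col)))
  X <- X[, keep, drop = FALSE]
  n <- nrow(X)
  maxima <- vapply(seq_len(n_perm), function(b) {
    z <- scale(ci[sample.int(n)])
    max(abs(crossprod(X, z) / (n - 1)))
  }, numeric(1))
  as.numeric(stats::quantile(maxima, prob))
}
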
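#' Univariate ordinary least squares fit
#'
#' Fits `y = intercept + slope * x` and reports the coefficient of
#' determination. Used for the cohort correlation analysis of fractional
#' LVEF against each SCG-derived index.
#'
#' @param x predictor values (finite, non-constant).
#' @param y response values (LVEF as a fraction in the cohort analysis).
#' @return A list of class `scg_linear_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) {
    scg_abort("x and y must have the same length", "scg_parameter_error")
  }
  if (length(x) < 3L) {
    scg_abort("need at least 3 points", "scg_parameter_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    scg_abort("x and y must be finite", "scg_parameter_error")
  }
  if (var(x) == 0) {
    scg_abort("predictor has zero variance", "scg_parameter_error")
  }
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n = length(x)),
    class = "scg_linear_fit"
  )
}

#' @export
print.scg_linear_fit <- function(x, ...) {
  cat(sprintf("<scg_linear_fit> y = %.4g x + %.4g, R^2 = %.4f, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' ROC analysis of a univariate logistic classifier
#'
#' Fits a univariate logistic GLM (logit link, binomial family) of the
#' positive label on the predictor, scores every subject by the fitted
#' probability, and sweeps all score thresholds to build the ROC curve.
#' Because the logistic score is monotone in the predictor, the AUC equals
#' the rank AUC of the raw predictor with the appropriate sign (the GLM
#' slope orients the score, so a predictor negatively associated with the
#' positive class — LVEF — needs no manual inversion). The optimal
#' operating point maximizes Youden's J = TPR - FPR; its cutoff is
#' reported on the predictor scale.
#'
#' @param predictor numeric predictor values.
#' @param labels class labels (character or factor).
#' @param positive the positive class label.
#' @return A list of class `scg_roc`: `auc`, `curve` (tibble `fpr`, `tpr`,
#'   `score`), `optimal_point` (list `fpr`, `tpr`, `cutoff`),
#'   `positive_label`, `n_pos`, `n_neg`.
#' @export
roc_classify <- function(predictor, labels, positive) {
  labels <- as.character(labels)
  if (length(predictor) != length(labels)) {
    scg_abort("predictor and labels must have the same length",
              "scg_parameter_error")
  }
  y <- as.integer(labels == positive)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    scg_abort("both the positive class and at least one other class must be present",
              "scg_parameter_error")
  }
  # perfect separation makes glm warn about fitted 0/1 probabilities; the
  # scores remain monotone in the predictor, which is all the ROC needs
  fit <- suppressWarnings(glm(y ~ predictor, family = binomial()))
  scores <- unname(fitted(fit))
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  y_sorted <- y[ord]
  p_sorted <- predictor[ord]
  # sweep rule "score >= threshold", collapsing tied scores
  tp <- cumsum(y_sorted)
  fp <- cumsum(1 - y_sorted)
  last_of_tie <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  tpr <- c(0, tp[last_of_tie] / n_pos)
  fpr <- c(0, fp[last_of_tie] / n_neg)
  thr <- c(Inf, s_sorted[last_of_tie])
  pred_at_thr <- c(NA_real_, p_sorted[last_of_tie])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- tpr - fpr
  k <- which.max(j)
  curve <- tibble::tibble(fpr = fpr, tpr = tpr, score = thr)
  structure(
    list(auc = auc, curve = curve,
         optimal_point = list(fpr = fpr[k], tpr = tpr[k],
                              cutoff = pred_at_thr[k]),
         positive_label = positive, n_pos = n_pos, n_neg = n_neg),
    class = "scg_roc"
  )
}

#' @export
print.scg_roc <- function(x, ...) {
  cat(sprintf(
    "<scg_roc> positive = %s (%d/%d), AUC = %.4f, optimal: TPR %.3f FPR %.3f at cutoff %.4g\n",
    x$positive_label, x$n_pos, x$n_pos + x$n_neg, x$auc,
    x$optimal_point$tpr, x$optimal_point$fpr, x$optimal_point$cutoff))
  invisible(x)
}

#' Cohort summary statistics
#'
#' @param records a subject-record table (see [load_table1()]).
#' @return A list of class `scg_cohort_summary`: means and sample SDs of
#'   age, LVEF (percent) and cycles, the cycle total, and sex/disease
#'   counts.
#' @export
cohort_summary <- function(records) {
  if (nrow(records) == 0L) {
    scg_abort("empty cohort", "scg_parameter_error")
  }
  sd0 <- function(x) if (length(x) == 1L) 0 else sd(x)
  structure(
    list(
      n = nrow(records),
      age_mean = mean(records$age), age_sd = sd0(records$age),
      lvef_pct_mean = mean(records$lvef) * 100,
      lvef_pct_sd = sd0(records$lvef) * 100,
      cycles_mean = mean(records$cycles), cycles_sd = sd0(records$cycles),
      cycles_total = sum(records$cycles),
      sex_counts = table(records$sex),
      disease_counts = table(records$disease)
    ),
    class = "scg_cohort_summary"
  )
}

#' @export
print.scg_cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<scg_cohort_summary> n = %d: age %.1f +/- %.1f, LVEF %.1f%% +/- %.1f%%, cycles %.1f +/- %.1f (total %d)\n",
    x$n, x$age_mean, x$age_sd, x$lvef_pct_mean, x$lvef_pct_sd,
    x$cycles_mean, x$cycles_sd, x$cycles_total))
  invisible(x)
}

#' Full cohort validation report
#'
#' Runs the two cohort-level validation analyses on a subject table:
#' (1) univariate linear models of fractional LVEF on the PEP/LVET ratio,
#' the Tei index, and their mean, with R-squared; (2) logistic-GLM ROC
#' classification of HFrEF using four predictors (LVEF itself, PEP/LVET,
#' Tei, and the mean of the two indexes), with AUC and the Youden-optimal
#' operating point. Also includes the cohort summary.
#'
#' @param records a subject-record table (see [load_table1()]).
#' @param positive positive disease label for the ROC analysis.
#' @return A list of class `scg_validation_report`: `fits` (named list of
#'   `scg_linear_fit`), `rocs` (named list of `scg_roc`), `cohort`.
#' @export
run_validation <- function(records, positive = "HFrEF") {
  validate_subject_records(records)
  mean_index <- 0.5 * (records$pep_lvet_avg + records$tei_avg)
  fits <- list(
    pep_lvet = fit_linear(records$pep_lvet_avg, records$lvef),
    tei = fit_linear(records$tei_avg, records$lvef),
    mean_index = fit_linear(mean_index, records$lvef)
  )
  rocs <- list(
    lvef = roc_classify(records$lvef, records$disease, positive),
    pep_lvet = roc_classify(records$pep_lvet_avg, records$disease, positive),
    tei = roc_classify(records$tei_avg, records$disease, positive),
    mean_index = roc_classify(mean_index, records$disease, positive)
  )
  structure(
    list(fits = fits, rocs = rocs, cohort = cohort_summary(records)),
    class = "scg_validation_report"
  )
}

#' Flatten a validation report for serialization
#'
#' @param report an `scg_validation_report`.
#' @return A plain nested list of numbers suitable for
#'   `jsonlite::write_json()`.
#' @export
report_to_list <- function(report) {
  list(
    cohort = list(
      n = report$cohort$n,
      age_mean = report$cohort$age_mean, age_sd = report$cohort$age_sd,
      lvef_pct_mean = report$cohort$lvef_pct_mean,
      lvef_pct_sd = report$cohort$lvef_pct_sd,
      cycles_mean = report$cohort$cycles_mean,
      cycles_sd = report$cohort$cycles_sd,
      cycles_total = report$cohort$cycles_total,
      sex = as.list(report$cohort$sex_counts),
      disease = as.list(report$cohort$disease_counts)
    ),
    linear_models = lapply(report$fits, function(f) {
      list(slope = f$slope, intercept = f$intercept,
           r_squared = f$r_squared, n = f$n)
    }),
    roc_models = lapply(report$rocs, function(r) {
      list(auc = r$auc, tpr = r$optimal_point$tpr, fpr = r$optimal_point$fpr,
           cutoff = r$optimal_point$cutoff)
    })
  )
}

#' @export
print.scg_validation_report <- function(x, ...) {
  print(x$cohort)
  for (nm in names(x$fits)) {
    cat(sprintf("  LVEF ~ %-10s ", nm))
    print(x$fits[[nm]])
  }
  for (nm in names(x$rocs)) {
    cat(sprintf("  ROC %-10s ", nm))
    print(x$rocs[[nm]])
  }
  invisible(x)
}
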
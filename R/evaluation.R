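#' Area under the ROC curve
#'
#' Rank-statistic formulation: the fraction of (positive, negative)
#' patient pairs in which the positive patient scores strictly higher,
#' with ties counted 1/2. Equals the trapezoidal area under the ROC
#' curve.
#'
#' @param score numeric scores.
#' @param label binary labels (1 = positive/MSI).
#' @return A single number in `[0, 1]`.
#' @export
auroc <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.integer(label)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for a patient-level metric
#'
#' Resamples patients with replacement (same n), recomputes the metric on
#' each resample, and reports the `(1 - level) / 2` and
#' `1 - (1 - level) / 2` empirical quantiles. Resamples on which the
#' metric is undefined (e.g. a single-class draw for AUROC) are redrawn,
#' keeping `n_boot` effective draws; if more than half of all attempted
#' draws fail, the interval is declared unattainable.
#'
#' @param score,label patient scores and binary labels.
#' @param metric function `(score, label) -> number`; default [auroc()].
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return List of class `metric_ci`: `point`, `lower`, `upper`,
#'   `n_boot`, `level`, `seed`, `n_redrawn`.
#' @export
bootstrap_ci <- function(score, label, metric = auroc, n_boot = 1000,
                         level = 0.95, seed = 1L) {
  stopifnot(length(score) == length(label), n_boot >= 1, level > 0, level < 1)
  point <- metric(score, label)
  n <- length(score)
  stats <- numeric(n_boot)
  redrawn <- 0L
  with_local_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(metric(score[idx], label[idx]), error = function(e) NA_real_)
        if (!is.na(val)) break
        redrawn <- redrawn + 1L
        if (redrawn > n_boot)
          stop("metric undefined on more than half of the bootstrap ",
               "resamples; confidence interval unattainable", call. = FALSE)
      }
      stats[b] <- val
    }
  })
  q <- stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  if (point < q[1] || point > q[2])
    message("percentile CI does not contain the point estimate ",
            "(possible on skewed resampling distributions)")
  structure(list(point = point, lower = q[1], upper = q[2],
                 n_boot = as.integer(n_boot), level = level,
                 seed = as.integer(seed), n_redrawn = redrawn),
            class = "metric_ci")
}

#' @export
print.metric_ci <- function(x, ...) {
  cat(sprintf("%.3f (%.0f%% CI %.3f-%.3f, %d resamples)\n", x$point,
              100 * x$level, x$lower, x$upper, x$n_boot))
  invisible(x)
}

#' Triage confusion statistics from raw counts
#'
#' Computes the full set of pre-screening metrics from the four
#' confusion-matrix counts, with MSI/dMMR as the positive class:
#' sensitivity, specificity, PPV, NPV, F1, the rule-out fraction
#' `tn / n` (patients safely excluded from confirmatory molecular
#' testing) and the false-negative fraction `fn / n` (MSI patients the
#' pre-screen would miss). Internally all values are proportions;
#' [format_confusion()] renders the percentage scale.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return An object of class `confusion_stats`.
#' @export
confusion_stats <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  n <- tp + fp + tn + fn
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    ruleout_fraction = tn / n,
    fn_fraction = fn / n), class = "confusion_stats")
}

#' Confusion statistics of a threshold policy on a scored cohort
#'
#' Predicts MSI/dMMR for every patient with `score >= policy$value` and
#' tabulates against the labels.
#'
#' @param score patient scores.
#' @param label binary labels (1 = MSI/dMMR).
#' @param policy a [threshold_policy()] or a bare numeric threshold.
#' @return A [confusion_stats()] object.
#' @export
confusion_at <- function(score, label, policy) {
  stopifnot(length(score) == length(label), length(score) > 0)
  value <- if (inherits(policy, "threshold_policy")) policy$value
           else as.numeric(policy)
  pred <- score >= value
  label <- as.integer(label) == 1L
  confusion_stats(tp = sum(pred & label), fp = sum(pred & !label),
                  tn = sum(!pred & !label), fn = sum(!pred & label))
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf(paste0("<confusion_stats> n=%d  TP=%d FP=%d TN=%d FN=%d\n",
                     "  sens %.1f%%  spec %.1f%%  PPV %.1f%%  NPV %.1f%%  ",
                     "F1 %.2f\n  rule-out %.1f%%  FN fraction %.2f%%\n"),
              x$n, x$tp, x$fp, x$tn, x$fn, 100 * x$sensitivity,
              100 * x$specificity, 100 * x$ppv, 100 * x$npv, x$f1,
              100 * x$ruleout_fraction, 100 * x$fn_fraction))
  invisible(x)
}

#' Formatted one-row summary of confusion statistics
#'
#' Percentages to one decimal (FN fraction to two, as it is typically
#' well below 1%), matching the conventions of multi-cohort triage
#' reports.
#'
#' @param x a [confusion_stats()].
#' @return One-row data frame of formatted values.
#' @export
format_confusion <- function(x) {
  data.frame(
    n = x$n,
    sensitivity_pct = round(100 * x$sensitivity, 1),
    specificity_pct = round(100 * x$specificity, 1),
    ppv_pct = round(100 * x$ppv, 1),
    npv_pct = round(100 * x$npv, 1),
    ruleout_pct = round(100 * x$ruleout_fraction, 1),
    fn_pct = round(100 * x$fn_fraction, 2),
    f1 = round(x$f1, 2))
}
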
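#' Threshold policy for patient-level rule-in/rule-out decisions
#'
#' A calibrated decision rule: a patient is called MSI/dMMR when their
#' patient-level score is greater than or equal to `value` (so a
#' threshold equal to a positive patient's score counts that patient as
#' detected).
#'
#' @param kind one of `"cohort_specific"`, `"fixed"`, `"learned"`.
#' @param value decision threshold in `[0, 1]`.
#' @param target_sensitivity the sensitivity the calibration aimed for
#'   (`NA` for fixed policies).
#' @param provenance list describing the cohorts/folds that produced the
#'   value.
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(kind, value, target_sensitivity = NA_real_,
                             provenance = list()) {
  kind <- match.arg(kind, c("cohort_specific", "fixed", "learned"))
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0, value <= 1)
  structure(list(kind = kind, value = value,
                 target_sensitivity = target_sensitivity,
                 provenance = provenance),
            class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat(sprintf("<threshold_policy %s> value %.4g%s\n", x$kind, x$value,
              if (is.na(x$target_sensitivity)) ""
              else sprintf(" (target sensitivity %.0f%%)",
                           100 * x$target_sensitivity)))
  invisible(x)
}

#' Cohort-specific threshold at fixed sensitivity
#'
#' Returns the largest threshold `t` such that the sensitivity of the
#' rule "MSI if score >= t" on the calibration set is at least `target`.
#' That threshold equals the k-th largest positive score with
#' `k = ceiling(target * n_pos)`, so the achieved sensitivity on the
#' calibration set is always `>= target`.
#'
#' @param score numeric patient scores.
#' @param label binary patient labels (1 = MSI/dMMR).
#' @param target target sensitivity (default 0.95).
#' @param cohort_id optional identifier recorded in the provenance.
#' @return A [threshold_policy()] of kind `"cohort_specific"`.
#' @export
threshold_at_sensitivity <- function(score, label, target = 0.95,
                                     cohort_id = NA_character_) {
  stopifnot(length(score) == length(label), target > 0, target <= 1)
  pos <- score[label == 1]
  if (length(pos) == 0L)
    stop("cannot calibrate a sensitivity threshold without positive ",
         "(MSI/dMMR) patients", call. = FALSE)
  k <- ceiling(target * length(pos))
  value <- sort(pos, decreasing = TRUE)[k]
  threshold_policy("cohort_specific", value, target_sensitivity = target,
                   provenance = list(cohort_id = cohort_id,
                                     n_pos = length(pos), k = k))
}

#' Fixed global threshold policies
#'
#' The default candidates are 0.25, 0.50 and 0.75, applied unchanged to
#' every cohort.
#'
#' @param values numeric thresholds.
#' @return List of [threshold_policy()] of kind `"fixed"`.
#' @export
fixed_policies <- function(values = c(0.25, 0.50, 0.75)) {
  lapply(values, function(v) threshold_policy("fixed", v))
}

#' Learned threshold from training cohorts
#'
#' For each training cohort, patient-level stratified k-fold
#' cross-validation produces an out-of-fold score for every patient; the
#' cohort's optimal threshold is the fixed-sensitivity threshold
#' ([threshold_at_sensitivity()]) on the pooled out-of-fold scores. The
#' learned value is the unweighted mean of the per-cohort optima.
#'
#' When `score_fn` is `NULL` the cohorts' existing `score` column is used
#' as the out-of-fold score (appropriate when scores come from a fixed,
#' data-independent scorer). Otherwise `score_fn(train_df, test_df)` must
#' return one score per test patient and is called once per fold.
#'
#' @param cohorts list of data frames with columns `patient_id`, `label`,
#'   and (when `score_fn` is `NULL`) `score`.
#' @param folds number of CV folds per cohort (default 3).
#' @param target target sensitivity of the per-cohort optima.
#' @param seed integer seed for fold assignment.
#' @param score_fn optional scoring function, see Details.
#' @return A [threshold_policy()] of kind `"learned"`; the provenance
#'   lists each cohort's optimum.
#' @export
learned_threshold <- function(cohorts, folds = 3, target = 0.95, seed = 1L,
                              score_fn = NULL) {
  stopifnot(length(cohorts) >= 1L)
  optima <- numeric(0)
  ids <- character(0)
  for (i in seq_along(cohorts)) {
    co <- cohorts[[i]]
    cid <- if (!is.null(co$cohort_id)) as.character(co$cohort_id[1])
           else as.character(i)
    npos <- sum(co$label == 1); nneg <- sum(co$label == 0)
    if (npos < folds || nneg < folds) {
      warning("cohort ", cid, " too small to stratify into ", folds,
              " folds; skipped")
      next
    }
    oof <- within_cohort_cv(co, folds = folds, seed = seed + i,
                            score_fn = score_fn)
    pol <- threshold_at_sensitivity(oof$score, oof$label, target = target,
                                    cohort_id = cid)
    optima <- c(optima, pol$value)
    ids <- c(ids, cid)
  }
  if (length(optima) == 0L)
    stop("no usable training cohorts for the learned threshold",
         call. = FALSE)
  threshold_policy("learned", mean(optima), target_sensitivity = target,
                   provenance = list(cohorts = ids, optima = optima,
                                     folds = folds, seed = seed))
}

#' Write / read threshold policies as YAML
#' @param policies a `threshold_policy` or list of them.
#' @param path output YAML path.
#' @return `path` invisibly, or the policy list for the reader.
#' @export
write_policies <- function(policies, path) {
  if (inherits(policies, "threshold_policy")) policies <- list(policies)
  yaml::write_yaml(lapply(policies, unclass), path)
  invisible(path)
}

#' @rdname write_policies
#' @export
read_policies <- function(path) {
  lapply(yaml::read_yaml(path), function(p)
    threshold_policy(p$kind, p$value,
                     target_sensitivity = p$target_sensitivity %||% NA_real_,
                     provenance = p$provenance %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
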
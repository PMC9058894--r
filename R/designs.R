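#' Label-stratified fold assignment
#'
#' Shuffles each class separately and deals patients round-robin into
#' `k` folds, so every fold's prevalence is within one patient of the
#' cohort prevalence and every fold contains positives whenever the
#' cohort has at least `k` of them.
#'
#' @param label binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids (1..k), one per patient.
#' @export
stratified_folds <- function(label, k, seed = 1L) {
  label <- as.integer(label)
  stopifnot(k >= 2, length(label) >= k)
  fold <- integer(length(label))
  with_local_seed(seed, {
    for (cls in unique(label)) {
      idx <- which(label == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Within-cohort patient-level cross-validation
#'
#' Splits one cohort into label-stratified patient-level folds (default
#' threefold) and produces an out-of-fold score for every patient: the
#' scorer is fitted on the other folds and applied to the held-out fold,
#' so no patient is ever scored by a model that saw them.
#'
#' When `train_fn`/`score_fn` are `NULL` the cohort's existing `score`
#' column is returned as the out-of-fold score -- the correct behaviour
#' for a fixed, data-independent scorer, and the entry point used when
#' calibrating thresholds on pre-scored cohorts.
#'
#' @param cohort data frame with `patient_id`, `label`, and either
#'   `score` or the columns consumed by `train_fn`/`score_fn`.
#' @param folds number of folds (default 3).
#' @param seed integer seed for fold assignment.
#' @param train_fn optional `function(train_df) -> model`.
#' @param score_fn optional `function(model, test_df) -> numeric` (or,
#'   when `train_fn` is `NULL`, `function(train_df, test_df) -> numeric`).
#' @return Data frame `patient_id`, `cohort_id`, `label`, `score`,
#'   `fold`; every patient appears exactly once.
#' @export
within_cohort_cv <- function(cohort, folds = 3, seed = 1L,
                             train_fn = NULL, score_fn = NULL) {
  stopifnot(nrow(cohort) >= folds)
  if (sum(cohort$label == 1) < folds || sum(cohort$label == 0) < folds)
    stop("cohort needs at least ", folds, " patients of each class for ",
         "stratified ", folds, "-fold cross-validation", call. = FALSE)
  fold <- stratified_folds(cohort$label, folds, seed = seed)
  score <- rep(NA_real_, nrow(cohort))
  for (f in seq_len(folds)) {
    test <- fold == f
    if (is.null(train_fn) && is.null(score_fn)) {
      score[test] <- cohort$score[test]
    } else if (is.null(train_fn)) {
      score[test] <- score_fn(cohort[!test, , drop = FALSE],
                              cohort[test, , drop = FALSE])
    } else {
      model <- train_fn(cohort[!test, , drop = FALSE])
      score[test] <- score_fn(model, cohort[test, , drop = FALSE])
    }
  }
  stopifnot(!anyNA(score))
  data.frame(patient_id = as.character(cohort$patient_id),
             cohort_id = as.character(
               if (!is.null(cohort$cohort_id)) cohort$cohort_id else NA),
             label = as.integer(cohort$label),
             score = score, fold = fold, stringsAsFactors = FALSE)
}

#' Leave-one-cohort-out external validation
#'
#' For each cohort in turn: fit a scorer on the union of all other
#' cohorts, score every patient of the held-out cohort exactly once,
#' then evaluate three threshold strategies on the held-out scores --
#' the cohort-specific threshold calibrated at fixed sensitivity on the
#' held-out set itself, the fixed global thresholds, and the learned
#' threshold averaged over within-cohort cross-validated optima of the
#' training cohorts only (the held-out cohort never contributes to its
#' own learned threshold).
#'
#' Train/test patient disjointness is asserted on every fold, and the
#' union of the held-out sets is checked to cover every patient exactly
#' once.
#'
#' @param cohorts named list of cohort data frames (`patient_id`,
#'   `cohort_id`, `label`, plus `score` or scorer inputs).
#' @param train_fn,score_fn scorer plugin, as in [within_cohort_cv()];
#'   `NULL` uses the pre-computed `score` column (data-independent
#'   scorer).
#' @param target target sensitivity for calibrated thresholds.
#' @param fixed numeric fixed thresholds (default 0.25/0.50/0.75).
#' @param folds folds for the learned-threshold inner CV.
#' @param n_boot bootstrap resamples for the AUROC CI.
#' @param seed integer seed.
#' @return List of class `loco_result`: `metrics` (one row per cohort x
#'   policy), `auroc` (per cohort, with CI), `patient_scores`, `models`,
#'   `policies`.
#' @export
leave_one_cohort_out <- function(cohorts, train_fn = NULL, score_fn = NULL,
                                 target = 0.95, fixed = c(0.25, 0.50, 0.75),
                                 folds = 3, n_boot = 1000, seed = 1L) {
  stopifnot(length(cohorts) >= 2L)
  ids <- names(cohorts)
  if (is.null(ids))
    ids <- vapply(cohorts, function(co) as.character(co$cohort_id[1]),
                  character(1))
  all_ids <- unlist(lapply(cohorts, function(co) as.character(co$patient_id)))
  if (anyDuplicated(all_ids))
    stop("patient ids must be unique across cohorts", call. = FALSE)

  metrics <- list(); auroc_rows <- list(); scores_out <- list()
  models <- list(); policies <- list()
  for (i in seq_along(cohorts)) {
    test <- cohorts[[i]]
    train <- do.call(rbind, lapply(cohorts[-i], function(co)
      co[, intersect(names(co), names(test)), drop = FALSE]))
    stopifnot(length(intersect(train$patient_id, test$patient_id)) == 0L)

    if (is.null(train_fn) && is.null(score_fn)) {
      model <- NULL
      sc <- test$score
    } else if (is.null(train_fn)) {
      model <- NULL
      sc <- score_fn(train, test)
    } else {
      model <- train_fn(train)
      sc <- score_fn(model, test)
    }
    held <- data.frame(patient_id = as.character(test$patient_id),
                       cohort_id = ids[i], label = as.integer(test$label),
                       score = sc, stringsAsFactors = FALSE)
    scores_out[[i]] <- held
    models[[i]] <- model

    pols <- list()
    single_class <- length(unique(held$label)) < 2L
    if (any(held$label == 1L))
      pols$cohort_specific <- threshold_at_sensitivity(
        held$score, held$label, target = target, cohort_id = ids[i])
    for (v in fixed) pols[[sprintf("fixed_%.2f", v)]] <- threshold_policy("fixed", v)
    pols$learned <- learned_threshold(
      cohorts[-i], folds = folds, target = target, seed = seed,
      score_fn = if (is.null(train_fn)) score_fn else function(tr, te) {
        score_fn(train_fn(tr), te)
      })
    policies[[ids[i]]] <- pols

    if (!single_class) {
      ci <- bootstrap_ci(held$score, held$label, metric = auroc,
                         n_boot = n_boot, seed = seed + i)
      auroc_rows[[i]] <- data.frame(cohort_id = ids[i], n = nrow(held),
                                    auroc = ci$point, ci_lower = ci$lower,
                                    ci_upper = ci$upper)
    } else {
      auroc_rows[[i]] <- data.frame(cohort_id = ids[i], n = nrow(held),
                                    auroc = NA_real_, ci_lower = NA_real_,
                                    ci_upper = NA_real_)
    }
    for (pn in names(pols)) {
      cs <- confusion_at(held$score, held$label, pols[[pn]])
      metrics[[length(metrics) + 1L]] <- cbind(
        data.frame(cohort_id = ids[i], policy = pn,
                   threshold = pols[[pn]]$value),
        format_confusion(cs))
    }
  }
  pooled <- do.call(rbind, scores_out)
  stopifnot(setequal(pooled$patient_id, all_ids),
            !anyDuplicated(pooled$patient_id))
  structure(list(metrics = do.call(rbind, metrics),
                 auroc = do.call(rbind, auroc_rows),
                 patient_scores = pooled, models = models,
                 policies = policies, seed = as.integer(seed)),
            class = "loco_result")
}

#' @export
print.loco_result <- function(x, ...) {
  cat("<loco_result>", nrow(x$auroc), "held-out cohorts,",
      nrow(x$patient_scores), "patients\n")
  print(x$auroc, row.names = FALSE)
  invisible(x)
}
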
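test_that("fixed-sensitivity threshold matches the exhaustive-scan oracle", {
  score <- c(0.9, 0.7, 0.5, 0.3, 0.2)
  label <- rep(1, 5)
  pol <- threshold_at_sensitivity(score, label, target = 0.8)
  expect_equal(pol$value, 0.3)   # k = ceil(0.8 * 5) = 4th largest
  expect_equal(mean(score >= pol$value), 0.8)
  expect_equal(pol$value, scan_threshold_oracle(score, label, 0.8))
})

test_that("edge targets behave as specified", {
  pos <- c(0.6, 0.4, 0.8)
  expect_equal(threshold_at_sensitivity(pos, rep(1, 3), target = 1)$value,
               min(pos))
  expect_equal(threshold_at_sensitivity(0.6, 1, target = 0.5)$value, 0.6)
  expect_error(threshold_at_sensitivity(c(0.2, 0.3), c(0, 0)),
               "positive")
  # all positive scores equal: degenerate but valid
  expect_equal(threshold_at_sensitivity(rep(0.4, 4), rep(1, 4))$value, 0.4)
})

test_that("calibration achieves the target and is maximal on random cohorts", {
  set.seed(17)
  for (i in 1:25) {
    co <- make_synthetic_cohort(cohort_spec(150, prevalence = 0.25,
                                            cohort_id = "cal"), seed = i)
    pol <- threshold_at_sensitivity(co$score, co$label, target = 0.95)
    sens <- confusion_at(co$score, co$label, pol)$sensitivity
    expect_gte(sens, 0.95)
    expect_equal(pol$value, scan_threshold_oracle(co$score, co$label, 0.95))
    # maximality: any strictly larger achievable threshold misses the target
    larger <- min(co$score[co$label == 1 & co$score > pol$value],
                  Inf)
    if (is.finite(larger))
      expect_lt(confusion_at(co$score, co$label, larger)$sensitivity, 0.95)
  }
})

test_that("raising the target never raises the threshold", {
  co <- make_synthetic_cohort(cohort_spec(200, prevalence = 0.3,
                                          cohort_id = "m"), seed = 2)
  vals <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.95, 1),
                 function(t) threshold_at_sensitivity(co$score, co$label,
                                                      target = t)$value,
                 numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("fixed policies default to 0.25 / 0.50 / 0.75", {
  pols <- fixed_policies()
  expect_equal(vapply(pols, function(p) p$value, numeric(1)),
               c(0.25, 0.50, 0.75))
  expect_true(all(vapply(pols, function(p) p$kind, character(1)) == "fixed"))
  expect_equal(fixed_policies(0.3)[[1]]$value, 0.3)
})

test_that("the learned threshold averages per-cohort optima", {
  # with pre-scored cohorts and no scorer, out-of-fold scores are the
  # scores themselves, so each cohort's optimum is known directly
  mk <- function(id, seed) make_synthetic_cohort(
    cohort_spec(120, prevalence = 0.25, cohort_id = id), seed = seed)
  cohorts <- list(mk("a", 1), mk("b", 2))
  pol <- learned_threshold(cohorts, folds = 3, target = 0.95, seed = 5)
  optima <- vapply(cohorts, function(co)
    threshold_at_sensitivity(co$score, co$label, 0.95)$value, numeric(1))
  expect_equal(pol$value, mean(optima))
  expect_equal(pol$provenance$optima, optima, ignore_attr = TRUE)
  expect_gte(pol$value, min(optima))
  expect_lte(pol$value, max(optima))
  # a single cohort returns its own optimum
  expect_equal(learned_threshold(cohorts[1], seed = 5)$value, optima[1])
})

test_that("homogeneous cohorts give mutually consistent optima", {
  for (s in 1:5) {
    cohorts <- lapply(1:8, function(i) make_synthetic_cohort(
      cohort_spec(3000, prevalence = 0.3, cohort_id = paste0("h", i)),
      seed = 800 * s + i))
    pol <- learned_threshold(cohorts, seed = s)
    expect_true(all(abs(pol$provenance$optima - pol$value) <= 0.05))
  }
})

test_that("unusable cohorts are skipped, empty calibrations error", {
  ok <- make_synthetic_cohort(cohort_spec(120, prevalence = 0.25,
                                          cohort_id = "ok"), seed = 1)
  tiny <- data.frame(patient_id = c("x1", "x2", "x3"), cohort_id = "tiny",
                     label = c(1, 0, 0), score = c(0.8, 0.2, 0.1))
  expect_warning(pol <- learned_threshold(list(ok, tiny), seed = 1),
                 "skipped")
  expect_equal(pol$provenance$cohorts, "ok")
  expect_error(suppressWarnings(learned_threshold(list(tiny))), "no usable")
})

test_that("policies round-trip through YAML", {
  pols <- c(fixed_policies(),
            list(threshold_policy("learned", 0.29, 0.95,
                                  provenance = list(cohorts = c("a", "b")))))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_policies(pols, path)
  back <- read_policies(path)
  expect_equal(vapply(back, function(p) p$value, numeric(1)),
               vapply(pols, function(p) p$value, numeric(1)))
  expect_equal(back[[4]]$kind, "learned")
})
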
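write_manifest <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("a valid manifest assembles cohorts", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(data.frame(
    patient_id = c("p1", "p2", "p3"), cohort_id = "A", label = c(1, 0, 0),
    slide_path = "none.png"), path)
  man <- read_manifest(path, check_files = FALSE)
  expect_length(man$cohorts, 1L)
  expect_equal(nrow(man$cohorts$A), 3L)
  expect_equal(man$n_kept, 3L)
  expect_equal(nrow(man$exclusions), 0L)
})

test_that("rows with missing labels or images are excluded and counted", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(data.frame(
    patient_id = c("p1", "p2", "p3"), cohort_id = "A",
    label = c(1, NA, 0), slide_path = "none.png"), path)
  man <- read_manifest(path, check_files = FALSE)
  expect_equal(man$n_kept, 2L)
  expect_equal(man$exclusions$patient_id, "p2")
  expect_match(man$exclusions$reason, "label")
  # with file checking on, the remaining rows drop too (image missing)
  man2 <- read_manifest(path, check_files = TRUE)
  expect_equal(man2$n_kept, 0L)
  expect_equal(man2$n_input, nrow(man2$exclusions) + man2$n_kept)
})

test_that("schema violations are hard errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(data.frame(patient_id = "p1", cohort_id = "A", label = 1),
                 path)
  expect_error(read_manifest(path), "slide_path")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_manifest(data.frame(
    patient_id = c("p1", "p1"), cohort_id = c("A", "B"), label = c(1, 0),
    slide_path = "x.png"), path2)
  expect_error(read_manifest(path2, check_files = FALSE), "duplicate")
})

test_that("result bundles round-trip and re-runs are byte-identical", {
  cohorts <- lapply(1:3, function(i) make_synthetic_cohort(
    cohort_spec(40, prevalence = 0.25, cohort_id = paste0("w", i)),
    seed = 20 + i))
  names(cohorts) <- paste0("w", 1:3)
  res <- leave_one_cohort_out(cohorts, n_boot = 30, seed = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_results(res, d1)
  back <- utils::read.csv(file.path(d1, "patient_scores.csv"),
                          colClasses = c(patient_id = "character"))
  expect_equal(back$score, res$patient_scores$score)
  expect_equal(back$patient_id, res$patient_scores$patient_id)
  summary <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_equal(summary$n_patients, 120L)
  expect_true(nzchar(summary$config_hash))
  # determinism audit: identical run, byte-identical outputs
  res2 <- leave_one_cohort_out(cohorts, n_boot = 30, seed = 6)
  write_results(res2, d2)
  for (f in c("metrics.csv", "auroc.csv", "patient_scores.csv",
              "policies.yaml", "summary.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("run configs validate fields and apply defaults", {
  cfg <- read_run_config()
  expect_equal(cfg$qc_threshold, 4)
  expect_equal(cfg$tile_edge_um, 256)
  expect_equal(cfg$fixed_thresholds, c(0.25, 0.5, 0.75))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(qc_threshold = 2, seed = 9), path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$qc_threshold, 2)
  expect_equal(cfg2$seed, 9)
  yaml::write_yaml(list(bogus = 1), path)
  expect_error(read_run_config(path), "unknown config")
})

test_that("slides score end to end through a manifest", {
  dir <- withr::local_tempdir()
  mpath <- make_synthetic_study(dir, n_cohorts = 1, patients_per_cohort = 4,
                                size_px = 128, seed = 30)
  man <- read_manifest(mpath)
  cfg <- read_run_config()
  cfg$tile_edge_um <- 64; cfg$out_edge_px <- 64
  m <- mock_scorer(function(px) mean(rgb_to_gray(px) < 150))
  out <- score_manifest_cohort(man$cohorts[[1]], m, cfg)
  expect_equal(nrow(out$scores) + nrow(out$exclusions), 4L)
  expect_true(all(out$scores$score >= 0 & out$scores$score <= 1))
  expect_true(all(out$scores$n_tiles >= 1))
})
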
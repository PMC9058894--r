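test_that("slide generation is a pure function of spec and seed", {
  a <- make_synthetic_slide(texture_spec(1), 96, 1, seed = 4)$slide
  b <- make_synthetic_slide(texture_spec(1), 96, 1, seed = 4)$slide
  expect_identical(a$pixels, b$pixels)
  c <- make_synthetic_slide(texture_spec(1), 96, 1, seed = 5)$slide
  expect_false(identical(a$pixels, c$pixels))
})

test_that("zero density gives a blank slide whose tiles all fail QC", {
  blank <- make_synthetic_slide(texture_spec(0, density = 0), 128, 1,
                                seed = 1)$slide
  expect_true(all(blank$pixels >= 250))
  qc <- qc_filter(tessellate(blank, 64, 64), threshold = 4)
  expect_length(qc$kept, 0L)
})

test_that("cohort prevalence follows the binomial model", {
  co <- make_synthetic_cohort(cohort_spec(1000, prevalence = 0.12,
                                          cohort_id = "prev"), seed = 7)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.12)
  expect_gte(sum(co$label), bounds[1])
  expect_lte(sum(co$label), bounds[2])
})

test_that("identical class models give null AUROC at large n", {
  co <- make_synthetic_cohort(
    cohort_spec(2000, prevalence = 0.12, beta_pos = c(2, 2),
                beta_neg = c(2, 2), cohort_id = "null"), seed = 11)
  n1 <- sum(co$label); n0 <- sum(1 - co$label)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(auroc(co$score, co$label) - 0.5), 3 * se)
})

test_that("empirical AUROC matches the closed-form generating model", {
  a <- beta_model_auroc(c(8, 2), c(2, 8))
  co <- make_synthetic_cohort(
    cohort_spec(2000, prevalence = 0.12, beta_pos = c(8, 2),
                beta_neg = c(2, 8), cohort_id = "sep"), seed = 13)
  n1 <- sum(co$label); n0 <- sum(1 - co$label)
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                (n0 - 1) * (q2 - a^2)) / (n1 * n0))
  expect_lt(abs(auroc(co$score, co$label) - a), 3 * se)
  # default generator sits in the ~0.9 AUROC regime
  expect_equal(beta_model_auroc(), 0.8968254, tolerance = 1e-6)
})

test_that("class-conditional scores follow their Beta models", {
  co <- make_synthetic_cohort(cohort_spec(5000, prevalence = 0.12,
                                          cohort_id = "ks"), seed = 17)
  expect_gt(suppressWarnings(
    stats::ks.test(co$score[co$label == 1], stats::pbeta, 4, 2))$p.value,
    0.01)
  expect_gt(suppressWarnings(
    stats::ks.test(co$score[co$label == 0], stats::pbeta, 2, 4))$p.value,
    0.01)
})

test_that("the two texture classes are separable by a texture statistic", {
  # 128-um tiles: large enough to hold a whole gland-like ring
  t0 <- mk_texture_tiles(0, n_slides = 6, seed0 = 400, slide_px = 256,
                         tile_um = 128)
  t1 <- mk_texture_tiles(1, n_slides = 6, seed0 = 500, slide_px = 256,
                         tile_um = 128)
  # mock texture-statistic scorer: mean connected-component area of the
  # dark (nucleus-like) mask -- small discs vs large rings are disjoint
  m <- mock_scorer(function(px) {
    dark <- rgb_to_gray(px) < 150
    if (!any(dark)) return(0.5)
    sizes <- tabulate(EBImage::bwlabel(dark))
    exp(-mean(sizes) / 300)   # small structures -> high MSI-like score
  })
  p <- score_tiles(m, c(t0, t1))
  expect_gte(auroc(p, rep(0:1, c(length(t0), length(t1)))), 0.95)
})

test_that("artifact injection behaves at its extremes", {
  sl <- make_synthetic_slide(texture_spec(0), 96, 1, seed = 21)$slide
  expect_identical(inject_artifacts(sl, "blur", severity = 0)$pixels,
                   sl$pixels)
  expect_error(inject_artifacts(sl, "tear"), "arg")
  f1 <- inject_artifacts(sl, "fold", severity = 1, seed = 3)
  f2 <- inject_artifacts(sl, "fold", severity = 1, seed = 3)
  expect_identical(f1$pixels, f2$pixels)
  expect_false(identical(f1$pixels, sl$pixels))
})

test_that("normalization moves an overstained slide back toward the target", {
  target <- make_synthetic_slide(texture_spec(0), 128, 1, seed = 22)$slide
  tgt_ctx <- estimate_stain_matrix(target$pixels)
  over <- inject_artifacts(target, "overstain", severity = 0.8)
  src_ctx <- estimate_stain_matrix(over$pixels)
  fixed <- macenko_normalize(over, src_ctx, tgt_ctx)
  d_before <- mean(abs(over$pixels - target$pixels))
  d_after <- mean(abs(fixed$pixels - target$pixels))
  expect_lt(d_after, d_before)
})

test_that("a synthetic study writes a complete, readable bundle", {
  dir <- withr::local_tempdir()
  mpath <- make_synthetic_study(dir, n_cohorts = 2, patients_per_cohort = 4,
                                size_px = 64, seed = 2)
  man <- read_manifest(mpath)
  expect_length(man$cohorts, 2L)
  expect_equal(man$n_kept, 8L)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  sl <- read_slide(man$cohorts[[1]]$slide_path[1],
                   microns_per_pixel = man$cohorts[[1]]$microns_per_pixel[1])
  expect_equal(dim(sl$pixels), c(64, 64, 3))
})
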
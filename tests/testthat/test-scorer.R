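test_that("the per-patient tile cap subsamples without replacement", {
  tiles <- as.list(seq_len(600))
  sub <- sample_patient_tiles(tiles, cap = 500, seed = 4)
  expect_length(sub, 500L)
  expect_false(anyDuplicated(unlist(sub)) > 0)
  expect_identical(sample_patient_tiles(tiles, cap = 500, seed = 4), sub)
  # at or below the cap: all tiles, original order
  expect_identical(sample_patient_tiles(as.list(1:300), cap = 500, seed = 1),
                   as.list(1:300))
})

test_that("class balancing undersamples the larger class exactly", {
  tiles <- as.list(seq_len(1400))
  labels <- rep(c(0, 1), c(1000, 400))
  b <- balance_training_tiles(tiles, labels, seed = 2)
  expect_equal(as.vector(table(b$labels)), c(400, 400))
  expect_false(anyDuplicated(unlist(b$tiles)) > 0)
  # equal classes pass through unchanged
  eq <- balance_training_tiles(as.list(1:10), rep(0:1, each = 5))
  expect_length(eq$tiles, 10L)
  expect_error(balance_training_tiles(as.list(1:5), rep(1, 5)), "non-empty")
})

test_that("undersampling is uniform over the larger class", {
  # selection frequencies of 6 majority tiles picked 3-at-a-time
  counts <- integer(6)
  for (s in 1:600) {
    b <- balance_training_tiles(as.list(1:9), rep(c(0, 1), c(6, 3)), seed = s)
    picked <- unlist(b$tiles)
    counts[picked[picked <= 6]] <- counts[picked[picked <= 6]] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("training separates linearly separable synthetic textures", {
  t0 <- mk_texture_tiles(0, n_slides = 13, seed0 = 0)
  t1 <- mk_texture_tiles(1, n_slides = 13, seed0 = 100)
  tiles <- c(t0, t1)
  labels <- rep(0:1, c(length(t0), length(t1)))
  b <- balance_training_tiles(tiles, labels, seed = 3)
  scorer <- train_tile_scorer(b$tiles, b$labels, desk_scale_config(seed = 7))
  last <- scorer$training_log[nrow(scorer$training_log), ]
  expect_gte(last$accuracy, 0.95)
  p <- score_tiles(scorer, tiles)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(auroc(p, labels), 0.95)
})

test_that("permuted labels carry no signal", {
  t0 <- mk_texture_tiles(0, n_slides = 8, seed0 = 200)
  t1 <- mk_texture_tiles(1, n_slides = 8, seed0 = 300)
  tiles <- c(t0, t1)
  n <- length(tiles)
  aucs <- vapply(1:5, function(s) {
    set.seed(s)
    perm <- sample(rep(0:1, c(length(t0), length(t1))))
    train_idx <- sample(n, round(0.7 * n))
    scorer <- train_tile_scorer(tiles[train_idx], perm[train_idx],
                                desk_scale_config(seed = s, epochs = 20))
    auroc(score_tiles(scorer, tiles[-train_idx]), perm[-train_idx])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("training is deterministic for a fixed seed", {
  tiles <- c(mk_texture_tiles(0, 2, seed0 = 40), mk_texture_tiles(1, 2, seed0 = 50))
  labels <- rep(0:1, each = length(tiles) / 2)
  cfg <- desk_scale_config(seed = 11, epochs = 5, batch_size = 8)
  s1 <- train_tile_scorer(tiles, labels, cfg)
  s2 <- train_tile_scorer(tiles, labels, cfg)
  expect_identical(s1$training_log, s2$training_log)
  expect_identical(s1$weights, s2$weights)
})

test_that("oversized batches shrink with a warning", {
  tiles <- c(mk_texture_tiles(0, 1, seed0 = 60), mk_texture_tiles(1, 1, seed0 = 70))
  labels <- rep(0:1, each = length(tiles) / 2)
  expect_warning(
    train_tile_scorer(tiles, labels,
                      desk_scale_config(seed = 1, epochs = 2,
                                        batch_size = 10000)),
    "shrinking")
})

test_that("the mock scorer is pure and batching-invariant", {
  red <- he_tile(array(rep(c(255, 0, 0), each = 16), c(4, 4, 3)), 0, 0, 4, 4)
  m <- mock_scorer()
  expect_equal(score_tiles(m, list(red)), 1.0)
  tiles <- mk_texture_tiles(1, 1, seed0 = 80)[1:3]
  batch <- score_tiles(m, tiles)
  singles <- vapply(tiles, function(t) score_tiles(m, list(t)), numeric(1))
  expect_identical(batch, singles)
  expect_identical(score_tiles(m, tiles), batch)
})

test_that("scorer configuration validates its invariants", {
  expect_error(scorer_config(epochs = 0), "epochs")
  expect_error(scorer_config(frozen_fraction = 1.5), "frozen_fraction")
  expect_error(scorer_config(input_px = 4), "input_px")
  cfg <- scorer_config()
  expect_equal(cfg$epochs, 5L)
  expect_equal(cfg$batch_size, 1024L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$weight_decay, 1e-5)
  expect_equal(cfg$input_px, 224L)
})
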
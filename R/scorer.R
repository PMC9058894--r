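#' Tile-scorer training configuration
#'
#' The documented defaults are the full transfer-learning recipe: five
#' epochs at mini-batch 1024, learning rate 1e-4, weight decay 1e-5,
#' inputs resized to 224 px, the first half of the backbone frozen. For
#' desk-scale work with the compact built-in backbone use
#' [desk_scale_config()].
#'
#' @param epochs number of passes over the training tiles.
#' @param batch_size mini-batch size (auto-shrunk with a warning when the
#'   training set is smaller).
#' @param learning_rate,weight_decay Adam step size and L2 penalty.
#' @param frozen_fraction fraction of the network (counted from the
#'   input) whose weights are frozen during fine-tuning.
#' @param input_px edge length tiles are resized to before scoring.
#' @param seed integer seed controlling shuffling and initialization.
#' @return An object of class `scorer_config`.
#' @export
scorer_config <- function(epochs = 5, batch_size = 1024,
                          learning_rate = 1e-4, weight_decay = 1e-5,
                          frozen_fraction = 0.5, input_px = 224, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1,
            frozen_fraction >= 0, frozen_fraction <= 1, input_px >= 8)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 frozen_fraction = frozen_fraction,
                 input_px = as.integer(input_px), seed = as.integer(seed)),
            class = "scorer_config")
}

#' Desk-scale configuration for the compact backbone
#'
#' Shrinks the input to 64 px and the batch to 32, and adapts the epoch
#' budget and learning rate to the small trainable head, which converges
#' at far larger steps than a full deep network.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [scorer_config()].
#' @return A `scorer_config`.
#' @export
desk_scale_config <- function(seed = 1L, ...) {
  defaults <- list(epochs = 40, batch_size = 32, learning_rate = 0.05,
                   weight_decay = 1e-5, frozen_fraction = 0.5,
                   input_px = 64, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(scorer_config, args)
}

#' Cap the number of tiles used per patient
#'
#' Patients with more than `cap` tiles contribute a uniform random subset
#' of exactly `cap` tiles (without replacement); patients at or below the
#' cap contribute all tiles in their original order. Reproducible for a
#' fixed seed.
#'
#' @param tiles list of tiles (any objects).
#' @param cap maximal number of tiles per patient (default 500).
#' @param seed integer seed for the subsample.
#' @return Sub-list of `tiles`.
#' @export
sample_patient_tiles <- function(tiles, cap = 500, seed = 1L) {
  stopifnot(cap >= 1)
  if (length(tiles) <= cap) return(tiles)
  idx <- with_local_seed(seed, sample.int(length(tiles), cap))
  tiles[idx]
}

#' Undersample the larger class to balance a training set
#'
#' The more abundant class is randomly undersampled without replacement
#' to the size of the rarer class. Applied to training tiles only; test
#' tiles are never balanced.
#'
#' @param tiles list of tiles.
#' @param labels binary labels (1 = MSI/dMMR, 0 = MSS/pMMR), one per tile.
#' @param seed integer seed.
#' @return List with balanced `tiles` and `labels`.
#' @export
balance_training_tiles <- function(tiles, labels, seed = 1L) {
  stopifnot(length(tiles) == length(labels))
  labels <- as.integer(labels)
  i1 <- which(labels == 1L); i0 <- which(labels == 0L)
  if (length(i1) == 0L || length(i0) == 0L)
    stop("both classes must be non-empty to balance a training set",
         call. = FALSE)
  n <- min(length(i0), length(i1))
  keep <- with_local_seed(seed, {
    sort(c(if (length(i0) > n) sample(i0, n) else i0,
           if (length(i1) > n) sample(i1, n) else i1))
  })
  list(tiles = tiles[keep], labels = labels[keep])
}

# run expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# ---- compact convolutional backbone -----------------------------------

# Fixed random convolution filters play the role of a pretrained, frozen
# feature extractor; only the softmax head is fine-tuned. The filters are
# seeded independently of the training seed so the backbone is identical
# across experiments.
.backbone_filters <- function(n_filters = 8L, size = 7L) {
  with_local_seed(980451L, {
    lapply(seq_len(n_filters), function(i) {
      f <- matrix(stats::rnorm(size * size), size, size)
      f - mean(f)
    })
  })
}

# feature vector of one tile: colour statistics plus pooled responses of
# the frozen convolution bank on the grayscale image
tile_features <- function(pixels, input_px, filters = .backbone_filters()) {
  if (dim(pixels)[1] != input_px) pixels <- resize_rgb(pixels, input_px)
  g <- rgb_to_gray(pixels)
  base <- c(mean(pixels[, , 1]), mean(pixels[, , 2]), mean(pixels[, , 3]),
            stats::sd(pixels[, , 1]), stats::sd(pixels[, , 2]),
            stats::sd(pixels[, , 3]),
            mean(abs(diff(g))), mean(abs(t(diff(t(g))))),
            mean(g < 128))
  conv <- unlist(lapply(filters, function(f) {
    r <- EBImage::filter2(g / 255, f)
    r <- pmax(r, 0)                       # ReLU
    c(mean(r), stats::sd(r))
  }))
  c(base, conv)
}

feature_matrix <- function(tiles, input_px) {
  filters <- .backbone_filters()
  t(vapply(tiles,
           function(tl) tile_features(
             if (inherits(tl, "he_tile")) tl$pixels else tl,
             input_px, filters),
           numeric(9L + 2L * length(filters))))
}

#' Train the tile-level MSI scorer
#'
#' Fine-tunes a two-class softmax head on top of a frozen convolutional
#' feature backbone, with the Adam optimizer, cross-entropy loss, L2
#' weight decay, and mini-batch shuffling controlled by the config seed.
#' The backbone (a fixed, seeded bank of convolution filters plus colour
#' statistics) stands in for a pretrained network's frozen layers; only
#' the head's weights are updated, mirroring a recipe that freezes the
#' first half of a pretrained network and fine-tunes the rest.
#'
#' @param tiles list of training tiles (balanced beforehand with
#'   [balance_training_tiles()]).
#' @param labels binary tile labels (1 = MSI/dMMR).
#' @param config a [scorer_config()]; use [desk_scale_config()] for the
#'   compact backbone.
#' @return An object of class `tile_scorer` with the fitted head, feature
#'   standardization constants, and a training log (`epoch`, `loss`,
#'   `accuracy`).
#' @export
train_tile_scorer <- function(tiles, labels, config = desk_scale_config()) {
  stopifnot(inherits(config, "scorer_config"),
            length(tiles) == length(labels), length(tiles) >= 2L)
  y <- as.integer(labels)
  stopifnot(all(y %in% 0:1))
  x <- feature_matrix(tiles, config$input_px)
  mu <- colMeans(x)
  sig <- apply(x, 2, stats::sd)
  sig[!is.finite(sig) | sig < 1e-8] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sig, "/")

  n <- nrow(xs); d <- ncol(xs)
  bs <- config$batch_size
  if (bs > n) {
    warning("batch size ", bs, " exceeds training set (", n,
            "); shrinking to ", n)
    bs <- n
  }
  w <- numeric(d); b <- 0
  mw <- vw <- numeric(d); mb <- vb <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate; wd <- config$weight_decay
  tlog <- data.frame(epoch = integer(), loss = numeric(),
                    accuracy = numeric())
  step <- 0L
  with_local_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        eta <- drop(xs[idx, , drop = FALSE] %*% w) + b
        p <- 1 / (1 + exp(-eta))
        err <- p - y[idx]
        gw <- drop(crossprod(xs[idx, , drop = FALSE], err)) / length(idx) +
          wd * w
        gb <- mean(err)
        step <- step + 1L
        mw <- beta1 * mw + (1 - beta1) * gw
        vw <- beta2 * vw + (1 - beta2) * gw^2
        mb <- beta1 * mb + (1 - beta1) * gb
        vb <- beta2 * vb + (1 - beta2) * gb^2
        cor1 <- 1 - beta1^step; cor2 <- 1 - beta2^step
        w <- w - lr * (mw / cor1) / (sqrt(vw / cor2) + eps)
        b <- b - lr * (mb / cor1) / (sqrt(vb / cor2) + eps)
      }
      eta <- drop(xs %*% w) + b
      p <- 1 / (1 + exp(-eta))
      loss <- -mean(y * log(pmax(p, 1e-12)) +
                    (1 - y) * log(pmax(1 - p, 1e-12)))
      tlog[ep, ] <- list(ep, loss, mean((p > 0.5) == (y == 1L)))
    }
  })
  structure(list(weights = w, bias = b, feature_mean = mu,
                 feature_sd = sig, config = config, training_log = tlog),
            class = c("tile_scorer", "msi_scorer"))
}

#' @export
print.tile_scorer <- function(x, ...) {
  last <- x$training_log[nrow(x$training_log), ]
  cat(sprintf(paste0("<tile_scorer> %d features, %d epochs ",
                     "(final loss %.4f, accuracy %.3f)\n"),
              length(x$weights), nrow(x$training_log), last$loss,
              last$accuracy))
  invisible(x)
}

#' Deterministic mock scorer
#'
#' Wraps a pure function of a tile's pixel array into the scorer plugin
#' contract, so the aggregation, calibration and study-design stages can
#' be exercised without any training. The default scores a tile by its
#' mean red-channel intensity divided by 255.
#'
#' @param fun function taking an `H x W x 3` pixel array (0--255) and
#'   returning a probability in `[0, 1]`.
#' @return An object of class `mock_scorer`.
#' @export
mock_scorer <- function(fun = function(px) mean(px[, , 1]) / 255) {
  structure(list(fun = fun), class = c("mock_scorer", "msi_scorer"))
}

#' Score tiles with a scorer
#'
#' @param scorer a `tile_scorer` or `mock_scorer`.
#' @param tiles list of [he_tile()] (or pixel arrays).
#' @return Numeric vector of MSI probabilities in `[0, 1]`, one per tile.
#'   Batched evaluation equals per-tile evaluation.
#' @export
score_tiles <- function(scorer, tiles) UseMethod("score_tiles")

#' @export
score_tiles.tile_scorer <- function(scorer, tiles) {
  if (length(tiles) == 0L) return(numeric(0))
  x <- feature_matrix(tiles, scorer$config$input_px)
  xs <- sweep(sweep(x, 2, scorer$feature_mean), 2, scorer$feature_sd, "/")
  p <- 1 / (1 + exp(-(drop(xs %*% scorer$weights) + scorer$bias)))
  pmin(pmax(p, 0), 1)
}

#' @export
score_tiles.mock_scorer <- function(scorer, tiles) {
  if (length(tiles) == 0L) return(numeric(0))
  p <- vapply(tiles, function(tl) {
    px <- if (inherits(tl, "he_tile")) tl$pixels else tl
    scorer$fun(px)
  }, numeric(1))
  if (any(p < 0 | p > 1)) stop("mock scorer returned values outside [0, 1]",
                               call. = FALSE)
  p
}
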
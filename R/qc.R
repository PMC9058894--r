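#' Canny edge map of a grayscale image
#'
#' Classic Canny detector: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' hysteresis thresholding on the gradient magnitude. The result is a
#' binary edge map valued \{0, 255\}, so tile quality thresholds operate
#' on the familiar 0--255 mean scale.
#'
#' Defaults (sigma 1.4, hysteresis 40/100 on 8-bit magnitude) are this
#' package's choices; they are deliberately conservative so that blurred
#' or background tiles produce few or no edges.
#'
#' @param gray numeric matrix of intensities in `[0, 255]`.
#' @param sigma Gaussian smoothing standard deviation, pixels.
#' @param low,high hysteresis thresholds on gradient magnitude.
#' @return Matrix of the same size valued 0 or 255.
#' @export
canny_edges <- function(gray, sigma = 1.4, low = 40, high = 100) {
  stopifnot(is.matrix(gray), low <= high)
  if (min(dim(gray)) < 3L) return(matrix(0, nrow(gray), ncol(gray)))
  sm <- if (sigma > 0) EBImage::gblur(gray, sigma = sigma) else gray

  p <- pad_replicate(sm)
  n <- nrow(sm); m <- ncol(sm)
  ri <- 1 + seq_len(n); ci <- 1 + seq_len(m)
  # 3x3 neighbourhood views of the padded image
  tl <- p[ri - 1, ci - 1]; tc <- p[ri - 1, ci]; tr <- p[ri - 1, ci + 1]
  ml <- p[ri,     ci - 1];                      mr <- p[ri,     ci + 1]
  bl <- p[ri + 1, ci - 1]; bc <- p[ri + 1, ci]; br <- p[ri + 1, ci + 1]
  gx <- (tr + 2 * mr + br) - (tl + 2 * ml + bl)
  gy <- (bl + 2 * bc + br) - (tl + 2 * tc + tr)
  mag <- sqrt(gx^2 + gy^2)

  # non-maximum suppression: compare against the two neighbours along the
  # gradient direction, quantized to 0/45/90/135 degrees
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- matrix(0L, n, m)
  sector[ang >= pi / 8 & ang < 3 * pi / 8] <- 1L
  sector[ang >= 3 * pi / 8 & ang < 5 * pi / 8] <- 2L
  sector[ang >= 5 * pi / 8 & ang < 7 * pi / 8] <- 3L

  pm <- matrix(-Inf, n + 2L, m + 2L)
  pm[ri, ci] <- mag
  nb <- function(dr, dc) pm[ri + dr, ci + dc]
  n1 <- matrix(-Inf, n, m); n2 <- n1
  s0 <- sector == 0L  # horizontal gradient -> left/right neighbours
  n1[s0] <- nb(0L, -1L)[s0]; n2[s0] <- nb(0L, 1L)[s0]
  s1 <- sector == 1L  # 45 degrees
  n1[s1] <- nb(-1L, 1L)[s1]; n2[s1] <- nb(1L, -1L)[s1]
  s2 <- sector == 2L  # vertical gradient -> up/down neighbours
  n1[s2] <- nb(-1L, 0L)[s2]; n2[s2] <- nb(1L, 0L)[s2]
  s3 <- sector == 3L  # 135 degrees
  n1[s3] <- nb(-1L, -1L)[s3]; n2[s3] <- nb(1L, 1L)[s3]
  keep <- mag >= n1 & mag >= n2

  strong <- keep & mag >= high
  weak <- keep & mag >= low
  # hysteresis: grow strong edges into 8-connected weak pixels
  repeat {
    pm[] <- 0
    pm[ri, ci] <- strong
    grown <- weak & (nb(-1L, -1L) | nb(-1L, 0L) | nb(-1L, 1L) |
                     nb(0L, -1L)  | nb(0L, 1L) |
                     nb(1L, -1L)  | nb(1L, 0L) | nb(1L, 1L)) > 0
    grown <- grown | strong
    if (identical(grown, strong)) break
    strong <- grown
  }
  matrix(as.numeric(strong) * 255, n, m)
}

pad_replicate <- function(x) {
  n <- nrow(x); m <- ncol(x)
  p <- matrix(0, n + 2L, m + 2L)
  p[1 + seq_len(n), 1 + seq_len(m)] <- x
  p[1, ] <- p[2, ]; p[n + 2L, ] <- p[n + 1L, ]
  p[, 1] <- p[, 2]; p[, m + 2L] <- p[, m + 1L]
  p
}

#' Grayscale conversion with standard luminance weights
#' @param pixels `H x W x 3` RGB array, 0--255.
#' @return Matrix of intensities, 0--255.
#' @export
rgb_to_gray <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

#' Edge-sharpness score of a tile
#'
#' Mean of the binary (0/255) Canny edge map of the tile's grayscale
#' image. Background and blurred tiles have few detected edges and score
#' near 0; sharp tissue tiles score well above the default quality
#' threshold of 4.
#'
#' @param tile an [he_tile()] or an `H x W x 3` pixel array.
#' @param sigma,low,high Canny parameters, see [canny_edges()].
#' @return A single number in `[0, 255]`.
#' @export
edge_sharpness_score <- function(tile, sigma = 1.4, low = 40, high = 100) {
  px <- if (inherits(tile, "he_tile")) tile$pixels else tile
  mean(canny_edges(rgb_to_gray(px), sigma = sigma, low = low, high = high))
}

#' Quality-control filter on tiles
#'
#' Removes tiles whose mean Canny edge value falls below the threshold
#' (default 4 on the 0--255 scale); a tile scoring exactly at the
#' threshold is kept. Returns the kept tiles together with one QC record
#' per input tile, in input order.
#'
#' @param tiles list of [he_tile()].
#' @param threshold minimal edge-sharpness score to keep a tile.
#' @param sigma,low,high Canny parameters, see [canny_edges()].
#' @return List with elements `kept` (tiles) and `records` (data frame:
#'   `tile`, `edge_score`, `passed`).
#' @export
qc_filter <- function(tiles, threshold = 4, sigma = 1.4, low = 40,
                      high = 100) {
  stopifnot(threshold >= 0)
  scores <- vapply(tiles, edge_sharpness_score, numeric(1),
                   sigma = sigma, low = low, high = high)
  passed <- scores >= threshold
  records <- data.frame(
    tile = vapply(tiles, tile_filename, character(1)),
    edge_score = scores, passed = passed,
    stringsAsFactors = FALSE)
  list(kept = tiles[passed], records = records)
}
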
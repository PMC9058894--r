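#' Stain context: H&E stain matrix and concentration scales
#'
#' Bundles a 3 x 2 optical-density stain matrix (columns = hematoxylin,
#' eosin; unit Euclidean norm, nonnegative components) with robust
#' per-stain concentration scales (99th percentile of the nonnegative
#' unmixed concentrations of the image the context was estimated from).
#'
#' @param stain_matrix 3 x 2 matrix of OD stain vectors.
#' @param max_concentrations length-2 positive vector of concentration
#'   scales.
#' @return An object of class `stain_context`.
#' @export
stain_context <- function(stain_matrix, max_concentrations) {
  stain_matrix <- as.matrix(stain_matrix)
  stopifnot(identical(dim(stain_matrix), c(3L, 2L)),
            all(stain_matrix >= 0),
            length(max_concentrations) == 2L, all(max_concentrations > 0))
  nrm <- sqrt(colSums(stain_matrix^2))
  if (any(nrm == 0)) stop("zero stain vector", call. = FALSE)
  stain_matrix <- sweep(stain_matrix, 2, nrm, "/")
  if (abs(det(crossprod(stain_matrix))) < 1e-10)
    stop("stain vectors are linearly dependent", call. = FALSE)
  structure(list(stain_matrix = stain_matrix,
                 max_concentrations = as.numeric(max_concentrations)),
            class = "stain_context")
}

#' @export
print.stain_context <- function(x, ...) {
  cat("<stain_context>\n  H:", sprintf("%.3f", x$stain_matrix[, 1]),
      "\n  E:", sprintf("%.3f", x$stain_matrix[, 2]),
      "\n  max conc:", sprintf("%.3f", x$max_concentrations), "\n")
  invisible(x)
}

#' Optical density of 8-bit RGB intensities
#'
#' `OD = -log10((I + 1) / 256)` per channel; the +1 offset keeps OD finite
#' at intensity 0. Pure white (255) maps to OD 0.
#'
#' @param pixels array or matrix of intensities, 0--255.
#' @return Same shape, optical densities.
#' @export
rgb_to_od <- function(pixels) -log10((pmax(pixels, 0) + 1) / 256)

od_to_rgb <- function(od) clamp8(round(256 * 10^(-od) - 1))

# pixels as an N x 3 matrix regardless of input shape
flatten_rgb <- function(x) {
  px <- if (inherits(x, c("slide_raster", "he_tile"))) x$pixels else x
  if (length(dim(px)) == 3L) px <- cbind(c(px[, , 1]), c(px[, , 2]), c(px[, , 3]))
  px
}

#' Estimate the stain matrix of an H&E image (Macenko method)
#'
#' Projects the optical-density pixel cloud onto its top-2 principal
#' plane and takes the extreme directions (at the stated angle
#' percentiles) as the two stain vectors. Background pixels -- those with
#' all OD components below `od_floor` -- are discarded before the
#' decomposition. Vectors are sign-corrected to nonnegative OD and
#' ordered so that column 1 is the more blue-absorbing (hematoxylin)
#' vector. Concentration scales are the 99th percentile of the
#' nonnegative-least-squares concentrations over all pixels.
#'
#' @param image a `slide_raster`, `he_tile`, `H x W x 3` array, or
#'   `N x 3` matrix of RGB intensities (0--255).
#' @param od_floor background OD threshold (default 0.15).
#' @param angle_percentile percentile (in percent) for the extreme
#'   angles (default 1, i.e. the 1st and 99th percentile directions).
#' @return A [stain_context()].
#' @export
estimate_stain_matrix <- function(image, od_floor = 0.15,
                                  angle_percentile = 1) {
  rgb <- flatten_rgb(image)
  od <- rgb_to_od(rgb)
  tissue <- od[apply(od, 1, max) >= od_floor, , drop = FALSE]
  if (nrow(tissue) < 2L)
    stop("degenerate stain estimation: fewer than 2 tissue pixels above ",
         "the OD floor", call. = FALSE)
  sv <- svd(tissue, nu = 0)
  # 8-bit quantization leaves ~0.2% residual energy off a rank-1 cloud;
  # genuine two-stain clouds carry >10% in the second direction
  if (sv$d[2] < 0.01 * sv$d[1])
    stop("degenerate stain estimation: optical-density cloud is ",
         "rank-deficient (single dye or blank image)", call. = FALSE)
  v <- sv$v[, 1:2]
  # orient the plane basis toward the data so angles are well defined
  if (sum(tissue %*% v[, 1]) < 0) v[, 1] <- -v[, 1]
  if (sum(tissue %*% v[, 2]) < 0) v[, 2] <- -v[, 2]
  proj <- tissue %*% v
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, c(angle_percentile, 100 - angle_percentile) / 100,
                        names = FALSE)
  vecs <- vapply(qs, function(a) as.numeric(v %*% c(cos(a), sin(a))),
                 numeric(3))
  for (j in 1:2) {
    if (sum(vecs[, j]) < 0) vecs[, j] <- -vecs[, j]
    vecs[vecs[, j] < 0, j] <- 0
    vecs[, j] <- vecs[, j] / sqrt(sum(vecs[, j]^2))
  }
  # hematoxylin absorbs more in the blue channel than eosin
  if (vecs[3, 1] < vecs[3, 2]) vecs <- vecs[, 2:1]
  conc <- nnls_concentrations(vecs, rgb_to_od(rgb))
  maxc <- apply(conc, 2, stats::quantile, probs = 0.99, names = FALSE)
  maxc[maxc <= 0] <- 1e-6
  stain_context(vecs, maxc)
}

# nonnegative least-squares unmixing of an N x 3 OD matrix against a
# 3 x 2 stain matrix; exact for two columns via active-set enumeration
nnls_concentrations <- function(stain_matrix, od) {
  m1 <- stain_matrix[, 1]; m2 <- stain_matrix[, 2]
  g11 <- sum(m1 * m1); g22 <- sum(m2 * m2); g12 <- sum(m1 * m2)
  b1 <- od %*% m1; b2 <- od %*% m2
  det <- g11 * g22 - g12^2
  c1 <- (g22 * b1 - g12 * b2) / det
  c2 <- (g11 * b2 - g12 * b1) / det
  neg1 <- c1 < 0; neg2 <- c2 < 0
  # a negative unconstrained coordinate pins that stain to zero
  c1[neg1] <- 0; c2[neg1] <- pmax(b2[neg1] / g22, 0)
  c2[neg2 & !neg1] <- 0
  c1[neg2 & !neg1] <- pmax(b1[neg2 & !neg1] / g11, 0)
  cbind(h = as.numeric(c1), e = as.numeric(c2))
}

#' Macenko color normalization of a tile
#'
#' Unmixes the tile into stain concentrations under the source context,
#' rescales each stain by the ratio of target to source concentration
#' scales, and recomposes the image with the target stain matrix. The
#' output has the same dimensions, clipped to valid 8-bit RGB. Near-white
#' background carries near-zero concentrations and passes through
#' essentially unchanged.
#'
#' @param tile an [he_tile()], `slide_raster`, or pixel array.
#' @param source [stain_context()] of the image being normalized.
#' @param target [stain_context()] of the normalization target image.
#' @return Object of the same kind as `tile` with normalized pixels.
#' @export
macenko_normalize <- function(tile, source, target) {
  stopifnot(inherits(source, "stain_context"),
            inherits(target, "stain_context"))
  px <- if (inherits(tile, c("slide_raster", "he_tile"))) tile$pixels else tile
  d <- dim(px)
  od <- rgb_to_od(flatten_rgb(px))
  conc <- nnls_concentrations(source$stain_matrix, od)
  conc <- sweep(conc, 2, target$max_concentrations / source$max_concentrations,
                "*")
  out <- od_to_rgb(conc %*% t(target$stain_matrix))
  out <- array(out, d)
  if (inherits(tile, c("slide_raster", "he_tile"))) {
    tile$pixels <- out
    tile
  } else out
}
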
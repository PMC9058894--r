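#' Construct a slide raster
#'
#' A `slide_raster` is the unit of ingestion: an RGB pixel grid with a
#' physical scale. Pixels are stored as an `H x W x 3` numeric array of
#' 8-bit intensities (0--255), indexed `[row, column, channel]` with the
#' origin at the top-left corner.
#'
#' @param pixels `H x W x 3` array of intensities in `[0, 255]`.
#' @param microns_per_pixel physical scale, micrometres per pixel (> 0).
#' @param slide_id,patient_id identifiers carried through the pipeline.
#' @return An object of class `slide_raster`.
#' @export
slide_raster <- function(pixels, microns_per_pixel, slide_id = "slide",
                         patient_id = slide_id) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 RGB array", call. = FALSE)
  if (any(dim(pixels)[1:2] < 1L))
    stop("slide must have at least one pixel per axis", call. = FALSE)
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop("`microns_per_pixel` must be a single finite positive number",
         call. = FALSE)
  structure(
    list(pixels = clamp8(pixels), microns_per_pixel = microns_per_pixel,
         slide_id = as.character(slide_id),
         patient_id = as.character(patient_id)),
    class = "slide_raster")
}

#' @export
print.slide_raster <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_raster '%s'> %d x %d px @ %.3g um/px (patient %s)\n",
              x$slide_id, d[1], d[2], x$microns_per_pixel, x$patient_id))
  invisible(x)
}

#' Construct a tile
#'
#' A square sub-image cut from a slide. `origin_x`/`origin_y` are 0-based
#' pixel offsets of the tile's top-left corner in the source slide
#' (x = column, y = row); the source footprint is the half-open square
#' `[x, x + src_edge_px) x [y, y + src_edge_px)`. `pixels` holds the tile
#' resampled to the configured output edge.
#'
#' @param pixels `E x E x 3` array of 8-bit intensities.
#' @param origin_x,origin_y 0-based offsets in the source slide.
#' @param src_edge_px source-resolution footprint edge, pixels.
#' @param edge_um physical edge length, micrometres.
#' @param slide_id source slide identifier.
#' @return An object of class `he_tile`.
#' @export
he_tile <- function(pixels, origin_x, origin_y, src_edge_px, edge_um,
                    slide_id = "slide") {
  d <- dim(pixels)
  if (length(d) != 3L || d[1] != d[2] || d[3] != 3L)
    stop("tile pixels must be a square E x E x 3 array", call. = FALSE)
  structure(
    list(pixels = pixels, origin_x = as.integer(origin_x),
         origin_y = as.integer(origin_y),
         src_edge_px = as.integer(src_edge_px), edge_um = edge_um,
         slide_id = as.character(slide_id)),
    class = "he_tile")
}

#' @export
print.he_tile <- function(x, ...) {
  cat(sprintf("<he_tile %s_x%d_y%d> %d px (footprint %d px / %g um)\n",
              x$slide_id, x$origin_x, x$origin_y, dim(x$pixels)[1],
              x$src_edge_px, x$edge_um))
  invisible(x)
}

#' Canonical file name of a tile
#' @param tile an `he_tile`.
#' @return e.g. `"slideA_x512_y0.png"`.
#' @export
tile_filename <- function(tile) {
  sprintf("%s_x%d_y%d.png", tile$slide_id, tile$origin_x, tile$origin_y)
}

clamp8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Read a slide raster from a PNG or TIFF file
#'
#' The physical scale is taken from `microns_per_pixel` when supplied
#' (e.g. from a manifest column); otherwise, for TIFF input, it is derived
#' from the image resolution tags. A manifest-supplied value always wins
#' over file metadata.
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @param microns_per_pixel optional explicit scale (overrides metadata).
#' @param slide_id,patient_id identifiers; default from the file name.
#' @return A [slide_raster()].
#' @export
read_slide <- function(path, microns_per_pixel = NULL,
                       slide_id = tools::file_path_sans_ext(basename(path)),
                       patient_id = slide_id) {
  if (!file.exists(path))
    stop("slide image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = is.null(microns_per_pixel))
    if (is.null(microns_per_pixel)) {
      info <- attributes(img)
      # TIFF stores pixels-per-unit; unit 3 = centimetre (10^4 um)
      if (!is.null(info$x.resolution) && isTRUE(info$x.resolution > 0)) {
        unit_um <- if (identical(info$resolution.unit, "cm")) 1e4 else 25400
        microns_per_pixel <- unit_um / info$x.resolution
      }
    }
  } else {
    stop("unsupported slide format: .", ext, call. = FALSE)
  }
  if (is.null(microns_per_pixel))
    stop("no microns-per-pixel metadata for ", path,
         "; supply it explicitly (manifest column `microns_per_pixel`)",
         call. = FALSE)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  slide_raster(round(img * 255), microns_per_pixel, slide_id, patient_id)
}

#' Write a slide or tile as PNG
#' @param x a `slide_raster` or `he_tile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_png_image <- function(x, path) {
  px <- if (inherits(x, c("slide_raster", "he_tile"))) x$pixels else x
  png::writePNG(clamp8(px) / 255, path)
  invisible(path)
}
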
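#' Tessellate a slide into physically sized tiles
#'
#' Cuts a non-overlapping, row-major grid of square tiles of fixed physical
#' edge length from the slide and resamples each to a fixed output edge
#' (bilinear). Partial tiles at the right and bottom margins are dropped,
#' not padded, so every tile carries the same physical footprint.
#'
#' The source footprint is `src_edge_px = round(tile_edge_um /
#' microns_per_pixel)` pixels; the grid has `floor(H / src_edge_px) *
#' floor(W / src_edge_px)` tiles.
#'
#' @param slide a [slide_raster()].
#' @param tile_edge_um physical tile edge, micrometres (default 256).
#' @param out_edge_px saved tile edge, pixels (default 512).
#' @return List of [he_tile()] in row-major order (may be empty, with a
#'   warning, when the footprint exceeds the slide).
#' @export
tessellate <- function(slide, tile_edge_um = 256, out_edge_px = 512) {
  stopifnot(inherits(slide, "slide_raster"))
  mpp <- slide$microns_per_pixel
  src <- as.integer(round(tile_edge_um / mpp))
  if (src < 1L)
    stop("tile footprint smaller than one pixel: ", tile_edge_um, " um at ",
         mpp, " um/px", call. = FALSE)
  d <- dim(slide$pixels)
  ny <- d[1] %/% src
  nx <- d[2] %/% src
  if (ny < 1L || nx < 1L) {
    warning("tile footprint (", src, " px) larger than slide (",
            d[1], " x ", d[2], "); no tiles produced")
    return(list())
  }
  tiles <- vector("list", nx * ny)
  k <- 0L
  for (iy in seq_len(ny) - 1L) {
    for (ix in seq_len(nx) - 1L) {
      sub <- slide$pixels[iy * src + seq_len(src),
                          ix * src + seq_len(src), , drop = FALSE]
      if (src != out_edge_px) sub <- resize_rgb(sub, out_edge_px)
      k <- k + 1L
      tiles[[k]] <- he_tile(sub, origin_x = ix * src, origin_y = iy * src,
                            src_edge_px = src, edge_um = tile_edge_um,
                            slide_id = slide$slide_id)
    }
  }
  tiles
}

# bilinear resize of an H x W x 3 array to edge x edge, 0-255 scale
resize_rgb <- function(px, edge) {
  out <- EBImage::resize(px / 255, w = edge, h = edge, filter = "bilinear")
  clamp8(round(out * 255))
}

#' Grid dimensions of a tessellation
#' @param slide a [slide_raster()].
#' @param tile_edge_um,out_edge_px as in [tessellate()].
#' @return `c(rows, cols, src_edge_px)`.
#' @export
tessellation_grid <- function(slide, tile_edge_um = 256, out_edge_px = 512) {
  src <- as.integer(round(tile_edge_um / slide$microns_per_pixel))
  d <- dim(slide$pixels)
  c(rows = d[1] %/% src, cols = d[2] %/% src, src_edge_px = src)
}
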
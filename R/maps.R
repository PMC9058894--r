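#' Per-tile score grid aligned to the tessellation
#'
#' Arranges tile-level MSI probabilities into the row x column grid of
#' the tessellation. Cells whose tiles were removed by quality control
#' (or never scored) are `NA` and are rendered transparent, so the map
#' never implies a prediction where none was made.
#'
#' @param slide the source [slide_raster()].
#' @param tiles list of scored [he_tile()].
#' @param p_msi tile probabilities, one per tile.
#' @param tile_edge_um physical tile edge used for the tessellation.
#' @return Numeric matrix (rows x cols of the grid) with `NA` for
#'   unscored cells.
#' @export
detection_grid <- function(slide, tiles, p_msi, tile_edge_um = 256) {
  stopifnot(length(tiles) == length(p_msi), all(is.na(p_msi) |
            (p_msi >= 0 & p_msi <= 1)))
  g <- tessellation_grid(slide, tile_edge_um)
  grid <- matrix(NA_real_, g["rows"], g["cols"])
  src <- g["src_edge_px"]
  for (k in seq_along(tiles)) {
    tl <- tiles[[k]]
    if (tl$origin_x %% src != 0 || tl$origin_y %% src != 0 ||
        tl$origin_y / src >= g["rows"] || tl$origin_x / src >= g["cols"])
      stop("tile at (", tl$origin_x, ",", tl$origin_y,
           ") does not align with the tessellation grid", call. = FALSE)
    grid[tl$origin_y / src + 1L, tl$origin_x / src + 1L] <- p_msi[k]
  }
  grid
}

# diverging blue-white-red ramp centred at the tile threshold
.map_ramp <- function(p, center = 0.5) {
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  # rescale so `center` maps to the middle of the ramp
  u <- ifelse(p <= center, p / (2 * center),
              0.5 + (p - center) / (2 * (1 - center)))
  ramp(pmin(pmax(u, 0), 1)) / 255
}

#' Render a tile-wise detection map over a slide thumbnail
#'
#' Alpha-blends a per-cell colour overlay (diverging colormap centred at
#' the tile threshold 0.5: blue = MSS-like, red = MSI-like) onto a
#' thumbnail of the slide and appends a vertical legend bar. QC-removed
#' cells (`NA` in the grid) stay transparent. Purely a visualization:
#' score data are never modified.
#'
#' @param slide the [slide_raster()].
#' @param grid score grid from [detection_grid()].
#' @param cell_px rendered size of one grid cell, pixels (default 16).
#' @param opacity overlay alpha in `[0, 1]` (default 0.55).
#' @param path optional PNG output path; a sidecar CSV of the grid values
#'   is written next to it.
#' @return Invisibly, a list with the overlay array (`H x W x 3`,
#'   0--255) and the grid.
#' @export
render_map <- function(slide, grid, cell_px = 16, opacity = 0.55,
                       path = NULL) {
  stopifnot(opacity >= 0, opacity <= 1)
  h <- nrow(grid) * cell_px; w <- ncol(grid) * cell_px
  thumb <- resize_rgb_rect(slide$pixels, h, w)
  out <- thumb / 255
  for (i in seq_len(nrow(grid))) for (j in seq_len(ncol(grid))) {
    p <- grid[i, j]
    if (is.na(p)) next
    col <- .map_ramp(p)
    ri <- (i - 1L) * cell_px + seq_len(cell_px)
    ci <- (j - 1L) * cell_px + seq_len(cell_px)
    for (ch in 1:3)
      out[ri, ci, ch] <- (1 - opacity) * out[ri, ci, ch] + opacity * col[ch]
  }
  legend <- legend_bar(h, max(8L, cell_px %/% 2L))
  full <- array(0, c(h, w + ncol(legend[, , 1]), 3))
  full[, seq_len(w), ] <- out
  full[, w + seq_len(dim(legend)[2]), ] <- legend
  full <- clamp8(round(full * 255))
  if (!is.null(path)) {
    png::writePNG(full / 255, path)
    utils::write.csv(grid, sub("\\.png$", "_grid.csv", path),
                     row.names = FALSE)
  }
  invisible(list(overlay = full, grid = grid))
}

legend_bar <- function(height, width) {
  p <- seq(1, 0, length.out = height)
  cols <- .map_ramp(p)
  bar <- array(0, c(height, width, 3))
  for (ch in 1:3) bar[, , ch] <- matrix(cols[, ch], height, width)
  bar
}

# bilinear resize to an arbitrary (possibly non-square) target
resize_rgb_rect <- function(px, h, w) {
  out <- EBImage::resize(px / 255, w = h, h = w, filter = "bilinear")
  clamp8(round(out * 255))
}
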
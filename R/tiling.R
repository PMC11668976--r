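#' Construct a tile set
#'
#' Grid-indexed foreground tiles of one slide.  Coordinates are 0-based,
#' `x` is the column axis and `y` the row axis, and pixel bounds are
#' half-open `[x0, x1) x [y0, y1)`, so tiles partition the grid without
#' sharing pixels.
#'
#' @param slide_id identifier.
#' @param tile_size tile edge length in pixels.
#' @param grid_rows,grid_cols grid dimensions.
#' @param tiles data frame with columns `row`, `col`, `x0`, `y0`, `x1`,
#'   `y1`, `tissue_frac` (foreground tiles only, row-major order).
#' @return object of class `tile_set`.
#' @export
tile_set <- function(slide_id, tile_size, grid_rows, grid_cols, tiles) {
  stopifnot(all(c("row", "col", "x0", "y0", "x1", "y1", "tissue_frac")
                %in% names(tiles)))
  if (anyDuplicated(tiles[c("row", "col")])) stop("duplicate (row, col) tiles")
  stopifnot(all(tiles$x1 - tiles$x0 == tile_size),
            all(tiles$y1 - tiles$y0 == tile_size),
            all(tiles$tissue_frac >= 0 & tiles$tissue_frac <= 1))
  structure(list(slide_id = slide_id, tile_size = as.integer(tile_size),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols), tiles = tiles),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat("<tile_set>", x$slide_id, ":", nrow(x$tiles), "foreground tiles on a",
      x$grid_rows, "x", x$grid_cols, "grid, tile_size", x$tile_size, "\n")
  invisible(x)
}

#' Compute a tissue mask for an RGB slide image
#'
#' Tissue is detected on the saturation channel of HSV: a pixel is tissue if
#' its saturation exceeds an Otsu threshold, after which connected components
#' smaller than 0.1% of the image area are removed.  White/near-gray
#' background has near-zero saturation, stained tissue does not, which is the
#' common whole-slide-image foreground heuristic.
#'
#' @param image H x W x 3 array with values in \[0, 1\].
#' @return logical H x W matrix (`TRUE` = tissue).
#' @export
compute_tissue_mask <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("compute_tissue_mask expects an RGB image (H x W x 3 array)")
  }
  if (length(image) < 3L) stop("image must have at least one pixel")
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  if (max(s) < 0.05) {
    return(matrix(FALSE, nrow(s), ncol(s)))
  }
  if (diff(range(s)) < 1e-8) {
    ## uniformly saturated image: everything is tissue
    return(matrix(TRUE, nrow(s), ncol(s)))
  }
  th <- EBImage::otsu(EBImage::Image(s), range = c(0, 1))
  mask <- s > th
  ## drop specks below 0.1% of the image area
  min_px <- 0.001 * length(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  sizes <- tabulate(labm[labm > 0])
  keep <- which(sizes >= min_px)
  mask <- matrix(labm %in% keep, nrow(mask), ncol(mask))
  mask
}

#' Extract foreground tiles from an image grid
#'
#' The grid is anchored at pixel (0, 0) with stride `tile_size` (no
#' overlap); partial edge tiles are discarded.  A tile is kept iff its
#' tissue fraction is at least `min_tissue_frac`.  Tiles are returned in
#' row-major order.
#'
#' @param image optional RGB image (only its dimensions are used when a mask
#'   is supplied).
#' @param mask logical tissue mask (from [compute_tissue_mask()]).
#' @param tile_size tile edge length in pixels (>= 1).
#' @param min_tissue_frac minimum tissue fraction per tile, in \[0, 1\]
#'   (default 0.5).
#' @param slide_id identifier stored in the result.
#' @return a [tile_set]; empty (zero tiles) if the image is smaller than a
#'   single tile.
#' @export
extract_tiles <- function(image = NULL, mask, tile_size,
                          min_tissue_frac = 0.5, slide_id = "slide") {
  stopifnot(tile_size >= 1, min_tissue_frac >= 0, min_tissue_frac <= 1)
  if (is.null(mask)) mask <- compute_tissue_mask(image)
  H <- nrow(mask); W <- ncol(mask)
  nr <- H %/% tile_size; nc <- W %/% tile_size
  empty <- data.frame(row = integer(0), col = integer(0),
                      x0 = integer(0), y0 = integer(0),
                      x1 = integer(0), y1 = integer(0),
                      tissue_frac = numeric(0))
  if (nr == 0L || nc == 0L) {
    return(tile_set(slide_id, tile_size, nr, nc, empty))
  }
  ## block means of the mask over the (cropped) grid
  m <- mask[seq_len(nr * tile_size), seq_len(nc * tile_size), drop = FALSE]
  ri <- (seq_len(nr * tile_size) - 1L) %/% tile_size
  ci <- (seq_len(nc * tile_size) - 1L) %/% tile_size
  grp <- outer(ri, ci, function(r, cc) r * nc + cc)
  tf <- as.numeric(rowsum(as.numeric(m), as.vector(grp))[, 1]) / tile_size^2
  ## rowsum sorts by group id = row-major (0-based) order
  idx <- sort(unique(as.vector(grp)))
  keep <- which(tf >= min_tissue_frac)
  if (length(keep) == 0L) return(tile_set(slide_id, tile_size, nr, nc, empty))
  id0 <- idx[keep]
  row <- id0 %/% nc; col <- id0 %% nc
  tile_set(slide_id, tile_size, nr, nc,
           data.frame(row = row, col = col,
                      x0 = col * tile_size, y0 = row * tile_size,
                      x1 = (col + 1L) * tile_size,
                      y1 = (row + 1L) * tile_size,
                      tissue_frac = tf[keep]))
}
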
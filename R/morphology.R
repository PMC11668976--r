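## Rasterisation and shape descriptors for nucleus contour polygons.
## Pixel convention: the pixel with integer corner (i, j) covers
## [i, i+1) x [j, j+1) and is tested at its centre (i + 0.5, j + 0.5).

## vectorised even-odd point-in-polygon test
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    denom <- yj - yi
    if (denom != 0) {
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / denom + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

## integer pixel centres covered by a polygon
polygon_pixels <- function(poly) {
  xmin <- floor(min(poly[, 1])); xmax <- ceiling(max(poly[, 1]))
  ymin <- floor(min(poly[, 2])); ymax <- ceiling(max(poly[, 2]))
  if (xmax <= xmin || ymax <= ymin) {
    return(cbind(x = numeric(0), y = numeric(0)))
  }
  xs <- seq(xmin + 0.5, xmax - 0.5)
  ys <- seq(ymin + 0.5, ymax - 0.5)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  keep <- points_in_polygon(px, py, poly)
  cbind(x = px[keep], y = py[keep])
}

## resample a closed polygon to m points evenly spaced by arc length
resample_contour <- function(poly, m = 64L) {
  closed <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cs <- c(0, cumsum(seg))
  total <- cs[length(cs)]
  t_new <- seq(0, total, length.out = m + 1L)[-(m + 1L)]
  x <- stats::approx(cs, closed[, 1], xout = t_new)$y
  y <- stats::approx(cs, closed[, 2], xout = t_new)$y
  cbind(x, y)
}

## circular k-point moving average of a closed contour
smooth_contour <- function(poly, k = 5L) {
  n <- nrow(poly)
  half <- (k - 1L) %/% 2L
  idx <- function(i) ((i - 1L) %% n) + 1L
  out <- poly
  for (i in seq_len(n)) {
    win <- idx((i - half):(i + half))
    out[i, ] <- colMeans(poly[win, , drop = FALSE])
  }
  out
}

#' Morphological features of one nucleus contour
#'
#' Computes, from a closed contour polygon:
#' * `area` — interior pixel count of the filled polygon;
#' * `major_axis`, `minor_axis` — `4 * sqrt(eigenvalue)` of the second
#'   central moments of the filled region (equivalent-ellipse convention);
#' * `elongation_ratio` — major / minor (the axis-ratio "eccentricity"
#'   convention: long-axis length over short-axis length);
#' * `solidity` — area divided by the pixel area of the convex hull of the
#'   contour;
#' * `mean_curvature` — mean absolute turning angle per unit arc length
#'   along the 5-point-smoothed, arc-length-resampled contour (1/pixels;
#'   approximately `1/r` for a circle of radius `r`);
#' * `mean_intensity` — carried through from the record, or averaged over
#'   interior pixels when an intensity image is supplied.
#'
#' @param contour numeric n x 2 matrix of polygon vertices (closed
#'   implicitly; >= 3 vertices).
#' @param mean_intensity optional precomputed intensity to carry through.
#' @param intensity_image optional grayscale matrix to average over the
#'   interior (overrides `mean_intensity`).
#' @return one-row data frame with the features above.
#' @export
morphology_features <- function(contour, mean_intensity = NA_real_,
                                intensity_image = NULL) {
  if (!is.matrix(contour) || nrow(contour) < 3L) {
    stop("contour must be a matrix with at least 3 vertices")
  }
  pix <- polygon_pixels(contour)
  if (nrow(pix) < 3L) stop("degenerate contour: no interior pixels")
  area <- nrow(pix)
  mu <- colMeans(pix)
  xc <- pix[, 1] - mu[1]; yc <- pix[, 2] - mu[2]
  cov <- matrix(c(mean(xc^2), mean(xc * yc), mean(xc * yc), mean(yc^2)), 2)
  ev <- eigen(cov, symmetric = TRUE)$values
  if (ev[2] <= 1e-9) stop("degenerate (collinear) contour")
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  hull <- contour[grDevices::chull(contour), , drop = FALSE]
  hull_area <- nrow(polygon_pixels(hull))
  solidity <- min(1, area / max(hull_area, 1))
  ## curvature along the smoothed resampled contour
  rc <- smooth_contour(resample_contour(contour, 64L), 5L)
  e <- diff(rbind(rc, rc[1, ]))
  ang <- atan2(e[, 2], e[, 1])
  dtheta <- diff(c(ang, ang[1]))
  dtheta <- atan2(sin(dtheta), cos(dtheta))  # wrap to (-pi, pi]
  seglen <- sqrt(rowSums(e^2))
  ds <- (seglen + c(seglen[-1], seglen[1])) / 2
  mean_curv <- mean(abs(dtheta) / ds)
  if (!is.null(intensity_image)) {
    idx <- cbind(pmax(1, pmin(nrow(intensity_image), round(pix[, 2] + 0.5))),
                 pmax(1, pmin(ncol(intensity_image), round(pix[, 1] + 0.5))))
    mean_intensity <- mean(intensity_image[idx])
  }
  data.frame(area = area, major_axis = major, minor_axis = minor,
             elongation_ratio = major / minor, solidity = solidity,
             mean_curvature = mean_curv, mean_intensity = mean_intensity)
}

#' Morphology features for a table of cell records
#'
#' @param cells data frame with a `contour` list column (and optionally
#'   `mean_intensity`, `cell_id`, `slide_id`, `type`).
#' @return data frame: identifying columns plus one [morphology_features()]
#'   row per cell.
#' @export
morphology_table <- function(cells) {
  stopifnot(is.data.frame(cells), "contour" %in% names(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    morphology_features(cells$contour[[i]],
                        mean_intensity =
                          if ("mean_intensity" %in% names(cells)) {
                            cells$mean_intensity[i]
                          } else NA_real_)
  })
  feat <- do.call(rbind, rows)
  keep <- intersect(c("cell_id", "slide_id", "tile_row", "tile_col", "type"),
                    names(cells))
  cbind(cells[keep], feat)
}
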
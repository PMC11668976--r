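#' Default colorblind-safe heatmap palette
#'
#' Five Okabe-Ito colours for the subtype classes plus gray for the
#' background class; fixed so rendered rasters are reproducible.
#'
#' @param class_labels subtype names.
#' @return named vector of hex colours, one per label plus `"background"`.
#' @export
default_palette <- function(class_labels = c("A", "AB", "B1", "B2", "B3")) {
  cols <- c("#E69F00", "#56B4E9", "#009E73", "#CC79A7", "#D55E00")
  stats::setNames(c(cols[seq_along(class_labels)], "#999999"),
                  c(class_labels, "background"))
}

#' Predict per-tile patch classes for one slide
#'
#' Applies the auxiliary patch classifier to each foreground tile's raw
#' features and takes the argmax class; ties break toward the lower class
#' index (documented, deterministic).  Non-tissue grid positions never
#' appear in the map.
#'
#' @param tiles a [tile_set] (foreground tiles of the slide).
#' @param features matrix of raw per-tile inputs, rows aligned with
#'   `tiles$tiles`.
#' @param classifier a [patch_classifier()] trained over `{1..C+1}`.
#' @return object of class `patch_class_map`: list with `slide_id`,
#'   `grid_rows`, `grid_cols`, `tile_size`, `tiles` (the foreground tile
#'   data frame) and `labels` (one predicted label in `1..C+1` per
#'   foreground tile).
#' @export
predict_patch_classes <- function(tiles, features, classifier) {
  stopifnot(inherits(tiles, "tile_set"))
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) != nrow(tiles$tiles)) {
    stop("features row count must equal foreground tile count")
  }
  P <- predict_patch(classifier, features)
  labels <- apply(P, 1L, which.max)  # which.max: first (lowest) index on ties
  structure(list(slide_id = tiles$slide_id, grid_rows = tiles$grid_rows,
                 grid_cols = tiles$grid_cols, tile_size = tiles$tile_size,
                 tiles = tiles$tiles, labels = as.integer(labels),
                 n_classes = classifier$n_out),
            class = "patch_class_map")
}

#' Render a patch-class map as an RGBA heatmap raster
#'
#' Each foreground tile is painted with its label's palette colour over the
#' tile's half-open pixel bounds; non-tissue positions are fully
#' transparent.  No smoothing or interpolation is applied: the output is
#' tile-resolution blocks, faithful to the per-patch predictions.  With a
#' base image, tile colours are alpha-blended over it at a fixed 0.4.
#'
#' @param map a [predict_patch_classes()] result (or any list with the same
#'   fields, e.g. built from ground truth).
#' @param palette named colour vector: one colour per class label index
#'   `1..C` plus `"background"` for class `C+1` (see [default_palette()]).
#' @param base optional H x W x 3 base image to blend over.
#' @param alpha blend weight of the class colour when `base` is given.
#' @return H x W x 4 RGBA array in \[0, 1\].
#' @export
render_heatmap <- function(map, palette = default_palette(), base = NULL,
                           alpha = 0.4) {
  stopifnot(inherits(map, "patch_class_map") || is.list(map))
  if (length(palette) < map$n_classes) {
    stop("palette must assign a colour to every label 1..C+1")
  }
  H <- map$grid_rows * map$tile_size
  W <- map$grid_cols * map$tile_size
  out <- array(0, dim = c(H, W, 4))
  if (!is.null(base)) {
    stopifnot(dim(base)[1] == H, dim(base)[2] == W)
  }
  rgb_tab <- grDevices::col2rgb(palette) / 255
  td <- map$tiles
  for (i in seq_len(nrow(td))) {
    colv <- rgb_tab[, map$labels[i]]
    ys <- (td$y0[i] + 1L):td$y1[i]
    xs <- (td$x0[i] + 1L):td$x1[i]
    if (is.null(base)) {
      for (ch in 1:3) out[ys, xs, ch] <- colv[ch]
    } else {
      for (ch in 1:3) {
        out[ys, xs, ch] <- alpha * colv[ch] + (1 - alpha) * base[ys, xs, ch]
      }
    }
    out[ys, xs, 4] <- 1
  }
  out
}

#' Write a heatmap raster and its legend sidecar
#'
#' @param raster RGBA array from [render_heatmap()].
#' @param path output PNG path; the legend JSON is written next to it as
#'   `<path>.legend.json`.
#' @param palette the palette used, for the legend.
#' @param class_labels label names in class-index order.
#' @return invisibly, the legend list.
#' @export
write_heatmap <- function(raster, path, palette = default_palette(),
                          class_labels = c("A", "AB", "B1", "B2", "B3")) {
  png::writePNG(raster, path)
  legend <- list(labels = c(class_labels, "background"),
                 colors = unname(palette[c(class_labels, "background")]))
  jsonlite::write_json(legend, paste0(path, ".legend.json"),
                       auto_unbox = FALSE)
  invisible(legend)
}

#' Patch-class map from phantom ground truth
#'
#' Convenience constructor used to compare predicted maps against the
#' generator's truth.
#'
#' @param slide a `phantom_slide`.
#' @return a `patch_class_map` whose labels are the true patch classes.
#' @export
truth_class_map <- function(slide) {
  structure(list(slide_id = slide$slide_id, grid_rows = slide$grid_rows,
                 grid_cols = slide$grid_cols, tile_size = slide$tile_size,
                 tiles = slide$tiles$tiles,
                 labels = as.integer(slide$patch_truth),
                 n_classes = length(slide$class_labels) + 1L),
            class = "patch_class_map")
}
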
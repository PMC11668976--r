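#' Write cell records in the HoverNet-style JSON dialect
#'
#' Top-level `"nuc"` map of id to `{"bbox", "centroid", "contour", "type",
#' "type_prob"}` with contours as vertex lists, for interoperability with
#' nucleus segmentation tools that emit this dialect.
#'
#' @param cells data frame with `cell_id`, `type`, `cx`, `cy` and a
#'   `contour` list column.
#' @param path output JSON path.
#' @param type_codes named integer codes per type (default tumor 1,
#'   inflammatory 2, other 3).
#' @return invisibly, `path`.
#' @export
write_hovernet_json <- function(cells, path,
                                type_codes = c(tumor = 1L,
                                               inflammatory = 2L,
                                               other = 3L)) {
  nuc <- list()
  for (i in seq_len(nrow(cells))) {
    poly <- cells$contour[[i]]
    nuc[[as.character(cells$cell_id[i])]] <- list(
      bbox = list(c(min(poly[, 2]), min(poly[, 1])),
                  c(max(poly[, 2]), max(poly[, 1]))),
      centroid = c(cells$cx[i], cells$cy[i]),
      contour = unname(lapply(seq_len(nrow(poly)),
                              function(r) c(poly[r, 1], poly[r, 2]))),
      type = unname(type_codes[[cells$type[i]]]),
      type_prob = 1.0)
  }
  jsonlite::write_json(list(nuc = nuc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read cell records from the HoverNet-style JSON dialect
#'
#' @param path JSON file with a top-level `"nuc"` map.
#' @param type_codes named integer codes per type (inverse mapping applied;
#'   unknown codes become `"other"`).
#' @param slide_id slide id to attach.
#' @return data frame with `cell_id`, `slide_id`, `type`, `cx`, `cy` and a
#'   `contour` list column.
#' @export
read_hovernet_json <- function(path,
                               type_codes = c(tumor = 1L,
                                              inflammatory = 2L,
                                              other = 3L),
                               slide_id = "slide") {
  obj <- jsonlite::read_json(path)
  nuc <- obj$nuc
  code_to_type <- stats::setNames(names(type_codes), type_codes)
  ids <- names(nuc)
  contours <- lapply(nuc, function(n) {
    do.call(rbind, lapply(n$contour, function(v) c(v[[1]], v[[2]])))
  })
  df <- data.frame(
    cell_id = ids,
    slide_id = slide_id,
    type = vapply(nuc, function(n) {
      ty <- as.character(n$type)
      if (ty %in% names(code_to_type)) code_to_type[[ty]] else "other"
    }, character(1)),
    cx = vapply(nuc, function(n) n$centroid[[1]], numeric(1)),
    cy = vapply(nuc, function(n) n$centroid[[2]], numeric(1)),
    stringsAsFactors = FALSE)
  df$contour <- unname(contours)
  rownames(df) <- NULL
  df
}

#' Write cell records as a flat CSV dialect
#'
#' One row per cell; the contour is serialized as `"x1 y1;x2 y2;..."`.
#'
#' @param cells cell data frame with a `contour` list column.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_cells_csv <- function(cells, path) {
  flat <- cells[setdiff(names(cells), "contour")]
  flat$contour <- vapply(cells$contour, function(p) {
    paste(apply(round(p, 3), 1L, paste, collapse = " "), collapse = ";")
  }, character(1))
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' Read the flat CSV cell dialect
#'
#' @param path CSV written by [write_cells_csv()].
#' @return cell data frame with a `contour` list column.
#' @export
read_cells_csv <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE)
  contours <- lapply(strsplit(flat$contour, ";", fixed = TRUE), function(vs) {
    do.call(rbind, lapply(strsplit(vs, " ", fixed = TRUE),
                          function(v) as.numeric(v)))
  })
  flat$contour <- NULL
  flat$contour <- contours
  flat
}

#' Export a phantom cohort to a directory
#'
#' Writes, per slide: the feature bag as CSV, the cells in the
#' HoverNet-style JSON dialect, and a cohort-level JSON manifest with slide
#' ids, labels, grid shapes and tile bounds.
#'
#' @param cohort list of phantom slides.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort, function(s) {
    utils::write.csv(s$features,
                     file.path(dir, paste0(s$slide_id, "_features.csv")),
                     row.names = FALSE)
    if (nrow(s$cells) > 0) {
      write_hovernet_json(s$cells,
                          file.path(dir, paste0(s$slide_id, "_cells.json")))
    }
    list(slide_id = s$slide_id, label = s$subtype,
         grid = c(s$grid_rows, s$grid_cols), tile_size = s$tile_size,
         tiles = s$tiles$tiles[c("row", "col", "x0", "y0", "x1", "y1")],
         patch_truth = s$patch_truth)
  })
  jsonlite::write_json(unname(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
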
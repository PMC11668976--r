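#' Configuration for the synthetic slide phantom
#'
#' The phantom emulates the statistical structure a weakly supervised thymoma
#' classifier must cope with: five subtypes with the cohort composition of a
#' realistic single-centre series (21/83/48/49/21 slides), mixed-subtype
#' heterogeneity (a minority contaminant focus inside some slides),
#' lymphocyte-rich versus tumor-rich patch composition, and subtype-dependent
#' tumor-nucleus area / axis-ratio distributions (lymphocyte-poor A and B3;
#' larger, more atypical nuclei in B3 than in A).
#'
#' @param class_labels ordered subtype names.
#' @param class_counts slides per subtype.
#' @param grid_rows,grid_cols tile-grid dimensions.
#' @param tile_size tile edge length in pixels (64 at desk scale; clinical
#'   pipelines typically use 256).
#' @param feature_dim encoder output size for feature-bag mode (must be
#'   at least `length(class_labels) + 1`).
#' @param signature_separation distance between class-conditional patch
#'   feature means, in feature units.
#' @param tumor_patch_frac fraction of foreground patches carrying the
#'   slide's subtype signal; the rest are background-class patches.
#' @param contaminant_frac fraction of slides containing a minority second
#'   subtype occupying 5--15% of patches.
#' @param empty_tile_frac fraction of grid positions with no tissue at all
#'   (white in image mode, absent from the bag).
#' @param cells_per_tile expected nucleus count per foreground tile
#'   (Poisson mean).
#' @param cell_params per-subtype list with `lymphocyte_frac`,
#'   `tumor_area_mean`, `tumor_area_sd`, `tumor_axis_ratio_mean`,
#'   `tumor_axis_ratio_sd`.
#' @param noise_sd isotropic feature noise standard deviation.
#' @param seed integer master seed; the whole cohort is a deterministic
#'   function of the config.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(class_labels = c("A", "AB", "B1", "B2", "B3"),
                           class_counts = c(21L, 83L, 48L, 49L, 21L),
                           grid_rows = 8L, grid_cols = 8L,
                           tile_size = 64L,
                           feature_dim = 64L,
                           signature_separation = 3.0,
                           tumor_patch_frac = 0.6,
                           contaminant_frac = 0.2,
                           empty_tile_frac = 0.1,
                           cells_per_tile = 3,
                           cell_params = default_cell_params(class_labels),
                           noise_sd = 1.0,
                           seed = 0L) {
  if (length(class_counts) != length(class_labels)) {
    stop("class_counts length must equal class_labels length")
  }
  if (any(class_counts < 1L)) stop("all class_counts must be >= 1")
  if (!(tumor_patch_frac > 0 && tumor_patch_frac <= 1)) {
    stop("tumor_patch_frac must lie in (0, 1]")
  }
  if (!(contaminant_frac >= 0 && contaminant_frac < 1)) {
    stop("contaminant_frac must lie in [0, 1)")
  }
  if (feature_dim < length(class_labels) + 1L) {
    stop("feature_dim must be >= number of classes + 1 (background signature)")
  }
  stopifnot(setequal(names(cell_params), class_labels))
  lf <- vapply(cell_params, `[[`, numeric(1), "lymphocyte_frac")[class_labels]
  poor <- names(sort(lf))[1:2]
  if (!setequal(poor, intersect(c("A", "B3"), class_labels)) &&
      all(c("A", "B3") %in% class_labels)) {
    stop("cell_params must make A and B3 the two lymphocyte-poorest subtypes")
  }
  if (all(c("A", "B3") %in% class_labels) &&
      cell_params[["B3"]]$tumor_area_mean <= cell_params[["A"]]$tumor_area_mean) {
    stop("cell_params must give B3 a larger tumor_area_mean than A")
  }
  structure(list(
    class_labels = class_labels, class_counts = as.integer(class_counts),
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    tile_size = as.integer(tile_size), feature_dim = as.integer(feature_dim),
    signature_separation = signature_separation,
    tumor_patch_frac = tumor_patch_frac,
    contaminant_frac = contaminant_frac,
    empty_tile_frac = empty_tile_frac,
    cells_per_tile = cells_per_tile,
    cell_params = cell_params, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Default per-subtype nucleus parameters
#'
#' A and B3 are lymphocyte-poor; B3 tumor nuclei are larger (greater nuclear
#' atypia) than A; A nuclei are spindle-shaped (high axis ratio).  Areas are
#' in pixels at the desk-scale 64 px tile.
#'
#' @param class_labels subtype names (subset of A/AB/B1/B2/B3).
#' @return named list of parameter lists.
#' @export
default_cell_params <- function(class_labels = c("A", "AB", "B1", "B2", "B3")) {
  all <- list(
    A  = list(lymphocyte_frac = 0.15, tumor_area_mean = 170, tumor_area_sd = 30,
              tumor_axis_ratio_mean = 2.2, tumor_axis_ratio_sd = 0.30),
    AB = list(lymphocyte_frac = 0.60, tumor_area_mean = 185, tumor_area_sd = 35,
              tumor_axis_ratio_mean = 1.60, tumor_axis_ratio_sd = 0.25),
    B1 = list(lymphocyte_frac = 0.70, tumor_area_mean = 205, tumor_area_sd = 40,
              tumor_axis_ratio_mean = 1.30, tumor_axis_ratio_sd = 0.20),
    B2 = list(lymphocyte_frac = 0.55, tumor_area_mean = 230, tumor_area_sd = 45,
              tumor_axis_ratio_mean = 1.25, tumor_axis_ratio_sd = 0.20),
    B3 = list(lymphocyte_frac = 0.20, tumor_area_mean = 260, tumor_area_sd = 55,
              tumor_axis_ratio_mean = 1.35, tumor_axis_ratio_sd = 0.25)
  )
  all[class_labels]
}

## class-conditional feature signatures: orthogonal scaled basis vectors,
## one per subtype plus one for the background class C+1.
class_signatures <- function(config) {
  C <- length(config$class_labels)
  S <- matrix(0, nrow = C + 1L, ncol = config$feature_dim)
  for (c in seq_len(C + 1L)) S[c, c] <- config$signature_separation
  S
}

## closed ellipse contour polygon (n vertices, slide pixel coordinates)
ellipse_contour <- function(cx, cy, area, axis_ratio, theta, n = 24L) {
  a <- sqrt(area * axis_ratio / pi)   # semi-major
  b <- sqrt(area / (pi * axis_ratio)) # semi-minor
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(cx + x * cos(theta) - y * sin(theta),
        cy + x * sin(theta) + y * cos(theta))
}

## intensity distributions per cell type (grayscale 0..255)
cell_intensity <- function(type, n) {
  mu <- c(tumor = 120, inflammatory = 60, other = 150)[type]
  sd <- c(tumor = 15, inflammatory = 10, other = 15)[type]
  pmin(255, pmax(0, stats::rnorm(n, mu, sd)))
}

#' Generate one phantom slide
#'
#' Draws the tile grid, patch ground-truth labels (subtype index or the
#' background class `C+1`), per-patch feature vectors from class-conditional
#' Gaussians, optionally a contiguous minority-subtype contaminant block, and
#' per-nucleus records (elliptical contours whose area and axis ratio follow
#' the subtype's nucleus distribution; nuclei never cross tile borders).
#'
#' @param config a [phantom_config()].
#' @param subtype subtype label for the slide.
#' @param slide_id identifier string.
#' @param seed integer seed for this slide (`NULL` uses the current RNG
#'   stream).
#' @param force_contaminant `NULL` for the configured random behaviour,
#'   `TRUE`/`FALSE` to force, or a subtype label to force that contaminant.
#' @return an object of class `phantom_slide`: a list with `slide_id`,
#'   `slide_label` (index), `subtype`, `tiles` (a [tile_set]), `patch_truth`
#'   (one label in `1..C+1` per foreground tile, row-major), `features`
#'   (matrix, one row per foreground tile), `cells` (data frame with a
#'   `contour` list column), and `contaminant` (`NULL` or a list with the
#'   contaminant subtype and its tile indices).
#' @export
generate_slide <- function(config, subtype, slide_id = subtype, seed = NULL,
                           force_contaminant = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!subtype %in% config$class_labels) {
    stop("unknown subtype '", subtype, "'")
  }
  gen <- function() generate_slide_impl(config, subtype, slide_id,
                                        force_contaminant)
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

generate_slide_impl <- function(config, subtype, slide_id, force_contaminant) {
  C <- length(config$class_labels)
  y <- match(subtype, config$class_labels)
  nr <- config$grid_rows; nc <- config$grid_cols
  ts <- config$tile_size
  n_grid <- nr * nc

  ## foreground tiles (row-major grid indices)
  n_empty <- min(n_grid - 1L, floor(config$empty_tile_frac * n_grid))
  empty <- if (n_empty > 0L) sort(sample.int(n_grid, n_empty)) else integer(0)
  fg <- setdiff(seq_len(n_grid), empty)
  n_fg <- length(fg)

  ## tumor-signal vs background-class tiles (MIL positivity: at least one)
  n_tum <- max(1L, round(config$tumor_patch_frac * n_fg))
  tum <- if (n_tum >= n_fg) fg else sort(sample(fg, n_tum))
  truth_grid <- rep.int(C + 1L, n_grid)
  truth_grid[tum] <- y

  ## contiguous minority contaminant block
  contaminant <- NULL
  want <- if (is.null(force_contaminant)) {
    stats::runif(1) < config$contaminant_frac
  } else if (is.character(force_contaminant)) TRUE else isTRUE(force_contaminant)
  if (want && C > 1L) {
    sub2 <- if (is.character(force_contaminant)) {
      force_contaminant
    } else {
      sample(setdiff(config$class_labels, subtype), 1L)
    }
    y2 <- match(sub2, config$class_labels)
    share <- stats::runif(1, 0.05, 0.15)
    target <- max(1L, round(share * n_fg))
    bh <- max(1L, min(nr, round(sqrt(target))))
    bw <- max(1L, min(nc, ceiling(target / bh)))
    r0 <- sample.int(nr - bh + 1L, 1L)
    c0 <- sample.int(nc - bw + 1L, 1L)
    block <- as.vector(outer(r0:(r0 + bh - 1L) - 1L, c0:(c0 + bw - 1L),
                             function(r, cc) r * nc + cc))
    cont_idx <- intersect(block, fg)
    ## keep MIL positivity: at least one tile of the slide's own subtype
    if (length(cont_idx) > 0L && all(tum %in% cont_idx)) {
      cont_idx <- setdiff(cont_idx, tum[1L])
    }
    if (length(cont_idx) > 0L) {
      truth_grid[cont_idx] <- y2
      contaminant <- list(subtype = sub2, label = y2, tiles = cont_idx)
    }
  }

  truth <- truth_grid[fg]

  ## per-tile features from class-conditional Gaussians
  S <- class_signatures(config)
  feats <- S[truth, , drop = FALSE] +
    matrix(stats::rnorm(n_fg * config$feature_dim, 0, config$noise_sd), n_fg)

  ## tile bookkeeping (0-based grid, half-open pixel bounds)
  row <- (fg - 1L) %/% nc
  col <- (fg - 1L) %% nc
  tiles <- tile_set(slide_id, ts, nr, nc,
                    data.frame(row = row, col = col,
                               x0 = col * ts, y0 = row * ts,
                               x1 = (col + 1L) * ts, y1 = (row + 1L) * ts,
                               tissue_frac = 1))

  cells <- generate_cells(config, slide_id, row, col, truth)

  structure(list(
    slide_id = slide_id, slide_label = y, subtype = subtype,
    tiles = tiles, patch_truth = truth, features = feats,
    cells = cells, contaminant = contaminant,
    class_labels = config$class_labels, tile_size = ts,
    grid_rows = nr, grid_cols = nc, fg_index = fg
  ), class = "phantom_slide")
}

## sample per-nucleus records for the foreground tiles of one slide
generate_cells <- function(config, slide_id, row, col, truth) {
  C <- length(config$class_labels)
  ts <- config$tile_size
  out <- list(); k <- 0L
  for (i in seq_along(truth)) {
    n_cells <- stats::rpois(1L, config$cells_per_tile)
    if (n_cells == 0L) next
    tr <- truth[i]
    if (tr <= C) {
      cp <- config$cell_params[[config$class_labels[tr]]]
      type <- ifelse(stats::runif(n_cells) < cp$lymphocyte_frac,
                     "inflammatory", "tumor")
    } else {
      ## background patches: mostly lymphocytes, some stromal nuclei
      type <- ifelse(stats::runif(n_cells) < 0.7, "inflammatory", "other")
      cp <- NULL
    }
    for (j in seq_len(n_cells)) {
      if (type[j] == "tumor") {
        area <- max(40, stats::rnorm(1, cp$tumor_area_mean, cp$tumor_area_sd))
        ratio <- max(1, stats::rnorm(1, cp$tumor_axis_ratio_mean,
                                     cp$tumor_axis_ratio_sd))
      } else if (type[j] == "inflammatory") {
        area <- max(25, stats::rnorm(1, 60, 10))
        ratio <- max(1, stats::rnorm(1, 1.05, 0.05))
      } else {
        area <- max(30, stats::rnorm(1, 90, 20))
        ratio <- max(1, stats::rnorm(1, 1.8, 0.3))
      }
      a <- sqrt(area * ratio / pi) # semi-major axis bounds the footprint
      margin <- min(a + 1.5, ts / 2 - 1)
      ## shrink the nucleus if it cannot fit inside the tile
      if (a + 1.5 > ts / 2 - 1) {
        a <- ts / 2 - 2.5
        area <- pi * a^2 / ratio
      }
      cx <- col[i] * ts + stats::runif(1, margin, ts - margin)
      cy <- row[i] * ts + stats::runif(1, margin, ts - margin)
      theta <- stats::runif(1, 0, pi)
      k <- k + 1L
      out[[k]] <- list(cell_id = paste0(slide_id, "_c", k),
                       slide_id = slide_id,
                       tile_row = row[i], tile_col = col[i],
                       type = type[j], cx = cx, cy = cy,
                       mean_intensity = cell_intensity(type[j], 1L),
                       gen_area = area, gen_axis_ratio = ratio,
                       contour = ellipse_contour(cx, cy, area, ratio, theta))
    }
  }
  if (k == 0L) {
    return(data.frame(cell_id = character(0), slide_id = character(0),
                      tile_row = integer(0), tile_col = integer(0),
                      type = character(0), cx = numeric(0), cy = numeric(0),
                      mean_intensity = numeric(0), gen_area = numeric(0),
                      gen_axis_ratio = numeric(0)))
  }
  df <- data.frame(
    cell_id = vapply(out, `[[`, character(1), "cell_id"),
    slide_id = slide_id,
    tile_row = vapply(out, `[[`, numeric(1), "tile_row"),
    tile_col = vapply(out, `[[`, numeric(1), "tile_col"),
    type = vapply(out, `[[`, character(1), "type"),
    cx = vapply(out, `[[`, numeric(1), "cx"),
    cy = vapply(out, `[[`, numeric(1), "cy"),
    mean_intensity = vapply(out, `[[`, numeric(1), "mean_intensity"),
    gen_area = vapply(out, `[[`, numeric(1), "gen_area"),
    gen_axis_ratio = vapply(out, `[[`, numeric(1), "gen_axis_ratio"),
    stringsAsFactors = FALSE)
  df$contour <- lapply(out, `[[`, "contour")
  df
}

#' Generate a phantom cohort
#'
#' @param config a [phantom_config()].
#' @return list of [generate_slide()] objects, `class_counts[i]` slides per
#'   subtype, deterministic given `config$seed` (same seed, identical
#'   cohort).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n_total <- sum(config$class_counts)
  seeds <- derive_seeds(config$seed, n_total)
  out <- vector("list", n_total)
  k <- 0L
  for (i in seq_along(config$class_labels)) {
    lab <- config$class_labels[i]
    for (j in seq_len(config$class_counts[i])) {
      k <- k + 1L
      id <- sprintf("%s_%03d", lab, j)
      out[[k]] <- generate_slide(config, lab, id, seed = seeds[k])
    }
  }
  names(out) <- vapply(out, `[[`, character(1), "slide_id")
  out
}

#' Stratified train/validation/test split of a cohort
#'
#' Uses largest-remainder apportionment within each subtype so that each
#' split's subtype composition tracks the cohort composition to within one
#' slide; the canonical 222-slide cohort with the default fractions yields
#' 141/42/39 slides.
#'
#' @param cohort list of phantom slides (or any objects with `slide_id` and
#'   `subtype`).
#' @param fractions length-3 numeric `(train, val, test)` summing to 1.
#' @param seed integer seed controlling the shuffle within subtypes.
#' @return list with character vectors `train`, `val`, `test` of slide ids
#'   (disjoint; union is the cohort).
#' @export
split_cohort <- function(cohort, fractions = c(141, 42, 39) / 222, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  ids <- vapply(cohort, `[[`, character(1), "slide_id")
  subs <- vapply(cohort, `[[`, character(1), "subtype")
  splits <- list(train = character(0), val = character(0), test = character(0))
  shuffles <- derive_seeds(seed, length(unique(subs)))
  for (si in seq_along(unique(subs))) {
    s <- unique(subs)[si]
    sid <- ids[subs == s]
    n <- length(sid)
    if (n < sum(fractions > 0)) {
      stop("subtype '", s, "' has fewer slides (", n,
           ") than nonzero splits")
    }
    ideal <- n * fractions
    base <- floor(ideal)
    rem <- ideal - base
    extra <- n - sum(base)
    if (extra > 0L) {
      give <- order(rem, decreasing = TRUE)[seq_len(extra)]
      base[give] <- base[give] + 1L
    }
    sid <- with_seed(shuffles[si], sample(sid))
    cuts <- cumsum(base)
    splits$train <- c(splits$train, sid[seq_len(base[1])])
    if (base[2] > 0) splits$val <- c(splits$val, sid[(cuts[1] + 1):cuts[2]])
    if (base[3] > 0) splits$test <- c(splits$test, sid[(cuts[2] + 1):cuts[3]])
  }
  splits
}

#' Render a phantom slide to an RGB raster
#'
#' Foreground tiles are painted with a saturated subtype-specific tint and
#' nuclei as darker filled ellipses; empty grid positions remain white, so
#' the painted tissue area is exactly `n_foreground_tiles * tile_size^2`
#' pixels (recorded in the result for mask oracles).
#'
#' @param slide a `phantom_slide`.
#' @return list with `image` (H x W x 3 array in \[0,1\]) and `painted_px`
#'   (integer pixel count of painted tissue).
#' @export
render_slide_image <- function(slide) {
  stopifnot(inherits(slide, "phantom_slide"))
  ts <- slide$tile_size
  H <- slide$grid_rows * ts; W <- slide$grid_cols * ts
  C <- length(slide$class_labels)
  hues <- seq(0, 0.75, length.out = C + 1L)
  img <- array(1, dim = c(H, W, 3))
  td <- slide$tiles$tiles
  for (i in seq_len(nrow(td))) {
    tr <- slide$patch_truth[i]
    rgb <- grDevices::hsv(hues[tr], 0.5, 0.95)
    colv <- grDevices::col2rgb(rgb)[, 1] / 255
    ys <- (td$y0[i] + 1L):td$y1[i]
    xs <- (td$x0[i] + 1L):td$x1[i]
    for (ch in 1:3) img[ys, xs, ch] <- colv[ch]
  }
  ## nuclei: darker, saturated ellipses in their tile's hue, value scaled by
  ## the recorded grayscale intensity (saturated so they count as tissue)
  if (nrow(slide$cells) > 0L) {
    tile_key <- td$row * slide$grid_cols + td$col
    for (i in seq_len(nrow(slide$cells))) {
      cc <- slide$cells[i, ]
      poly <- slide$cells$contour[[i]]
      tr_i <- slide$patch_truth[match(cc$tile_row * slide$grid_cols +
                                        cc$tile_col, tile_key)]
      v <- 0.25 + cc$mean_intensity / 255 * 0.5
      cellcol <- grDevices::col2rgb(grDevices::hsv(hues[tr_i], 0.8, v))[, 1] / 255
      xmin <- max(1L, floor(min(poly[, 1]))); xmax <- min(W, ceiling(max(poly[, 1])))
      ymin <- max(1L, floor(min(poly[, 2]))); ymax <- min(H, ceiling(max(poly[, 2])))
      if (xmin > xmax || ymin > ymax) next
      px <- rep(seq(xmin, xmax) - 0.5, times = ymax - ymin + 1L)
      py <- rep(seq(ymin, ymax) - 0.5, each = xmax - xmin + 1L)
      inside <- points_in_polygon(px, py, poly)
      if (!any(inside)) next
      xi <- px[inside] + 0.5; yi <- py[inside] + 0.5
      for (ch in 1:3) {
        idx <- cbind(yi, xi, ch)
        img[idx] <- cellcol[ch]
      }
    }
  }
  list(image = img, painted_px = nrow(td) * ts^2L)
}

#' @export
print.phantom_slide <- function(x, ...) {
  cat("<phantom_slide>", x$slide_id, "subtype", x$subtype,
      "|", nrow(x$tiles$tiles), "foreground tiles,",
      nrow(x$cells), "cells",
      if (!is.null(x$contaminant)) {
        paste0("| contaminant ", x$contaminant$subtype, " (",
               length(x$contaminant$tiles), " tiles)")
      } else "", "\n")
  invisible(x)
}
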
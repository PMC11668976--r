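#' Per-slide cell summary features
#'
#' Twelve slide-level features: for each of the two analysed cell types
#' (tumor, inflammatory), the cell proportion, mean area, mean
#' elongation-ratio eccentricity (long axis over short axis), mean solidity,
#' mean curvature, and mean intensity.  The proportion of a cell type in a
#' slide is its count divided by the *cohort grand total* cell count, so
#' proportions sum to 1 over all slides and all cell types cohort-wide.
#'
#' @param cells per-cell feature rows for one slide (from
#'   [morphology_table()], or generator-emitted feature columns renamed to
#'   match), with columns `type`, `area`, `elongation_ratio`, `solidity`,
#'   `mean_curvature`, `mean_intensity`.
#' @param grand_total total cell count across the whole cohort (> 0).
#' @param slide_id,subtype identifiers stored in the row.
#' @param types cell types to summarise (default tumor + inflammatory; all
#'   other types still count toward proportions via `grand_total`).
#' @return one-row data frame (`slide_id`, `subtype`, then
#'   `<type>_<feature>` columns; missing cell types give `NA` means and
#'   proportion 0).
#' @export
summarize_slide <- function(cells, grand_total, slide_id = "slide",
                            subtype = NA_character_,
                            types = c("tumor", "inflammatory"),
                            extra_types = setdiff(unique(cells$type), types)) {
  stopifnot(grand_total > 0)
  out <- data.frame(slide_id = slide_id, subtype = subtype,
                    stringsAsFactors = FALSE)
  feats <- c("area", "elongation_ratio", "solidity", "mean_curvature",
             "mean_intensity")
  for (ty in types) {
    sub <- cells[cells$type == ty, , drop = FALSE]
    out[[paste0(ty, "_proportion")]] <- nrow(sub) / grand_total
    for (f in feats) {
      out[[paste0(ty, "_mean_", f)]] <-
        if (nrow(sub) > 0) mean(sub[[f]]) else NA_real_
    }
  }
  ## proportion-only columns for any remaining cell types, so that the
  ## cohort-wide sum of proportions over all slides and types is 1
  for (ty in extra_types) {
    out[[paste0(ty, "_proportion")]] <- sum(cells$type == ty) / grand_total
  }
  out
}

#' Summarise every slide of a cohort
#'
#' @param cell_features per-cell feature rows for the whole cohort
#'   (columns `slide_id`, `type`, and the feature columns of
#'   [morphology_table()]).
#' @param slide_subtypes named character vector mapping slide id to subtype.
#' @return data frame with one [summarize_slide()] row per slide.
#' @export
cohort_cell_summary <- function(cell_features, slide_subtypes) {
  grand_total <- nrow(cell_features)
  ids <- names(slide_subtypes)
  base_types <- c("tumor", "inflammatory")
  extra <- setdiff(unique(cell_features$type), base_types)
  do.call(rbind, lapply(ids, function(id) {
    summarize_slide(cell_features[cell_features$slide_id == id, ,
                                  drop = FALSE],
                    grand_total, slide_id = id,
                    subtype = slide_subtypes[[id]],
                    extra_types = extra)
  }))
}

#' Build (subtype x cell type) feature groups
#'
#' With five subtypes and two cell types this yields the ten groups used
#' for the between-group statistics; [tumor_groups()] selects the five
#' tumor-cell groups for inter-subtype testing.
#'
#' @param summaries cohort summary table from [cohort_cell_summary()].
#' @param feature summary feature name (e.g. `"proportion"`,
#'   `"mean_area"`).
#' @param types cell types to cross with subtypes.
#' @return object of class `group_table`: list with `feature` and `groups`
#'   (named list `"<subtype>|<type>"` of per-slide value vectors).
#' @export
group_features <- function(summaries, feature,
                           types = c("tumor", "inflammatory")) {
  subs <- unique(summaries$subtype)
  if (any(!vapply(subs, function(s) any(summaries$subtype == s),
                  logical(1)))) {
    stop("every subtype needs at least one slide")
  }
  groups <- list()
  for (s in subs) {
    for (ty in types) {
      colname <- paste0(ty, "_", feature)
      if (!colname %in% names(summaries)) {
        stop("unknown feature column: ", colname)
      }
      v <- summaries[[colname]][summaries$subtype == s]
      if (anyNA(v)) {
        warning("dropping ", sum(is.na(v)), " NA values in group ", s, "|",
                ty)
        v <- v[!is.na(v)]
      }
      if (length(v) == 0L) stop("empty group: ", s, "|", ty)
      groups[[paste0(s, "|", ty)]] <- v
    }
  }
  structure(list(feature = feature, groups = groups), class = "group_table")
}

#' Select the tumor-cell groups of a group table
#'
#' @param gt a [group_features()] table.
#' @return a `group_table` restricted to the `"|tumor"` groups.
#' @export
tumor_groups <- function(gt) {
  stopifnot(inherits(gt, "group_table"))
  keep <- grepl("\\|tumor$", names(gt$groups))
  structure(list(feature = gt$feature, groups = gt$groups[keep]),
            class = "group_table")
}

as_group_list <- function(groups) {
  if (inherits(groups, "group_table")) groups$groups else groups
}

#' Kruskal-Wallis test over feature groups
#'
#' Tie-corrected H statistic with `df = g - 1` and the chi-squared
#' upper-tail p-value.  All-identical values give `H = 0, p = 1` rather
#' than an error.
#'
#' @param groups a [group_features()] table or a named list of numeric
#'   vectors.
#' @return object of class `kw_result`: list with `chi_squared`, `df`,
#'   `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  g <- as_group_list(groups)
  stopifnot(length(g) >= 2L, all(lengths(g) >= 1L))
  values <- unlist(g, use.names = FALSE)
  fac <- factor(rep(names(g), lengths(g)), levels = names(g))
  df <- length(g) - 1L
  if (length(unique(values)) < 2L) {
    res <- list(chi_squared = 0, df = df, p_value = 1)
  } else {
    kt <- stats::kruskal.test(values, fac)
    res <- list(chi_squared = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value)
  }
  structure(res, class = "kw_result")
}

#' Dunn's post hoc test with Benjamini-Hochberg adjustment
#'
#' For every unordered pair of groups, the Z statistic on pooled
#' (tie-corrected) ranks: `Z = (meanrank_i - meanrank_j) / SE` with
#' `SE = sqrt((N(N+1)/12 - T/(12(N-1))) * (1/n_i + 1/n_j))` and
#' `T = sum(t^3 - t)` over tie groups.  The sign is positive when group i's
#' mean rank exceeds group j's (the operationalisation of "the first
#' group's median is higher").  Unadjusted p-values are two-sided normal;
#' adjusted p-values apply the Benjamini-Hochberg step-up over the
#' `g(g-1)/2` pairs, capped at 1, and are star-graded.
#'
#' @param groups a [group_features()] table or named list of numeric
#'   vectors (each nonempty).
#' @param adjust p-adjustment method (default `"BH"`).
#' @return data frame with one row per pair: `group_i`, `group_j`, `Z`,
#'   `p_unadj`, `p_adj`, `stars`.
#' @export
dunn_posthoc <- function(groups, adjust = "BH") {
  g <- as_group_list(groups)
  if (length(g) < 2L) stop("need at least 2 groups")
  if (any(lengths(g) == 0L)) stop("groups must be nonempty")
  values <- unlist(g, use.names = FALSE)
  fac <- rep(names(g), lengths(g))
  N <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, fac, mean)
  ns <- lengths(g)
  ties <- table(values)
  Tie <- sum(ties^3 - ties)
  var_term <- N * (N + 1) / 12 - Tie / (12 * (N - 1))
  pairs <- utils::combn(names(g), 2L)
  Z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_term * (1 / ns[[i]] + 1 / ns[[j]]))
    Z[k] <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(Z[k]))
  }
  p_adj <- pmin(1, stats::p.adjust(p, method = adjust))
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ], Z = Z,
             p_unadj = p, p_adj = p_adj, stars = star_grade(p_adj),
             stringsAsFactors = FALSE)
}

#' Significance star grading
#'
#' `>= 0.05` is `"ns"`; `< 0.05` one star, `< 0.01` two, `< 0.001` three,
#' `< 0.0001` four (strict inequalities; the most significant bracket
#' wins).
#'
#' @param p numeric p-values in \[0, 1\].
#' @return character vector of grades.
#' @export
star_grade <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Tidy long-format export for violin plots
#'
#' @param groups a [group_features()] table or named list of vectors
#'   (names `"<subtype>|<type>"`).
#' @return list with `data` (long rows: `subtype`, `cell_type`, `feature`,
#'   `value`) and `summary` (per group: `median`, `q1`, `q3`, `n`).
#' @export
violin_export <- function(groups) {
  g <- as_group_list(groups)
  if (length(g) == 0L || any(lengths(g) == 0L)) {
    stop("groups must be nonempty")
  }
  feature <- if (inherits(groups, "group_table")) groups$feature else NA
  split_name <- function(nm) strsplit(nm, "|", fixed = TRUE)[[1]]
  data <- do.call(rbind, lapply(names(g), function(nm) {
    parts <- split_name(nm)
    data.frame(subtype = parts[1],
               cell_type = if (length(parts) > 1) parts[2] else NA,
               feature = feature, value = g[[nm]],
               stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(names(g), function(nm) {
    parts <- split_name(nm)
    q <- stats::quantile(g[[nm]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(subtype = parts[1],
               cell_type = if (length(parts) > 1) parts[2] else NA,
               feature = feature, median = q[2], q1 = q[1], q3 = q[3],
               n = length(g[[nm]]), stringsAsFactors = FALSE)
  }))
  list(data = data, summary = summary)
}
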
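test_that("morphology of canonical shapes matches closed forms", {
  ## axis-aligned 10x10 square
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  f <- morphology_features(sq)
  expect_equal(f$area, 100)
  expect_equal(f$solidity, 1.0)
  expect_equal(f$elongation_ratio, 1.0, tolerance = 1e-9)
  ## digitized circle of radius 20: curvature ~ 1/r
  circ <- thymil:::ellipse_contour(40, 40, pi * 20^2, 1, 0, n = 48)
  fc <- morphology_features(circ)
  expect_lt(abs(fc$mean_curvature - 1 / 20) / (1 / 20), 0.10)
  expect_lt(abs(fc$area - pi * 400) / (pi * 400), 0.05)
  ## 40x10 rectangle: elongation ratio ~ 4
  rect <- cbind(c(0, 40, 40, 0), c(0, 0, 10, 10))
  fr <- morphology_features(rect)
  expect_lt(abs(fr$elongation_ratio - 4) / 4, 0.05)
  ## degenerate collinear contour
  expect_error(morphology_features(cbind(c(0, 1, 2), c(0, 1, 2))),
               "degenerate|interior")
  expect_error(morphology_features(cbind(0:1, 0:1)), "3 vertices")
})

test_that("contour-derived features recover the generator's sampled parameters", {
  cfg <- phantom_config()
  s <- generate_slide(cfg, "B3", seed = 21)
  mt <- morphology_table(s$cells)
  expect_equal(nrow(mt), nrow(s$cells))
  expect_gt(cor(mt$area, s$cells$gen_area), 0.99)
  expect_gt(cor(mt$elongation_ratio, s$cells$gen_axis_ratio), 0.9)
})

test_that("slide summaries use the cohort grand total for proportions", {
  cells <- data.frame(type = c(rep("tumor", 4), rep("inflammatory", 6)),
                      area = rep(100, 10), elongation_ratio = rep(1.5, 10),
                      solidity = rep(1, 10), mean_curvature = rep(0.1, 10),
                      mean_intensity = rep(120, 10))
  row <- summarize_slide(cells, grand_total = 10)
  expect_equal(row$tumor_proportion, 0.4)
  expect_equal(row$inflammatory_proportion, 0.6)
  expect_equal(row$tumor_mean_area, 100)
  ## identical cells: mean equals the single-cell value
  expect_equal(row$tumor_mean_elongation_ratio, 1.5)
  ## absent type: NA means, proportion 0
  row2 <- summarize_slide(cells[cells$type == "tumor", ], grand_total = 10)
  expect_equal(row2$inflammatory_proportion, 0)
  expect_true(is.na(row2$inflammatory_mean_area))
})

test_that("cohort proportions sum to one across slides and cell types", {
  co <- generate_cohort(phantom_config(class_counts = rep(3L, 5), seed = 31))
  cells <- do.call(rbind, lapply(co, `[[`, "cells"))
  ## generator-sampled parameters serve as the per-cell features here
  feats <- data.frame(slide_id = cells$slide_id, type = cells$type,
                      area = cells$gen_area,
                      elongation_ratio = cells$gen_axis_ratio,
                      solidity = 1, mean_curvature = 0.1,
                      mean_intensity = cells$mean_intensity)
  subs <- vapply(co, `[[`, character(1), "subtype")
  summ <- cohort_cell_summary(feats, subs)
  prop_cols <- grep("_proportion$", names(summ), value = TRUE)
  expect_equal(sum(unlist(summ[prop_cols])), 1, tolerance = 1e-9)
  ## 5 subtypes x 2 analysed cell types = 10 groups; 5 tumor groups
  gt <- group_features(summ, "mean_area")
  expect_length(gt$groups, 10L)
  expect_length(tumor_groups(gt)$groups, 5L)
  expect_true(all(lengths(tumor_groups(gt)$groups) == 3L))
  ## 2 subtypes x 2 types = 4 groups
  summ2 <- summ[summ$subtype %in% c("A", "B3"), ]
  expect_length(group_features(summ2, "mean_area")$groups, 4L)
})

test_that("Kruskal-Wallis reports tie-corrected H with df = groups - 1", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7),
                 d = c(1, 1, 2), e = c(9, 9, 9))
  kw <- kruskal_wallis(groups)
  expect_equal(kw$df, 4L)
  ref <- kruskal.test(unlist(groups),
                      factor(rep(names(groups), each = 3)))
  expect_equal(kw$chi_squared, unname(ref$statistic))
  ## identical values: H = 0, p = 1 rather than an error
  kw0 <- kruskal_wallis(list(a = c(1, 1), b = c(1, 1)))
  expect_equal(kw0$chi_squared, 0)
  expect_equal(kw0$p_value, 1)
  expect_equal(kw0$df, 1L)
})

test_that("Kruskal-Wallis p-value agrees with a permutation oracle", {
  set.seed(5)
  groups <- list(a = c(1.2, 3.4, 0.5, 2.2), b = c(2.1, 4.0, 3.3, 5.1),
                 c = c(0.1, 1.1, 0.9, 2.0))
  kw <- kruskal_wallis(groups)
  ## independent oracle: permutation distribution of hand-computed H
  values <- unlist(groups)
  sizes <- lengths(groups)
  hand_H <- function(v) {
    r <- rank(v)
    N <- length(v)
    idx <- rep(seq_along(sizes), sizes)
    Rbar <- tapply(r, idx, mean)
    H <- 12 / (N * (N + 1)) * sum(sizes * (Rbar - (N + 1) / 2)^2)
    ties <- table(v)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  H_obs <- hand_H(values)
  expect_equal(H_obs, kw$chi_squared, tolerance = 1e-9)
  reps <- 1e5
  H_perm <- replicate(reps, hand_H(sample(values)))
  p_perm <- mean(H_perm >= H_obs - 1e-12)
  expect_lt(abs(kw$p_value - p_perm), 0.02)
})

test_that("Dunn's test has the pair count, sign convention and BH adjustment", {
  groups <- list(hi = c(11, 12, 13, 14, 15, 16, 17, 18, 19, 20),
                 lo = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  d <- dunn_posthoc(groups)
  expect_equal(nrow(d), 1L)
  expect_gt(d$Z, 0)  # first group's ranks are higher
  five <- lapply(1:5, function(i) rnorm(6, mean = i))
  names(five) <- paste0("g", 1:5)
  d5 <- dunn_posthoc(five)
  expect_equal(nrow(d5), 10L)  # C(5,2)
  ## BH step-up oracle implemented independently
  m <- nrow(d5)
  ord <- order(d5$p_unadj)
  bh <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, d5$p_unadj[ord[i]] * m / i)
    bh[ord[i]] <- prev
  }
  expect_equal(d5$p_adj, pmin(1, bh), tolerance = 1e-12)
  ## monotone after sorting by p_unadj
  expect_true(all(diff(d5$p_adj[ord]) >= -1e-12))
  expect_true(all(d5$p_adj <= 1))
  expect_error(dunn_posthoc(list(a = numeric(0), b = 1:3)), "nonempty")
})

test_that("star grading uses strict thresholds", {
  expect_equal(star_grade(0.03), "*")
  expect_equal(star_grade(0.0005), "***")
  expect_equal(star_grade(0.05), "ns")
  expect_equal(star_grade(c(0.2, 0.009, 9e-5)), c("ns", "**", "****"))
  expect_error(star_grade(1.2))
})

test_that("violin export produces long rows plus per-group summaries", {
  g <- setNames(lapply(1:10, function(i) rnorm(3)),
                paste(rep(c("A", "AB", "B1", "B2", "B3"), each = 2),
                      c("tumor", "inflammatory"), sep = "|"))
  ve <- violin_export(g)
  expect_equal(nrow(ve$data), 30L)
  expect_equal(nrow(ve$summary), 10L)
  ## median equals an independent sort-middle computation
  for (nm in names(g)) {
    v <- sort(g[[nm]])
    expect_equal(ve$summary$median[paste(ve$summary$subtype,
                                         ve$summary$cell_type,
                                         sep = "|") == nm], v[2])
  }
  expect_error(violin_export(list(a = numeric(0))), "nonempty")
})

test_that("cell records round-trip through the JSON and CSV dialects", {
  s <- generate_slide(phantom_config(), "AB", seed = 41)
  cells <- s$cells[1:10, ]
  path <- withr::local_tempfile(fileext = ".json")
  write_hovernet_json(cells, path)
  back <- read_hovernet_json(path, slide_id = cells$slide_id[1])
  expect_equal(nrow(back), 10L)
  expect_equal(back$type, cells$type)
  expect_equal(back$cx, cells$cx, tolerance = 1e-9)
  expect_equal(back$contour[[3]], unname(cells$contour[[3]]),
               tolerance = 1e-9)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cells_csv(cells, csv)
  back2 <- read_cells_csv(csv)
  expect_equal(back2$type, cells$type)
  expect_equal(back2$contour[[5]], unname(round(cells$contour[[5]], 3)))
})
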
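test_that("config validation enforces the phantom's structural invariants", {
  expect_error(phantom_config(class_counts = c(1, 2, 3)), "length")
  expect_error(phantom_config(tumor_patch_frac = 0), "tumor_patch_frac")
  expect_error(phantom_config(contaminant_frac = 1), "contaminant_frac")
  ## lymphocyte ordering: A and B3 must be the poorest
  bad <- default_cell_params()
  bad$A$lymphocyte_frac <- 0.9
  expect_error(phantom_config(cell_params = bad), "lymphocyte")
  ## B3 nuclei must be larger than A
  bad2 <- default_cell_params()
  bad2$B3$tumor_area_mean <- 100
  expect_error(phantom_config(cell_params = bad2), "tumor_area_mean")
  expect_error(generate_slide(phantom_config(), "Z"), "unknown subtype")
})

test_that("no contamination means every non-background patch carries the slide label", {
  cfg <- phantom_config(contaminant_frac = 0)
  for (seed in 1:5) {
    s <- generate_slide(cfg, "B2", seed = seed)
    tum <- s$patch_truth[s$patch_truth <= 5]
    expect_true(all(tum == s$slide_label))
  }
})

test_that("tumor_patch_frac 1 with no background gives all patches the slide label", {
  cfg <- phantom_config(tumor_patch_frac = 1, empty_tile_frac = 0,
                        contaminant_frac = 0)
  s <- generate_slide(cfg, "AB", seed = 2)
  expect_equal(length(s$patch_truth), 64L)
  expect_true(all(s$patch_truth == s$slide_label))
})

test_that("MIL positivity holds across many generated slides", {
  cfg <- phantom_config()
  seeds <- seq_len(500)
  labels <- rep_len(cfg$class_labels, 500)
  ok <- vapply(seq_len(500), function(i) {
    s <- generate_slide(cfg, labels[i], seed = seeds[i])
    any(s$patch_truth == s$slide_label) &&
      all(s$patch_truth >= 1 & s$patch_truth <= 6) &&
      nrow(s$features) == nrow(s$tiles$tiles)
  }, logical(1))
  expect_true(all(ok))
})

test_that("contaminant patch share matches the configured rate", {
  ## Monte-Carlo: contaminant_frac 0.2 times a 5-15% block share, measured
  ## over 200 B1 slides
  cfg <- phantom_config(seed = 0)
  n_min <- 0; n_tot <- 0
  for (i in 1:200) {
    s <- generate_slide(cfg, "B1", seed = 10000 + i)
    n_tot <- n_tot + length(s$patch_truth)
    if (!is.null(s$contaminant)) {
      n_min <- n_min + sum(s$patch_truth == s$contaminant$label)
    }
  }
  rate <- n_min / n_tot
  expected <- cfg$contaminant_frac * 0.10
  ## binomial-style band around the configured rate (block sizes cluster,
  ## so allow a generous factor-of-two band)
  expect_gt(rate, expected * 0.5)
  expect_lt(rate, expected * 2)
})

test_that("cohorts have the configured composition and are seed-deterministic", {
  cfg <- phantom_config()
  co <- generate_cohort(cfg)
  expect_length(co, 222L)
  subtypes <- vapply(co, `[[`, character(1), "subtype")
  expect_equal(unname(table(subtypes)[cfg$class_labels]),
               c(21L, 83L, 48L, 49L, 21L), ignore_attr = TRUE)
  co_small <- generate_cohort(phantom_config(class_counts = rep(1L, 5)))
  expect_length(co_small, 5L)
  ## determinism: same seed, bit-identical features and cells
  cfg2 <- phantom_config(class_counts = c(3L, 3L, 3L, 3L, 3L), seed = 42L)
  a <- generate_cohort(cfg2)
  b <- generate_cohort(cfg2)
  expect_identical(lapply(a, `[[`, "features"), lapply(b, `[[`, "features"))
  expect_identical(lapply(a, `[[`, "patch_truth"),
                   lapply(b, `[[`, "patch_truth"))
  expect_identical(lapply(a, function(s) s$cells$gen_area),
                   lapply(b, function(s) s$cells$gen_area))
})

test_that("split_cohort reproduces the 141/42/39 split, stratified and disjoint", {
  co <- generate_cohort(phantom_config())
  sp <- split_cohort(co, seed = 7)
  expect_equal(lengths(sp), c(train = 141L, val = 42L, test = 39L))
  ids <- vapply(co, `[[`, character(1), "slide_id")
  expect_setequal(c(sp$train, sp$val, sp$test), unname(ids))
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  ## stratification: per-subtype train share within one slide of global share
  subs <- vapply(co, `[[`, character(1), "subtype")
  names(subs) <- ids
  for (s in unique(subs)) {
    n_s <- sum(subs == s)
    in_train <- sum(subs[sp$train] == s)
    expect_lte(abs(in_train - n_s * 141 / 222), 1)
  }
  ## degenerate fractions
  sp_all <- split_cohort(co, fractions = c(1, 0, 0), seed = 1)
  expect_length(sp_all$train, 222L)
  expect_error(split_cohort(co[1:2], fractions = c(0.4, 0.3, 0.3)), "fewer")
  expect_error(split_cohort(co, fractions = c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("generated cell populations carry the built-in morphology trends", {
  co <- generate_cohort(phantom_config(class_counts = c(8L, 8L, 8L, 8L, 8L),
                                       seed = 3))
  cells <- do.call(rbind, lapply(co, `[[`, "cells"))
  subs <- vapply(co, `[[`, character(1), "subtype")
  cells$subtype <- subs[cells$slide_id]
  tum <- cells[cells$type == "tumor", ]
  ## B3 tumor nuclei larger than A
  expect_gt(median(tum$gen_area[tum$subtype == "B3"]),
            median(tum$gen_area[tum$subtype == "A"]))
  ## lymphocyte poverty of A and B3
  lfrac <- vapply(split(cells, cells$subtype),
                  function(d) mean(d$type == "inflammatory"), numeric(1))
  expect_true(all(lfrac[c("A", "B3")] <
                    min(lfrac[c("AB", "B1", "B2")])))
})

test_that("cohort export writes feature bags, cells and a manifest", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(phantom_config(class_counts = rep(1L, 5), seed = 9))
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(man, 5L)
  f <- utils::read.csv(file.path(dir, paste0(co[[1]]$slide_id,
                                             "_features.csv")))
  expect_equal(dim(f), dim(co[[1]]$features))
})
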
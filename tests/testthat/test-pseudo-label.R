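test_that("confidence is the exact product of attention and category score", {
  expect_identical(patch_confidence(0.5, 0.8), 0.4)
  expect_identical(patch_confidence(0, 0.73), 0)
  expect_identical(patch_confidence(1, 1), 1)
  ## exactness to machine precision on random values
  set.seed(1)
  a <- runif(100); p <- runif(100)
  expect_identical(patch_confidence(a, p), a * p)
  expect_error(patch_confidence(1.2, 0.5), "0, 1")
  expect_error(patch_confidence(0.5, -0.1), "0, 1")
})

test_that("top-k/bottom-k selection follows the documented order and tie-break", {
  conf <- data.frame(patch_id = 1:4, s = c(0.9, 0.1, 0.8, 0.2))
  sel <- select_pseudo_labels(conf, slide_class = 3L, k = 1, n_classes = 5L)
  expect_equal(sel$positives, 1L)
  expect_equal(sel$negatives, 2L)
  expect_equal(unname(sel$labels), c(3L, 6L))
  ## all-equal scores: ties go to ascending patch_id
  tied <- data.frame(patch_id = 1:6, s = rep(0.5, 6))
  sel2 <- select_pseudo_labels(tied, 1L, 2, n_classes = 2L)
  expect_equal(sel2$positives, c(1L, 2L))
  expect_equal(sel2$negatives, c(5L, 6L))
  ## k shrinks with warning when 2k > N
  expect_warning(s3 <- select_pseudo_labels(conf, 1L, 3, n_classes = 2L),
                 "shrunk")
  expect_equal(s3$k, 2L)
  expect_error(select_pseudo_labels(conf, 1L, 0), "positive")
})

test_that("selection agrees with a brute-force full sort on large random inputs", {
  set.seed(42)
  n <- 10000L
  conf <- data.frame(patch_id = seq_len(n),
                     s = round(runif(n), 3))  # rounding forces many ties
  k <- 20L
  sel <- select_pseudo_labels(conf, 2L, k, n_classes = 5L)
  ## independent oracle: repeated extraction of the extreme element
  oracle_top <- integer(0)
  pool <- conf
  for (i in seq_len(k)) {
    best <- pool$patch_id[pool$s == max(pool$s)]
    pick <- min(best)
    oracle_top <- c(oracle_top, pick)
    pool <- pool[pool$patch_id != pick, ]
  }
  oracle_bot <- integer(0)
  pool <- conf
  for (i in seq_len(k)) {
    worst <- pool$patch_id[pool$s == min(pool$s)]
    pick <- max(worst)
    oracle_bot <- c(oracle_bot, pick)
    pool <- pool[pool$patch_id != pick, ]
  }
  expect_equal(sel$positives, oracle_top)
  expect_equal(sort(sel$negatives), sort(oracle_bot))
  expect_length(intersect(sel$positives, sel$negatives), 0L)
})

test_that("patch classifier separates phantom pseudo-labels and shares encoder weights", {
  co <- generate_cohort(two_class_config(separation = 5, seed = 3))
  feats <- do.call(rbind, lapply(co, `[[`, "features"))
  truth <- unlist(lapply(co, `[[`, "patch_truth"))
  set.seed(8)
  hold <- sample(nrow(feats), 200)
  enc <- encoder_spec("mlp", input_dim = 64, seed = 2)
  pc <- patch_classifier(enc, 64L, 3L)
  z_before <- encode(feats[1, , drop = FALSE], enc)
  pc <- train_patch_classifier(pc, feats[-hold, ], truth[-hold],
                               phantom_train_config(seed = 2, epochs = 40))
  ## held-out accuracy on separable signatures
  pred <- apply(predict_patch(pc, feats[hold, ]), 1, which.max)
  expect_gte(mean(pred == truth[hold]), 0.95)
  ## weight sharing: the MIL-side encoder moved
  z_after <- encode(feats[1, , drop = FALSE], enc)
  expect_false(isTRUE(all.equal(z_before, z_after)))
  ## degenerate single-class pseudo-label set errors
  expect_error(train_patch_classifier(pc, feats[1:10, ], rep(1L, 10),
                                      phantom_train_config()),
               "2 classes")
})

test_that("one refinement round with a frozen identity encoder equals plain MIL", {
  co <- generate_cohort(two_class_config(separation = 3, seed = 4,
                                         counts = c(10L, 10L)))
  cb <- cohort_bags(co)
  cfg <- phantom_train_config(seed = 5, epochs = 10)
  bun <- refine_loop(cb$bags, cb$labels, cb$bags, cb$labels, n_classes = 2,
                     config = cfg, n_rounds = 1,
                     encoder = encoder_spec("identity"))
  ## the loop trains the MIL head with a round-derived seed; reproduce it
  cfg1 <- cfg; cfg1$seed <- cfg$seed + 1L
  plain <- train_mil(cb$bags, cb$labels, cfg1, cb$bags, cb$labels,
                     n_classes = 2)
  expect_identical(bun$mil$par, plain$par)
  expect_identical(predict_bundle(bun, cb$bags), predict_mil(plain, cb$bags))
})

test_that("the refinement log's best round is the argmax of validation accuracy", {
  co <- generate_cohort(two_class_config(separation = 1.5, seed = 6))
  cb <- cohort_bags(co)
  sp <- split_cohort(co, fractions = c(0.6, 0.4, 0), seed = 1)
  bun <- refine_loop(cb$bags[sp$train], cb$labels[sp$train],
                     cb$bags[sp$val], cb$labels[sp$val], n_classes = 2,
                     config = phantom_train_config(seed = 7, epochs = 15),
                     n_rounds = 2, patience_rounds = 2)
  log <- bun$log
  expect_equal(bun$best_round,
               log$round[which.max(log$val_acc)])
})

test_that("pseudo-label refinement does not degrade accuracy on a moderate phantom", {
  ## ablation direction at moderate separability: refined validation
  ## accuracy stays within noise of (or above) the unrefined one
  accs <- vapply(1:3, function(seed) {
    co <- generate_cohort(two_class_config(separation = 1.5, seed = seed,
                                           counts = c(15L, 15L)))
    cb <- cohort_bags(co)
    sp <- split_cohort(co, fractions = c(0.5, 0.25, 0.25), seed = seed)
    cfg <- phantom_train_config(seed = seed, epochs = 15)
    bun <- refine_loop(cb$bags[sp$train], cb$labels[sp$train],
                       cb$bags[sp$val], cb$labels[sp$val], n_classes = 2,
                       config = cfg, n_rounds = 2, patience_rounds = 2)
    cfg1 <- cfg; cfg1$seed <- cfg$seed + 1L
    plain <- train_mil(cb$bags[sp$train], cb$labels[sp$train], cfg1,
                       cb$bags[sp$val], cb$labels[sp$val], n_classes = 2)
    test_acc <- function(probs) {
      mean(apply(probs, 1, which.max) == cb$labels[sp$test])
    }
    test_acc(predict_bundle(bun, cb$bags[sp$test])) -
      test_acc(predict_mil(plain, cb$bags[sp$test]))
  }, numeric(1))
  expect_gte(median(accs), -0.05)
})
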
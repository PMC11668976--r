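test_that("attention aggregation satisfies its normalisation invariants", {
  par <- thymil:::mil_init(8, 3, hidden = 16, seed = 1)
  ## singleton bag: every attention column is exactly 1
  one <- attention_aggregate(matrix(rnorm(8), 1, 8), par)
  expect_equal(as.numeric(one$attention), rep(1, 3))
  expect_equal(sum(one$probs), 1, tolerance = 1e-12)
  ## identical instances: uniform attention 1/N per column
  z <- matrix(rnorm(8), 1, 8)
  same <- attention_aggregate(z[rep(1, 6), ], par)
  expect_equal(as.numeric(same$attention), rep(1 / 6, 18), tolerance = 1e-9)
  ## random bags: columns sum to 1, probs sum to 1
  set.seed(2)
  for (i in 1:20) {
    bp <- attention_aggregate(matrix(rnorm(10 * 8), 10, 8), par)
    expect_equal(unname(colSums(bp$attention)), rep(1, 3), tolerance = 1e-6)
    expect_equal(sum(bp$probs), 1, tolerance = 1e-6)
    expect_true(all(bp$probs >= 0))
  }
})

test_that("one-hot attention recovers a single instance; uniform attention the mean", {
  ## closed-form limits of the weighted aggregation
  Z <- matrix(rnorm(5 * 4), 5, 4)
  A <- matrix(0, 5, 2); A[3, ] <- 1
  expect_equal(crossprod(A, Z)[1, ], Z[3, ])
  A_unif <- matrix(1 / 5, 5, 2)
  expect_equal(crossprod(A_unif, Z)[1, ], colMeans(Z))
})

test_that("bag predictions are permutation invariant", {
  par <- thymil:::mil_init(6, 4, hidden = 12, seed = 3)
  set.seed(5)
  for (i in 1:10) {
    Z <- matrix(rnorm(12 * 6), 12, 6)
    p1 <- attention_aggregate(Z, par)$probs
    perm <- sample(12)
    p2 <- attention_aggregate(Z[perm, ], par)$probs
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(7)
  Z <- matrix(rnorm(6 * 5), 6, 5)
  y <- 2L
  par <- thymil:::mil_init(5, 3, hidden = 4, seed = 11)
  fw <- thymil:::mil_forward(Z, par, keep = TRUE)
  gr <- thymil:::mil_backward(Z, y, par, fw, weight = 1.7)
  loss_at <- function(p) -1.7 * log(thymil:::mil_forward(Z, p)$probs[y])
  eps <- 1e-6
  for (nm in names(par)) {
    for (i in sample(length(par[[nm]]), min(4, length(par[[nm]])))) {
      up <- par; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- par; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training separates a linearly separable two-class phantom", {
  co <- generate_cohort(two_class_config(separation = 5, seed = 1))
  cb <- cohort_bags(co)
  cfg <- phantom_train_config(seed = 1)
  model <- train_mil(cb$bags, cb$labels, cfg)
  pred <- apply(predict_mil(model, cb$bags), 1, which.max)
  expect_equal(mean(pred == cb$labels), 1.0)
  expect_lte(nrow(model$history), 30L)
  ## determinism: same config, identical final loss
  model2 <- train_mil(cb$bags, cb$labels, cfg)
  expect_identical(model$history$loss, model2$history$loss)
  expect_identical(model$par, model2$par)
  ## degenerate single-class input errors
  expect_error(train_mil(cb$bags[1:5], rep(1L, 5), cfg), "2 classes")
})

test_that("encoded class centroids separate with growing signature separation", {
  margins <- vapply(c(1, 3), function(sep) {
    co <- generate_cohort(two_class_config(separation = sep, seed = 2,
                                           counts = c(6L, 6L)))
    feats <- do.call(rbind, lapply(co, `[[`, "features"))
    truth <- unlist(lapply(co, `[[`, "patch_truth"))
    enc <- encoder_spec("identity")
    z <- encode(feats, enc)
    mu1 <- colMeans(z[truth == 1, , drop = FALSE])
    mu2 <- colMeans(z[truth == 2, , drop = FALSE])
    sqrt(sum((mu1 - mu2)^2))
  }, numeric(1))
  expect_gt(margins[2], margins[1])
})

test_that("identity encoding passes vectors through unchanged; mlp is deterministic", {
  x <- matrix(rnorm(3 * 10), 3, 10)
  expect_identical(encode(x, encoder_spec("identity")), x)
  enc <- encoder_spec("mlp", input_dim = 10, seed = 4)
  expect_identical(encode(x, enc), encode(x, enc))
  expect_error(encode(matrix(0, 2, 7), enc), "dimension mismatch")
  ## snapshot/restore round-trips weights exactly
  enc2 <- encoder_restore(encoder_snapshot(enc))
  expect_identical(encode(x, enc2), encode(x, enc))
})

test_that("evaluation metrics match hand-computed values", {
  ## perfect predictions
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3),
                             diag(3), n_classes = 3)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$f1, 1)
  expect_equal(ev$macro_auc, 1)
  ## symmetric confusion matrix [[1,1],[1,1]]: all metrics 0.5
  ev2 <- evaluate_predictions(c(1, 2, 1, 2), c(1, 1, 2, 2), n_classes = 2)
  expect_equal(unname(as.vector(ev2$confusion)), rep(1, 4))
  expect_equal(ev2$accuracy, 0.5)
  expect_equal(ev2$precision, 0.5)
  expect_equal(ev2$recall, 0.5)
  expect_equal(ev2$f1, 0.5)
  ## absent class is excluded with a warning
  expect_warning(evaluate_predictions(c(1, 2), c(1, 1), n_classes = 2),
                 "absent")
})

test_that("macro AUC of random scores is near one half", {
  set.seed(9)
  n <- 300
  truth <- sample(1:3, n, replace = TRUE)
  scores <- matrix(runif(n * 3), n)
  scores <- scores / rowSums(scores)
  pred <- apply(scores, 1, which.max)
  ev <- evaluate_predictions(pred, truth, scores, n_classes = 3)
  expect_lt(abs(ev$macro_auc - 0.5), 0.08)
})
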
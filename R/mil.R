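#' Training hyperparameters
#'
#' Defaults follow standard practice for attention-MIL slide classifiers:
#' Adam, slide-level batch size 1 with initial learning rate 1e-4 for the
#' MIL head, batch size 64 with learning rate 5e-5 for the patch classifier,
#' both decayed by 0.5 every 10 epochs.
#'
#' @param mil_batch_size bags per MIL update (1; each slide is one batch).
#' @param mil_lr initial MIL learning rate.
#' @param patch_batch_size patch-classifier minibatch size.
#' @param patch_lr initial patch-classifier learning rate.
#' @param lr_decay multiplicative decay factor, in (0, 1].
#' @param decay_every epochs between decays.
#' @param epochs maximum training epochs.
#' @param patience early-stop patience on validation accuracy (epochs).
#' @param patch_optimizer optimizer for the auxiliary patch classifier:
#'   `"sgd"` (plain minibatch gradient descent; default) or `"adam"`.  The
#'   MIL head always uses Adam.  On the phantom's low-dimensional feature
#'   bags, Adam's per-coordinate step normalisation inflates weights along
#'   pure-noise feature dimensions of the small linear patch head, so plain
#'   gradient descent generalises markedly better there; for a large CNN
#'   backbone `"adam"` is the conventional choice.
#' @param seed integer seed controlling initialisation and shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(mil_batch_size = 1L, mil_lr = 1e-4,
                         patch_batch_size = 64L, patch_lr = 5e-5,
                         lr_decay = 0.5, decay_every = 10L,
                         epochs = 50L, patience = 10L,
                         patch_optimizer = c("sgd", "adam"), seed = 1L) {
  stopifnot(mil_lr > 0, patch_lr > 0, lr_decay > 0, lr_decay <= 1,
            epochs >= 1, mil_batch_size >= 1, patch_batch_size >= 1)
  structure(list(mil_batch_size = as.integer(mil_batch_size),
                 mil_lr = mil_lr,
                 patch_batch_size = as.integer(patch_batch_size),
                 patch_lr = patch_lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 patch_optimizer = match.arg(patch_optimizer),
                 seed = as.integer(seed)),
            class = "train_config")
}

## Parameter initialisation for the gated-attention MIL head.
##
## The attention score of instance i for class c combines a gated
## (tanh x sigmoid) branch with a linear instance-evidence term
## z_i' Psi[, c].  Bag-level cross-entropy alone cannot identify *which*
## instances carry the class evidence: a head that attends the background
## patches common to all slides and classifies through the attention
## leakage is as good a bag classifier as one that attends the tumor
## patches, so the attention ranking -- which drives pseudo-labelling --
## is unidentified.  The instance-evidence term is additionally trained
## with a mean-pooled instance-level auxiliary loss (see train_mil), which
## pins the correct sign: only instances whose presence predicts the bag
## label earn positive evidence.
mil_init <- function(input_dim, n_classes, hidden = 128L, seed = 1L) {
  with_seed(seed, {
    s0 <- sqrt(1 / input_dim); sh <- sqrt(1 / hidden)
    list(V = matrix(stats::rnorm(input_dim * hidden, 0, s0), input_dim),
         U = matrix(stats::rnorm(input_dim * hidden, 0, s0), input_dim),
         w = matrix(stats::rnorm(hidden * n_classes, 0, sh), hidden),
         Psi = matrix(stats::rnorm(input_dim * n_classes, 0, s0), input_dim),
         Phi = matrix(stats::rnorm(input_dim * n_classes, 0, s0), input_dim),
         beta = numeric(n_classes))
  })
}

## Forward pass of the gated-attention head on one bag (Z: N x D).
## The raw attention score of instance i for class c is
##   E[i, c] = 2 * sigmoid(gate[i, c]) * inst[i, c]
## with gate = (tanh(Z V) * sigmoid(Z U)) w  (the gated tanh x sigmoid
## branch) and inst = Z Psi the signed instance-evidence score.  The gate
## is strictly positive, so it modulates the magnitude of the evidence but
## cannot flip its sign — the attention ranking stays anchored to the
## instance evidence, which is what the instance-level auxiliary loss
## identifies (factor 2 centres the gate at 1).
mil_forward <- function(Z, par, keep = FALSE) {
  TT <- tanh(Z %*% par$V)
  S <- stats::plogis(Z %*% par$U)
  G <- TT * S
  inst <- Z %*% par$Psi                 # N x C instance evidence scores
  Sg <- 2 * stats::plogis(G %*% par$w)  # positive gate in (0, 2)
  E <- Sg * inst                        # N x C raw attention scores
  A <- col_softmax(E)                   # per-class attention over instances
  Fm <- crossprod(A, Z)                 # C x D per-class bag features
  logits <- rowSums(Fm * t(par$Phi)) + par$beta
  probs <- softmax(logits)
  out <- list(probs = probs, attention = A, bag_features = Fm,
              logits = logits,
              instance_logits = colMeans(inst))
  if (keep) out$cache <- list(TT = TT, S = S, G = G, Sg = Sg, inst = inst)
  out
}

## backward pass: gradient of weighted cross-entropy wrt head parameters.
## `entropy_weight` adds an attention-entropy penalty: diffuse attention can
## classify bags through the bag mean without ever localising the class
## evidence, so a small sharpness pressure keeps the attention ranking
## informative (which the pseudo-labelling stage depends on).
mil_backward <- function(Z, y, par, fw, weight = 1, entropy_weight = 0,
                         instance_weight = 0) {
  C <- length(fw$probs)
  N <- nrow(Z)
  dlogits <- fw$probs
  dlogits[y] <- dlogits[y] - 1
  dlogits <- dlogits * weight
  dbeta <- dlogits
  dPhi <- fw$bag_features * 0
  dFm <- matrix(0, C, ncol(Z))
  for (c in seq_len(C)) {
    dPhi[c, ] <- dlogits[c] * fw$bag_features[c, ]
    dFm[c, ] <- dlogits[c] * par$Phi[, c]
  }
  A <- fw$attention
  dA <- Z %*% t(dFm)                    # N x C
  if (entropy_weight > 0 && N > 1L) {
    ## d/da of H = -sum(a log a) is -(log a + 1)
    dA <- dA - entropy_weight * (log(pmax(A, 1e-12)) + 1)
  }
  colsum <- colSums(A * dA)
  dE <- A * sweep(dA, 2L, colsum, "-")
  cache <- fw$cache
  ## E = Sg * inst with Sg = 2 * sigmoid(gate)
  dinst_attn <- dE * cache$Sg
  dSg <- dE * cache$inst
  dgate <- dSg * cache$Sg * (1 - cache$Sg / 2)  # d/dx 2*sigmoid = Sg(1-Sg/2)
  dw <- crossprod(cache$G, dgate)
  dG <- dgate %*% t(par$w)
  dT <- dG * cache$S
  dS <- dG * cache$TT
  dZV <- dT * (1 - cache$TT^2)
  dZU <- dS * cache$S * (1 - cache$S)
  dPsi <- crossprod(Z, dinst_attn)
  ## the mean-pooled instance auxiliary loss adds its own CE gradient
  if (instance_weight > 0) {
    dinst <- softmax(fw$instance_logits)
    dinst[y] <- dinst[y] - 1
    dinst <- dinst * weight * instance_weight
    dPsi <- dPsi + crossprod(Z, matrix(dinst, N, C, byrow = TRUE) / N)
  }
  list(V = crossprod(Z, dZV), U = crossprod(Z, dZU), w = dw, Psi = dPsi,
       Phi = t(dPhi), beta = dbeta)
}

#' Attention aggregation of one bag
#'
#' Applies the attention-MIL head to a bag: per class, an attention score
#' per instance (softmax-normalised over the bag) from a signed
#' instance-evidence score modulated by a positive gated tanh-times-sigmoid
#' branch, the class bag feature as the attention-weighted sum of instance
#' features, and bag class probabilities from per-class linear scores on
#' the aggregated features.
#'
#' @param bag numeric matrix, one instance feature vector per row (N x D).
#' @param par MIL head parameters (from a fitted model's `$par`, or
#'   `mil_init()` internally).
#' @return list with `probs` (length-C, sums to 1), `attention` (N x C,
#'   each column sums to 1), `bag_features` (C x D), `logits`.
#' @export
attention_aggregate <- function(bag, par) {
  if (!is.matrix(bag)) bag <- matrix(bag, nrow = 1L)
  stopifnot(nrow(bag) >= 1L)
  mil_forward(bag, par)
}

#' Train the attention-MIL bag classifier
#'
#' Minimises (optionally class-weighted) cross-entropy on bag probabilities
#' with Adam, one slide per update, stepwise learning-rate decay, and early
#' stopping on validation bag accuracy.  Deterministic given
#' `config$seed` (single-threaded).
#'
#' @param bags list of N_i x D feature matrices.
#' @param labels integer bag labels in `1..n_classes`.
#' @param config a [train_config()].
#' @param val_bags,val_labels optional validation set for early stopping and
#'   best-epoch selection.
#' @param n_classes number of classes (default `max(labels)`).
#' @param class_weights optional per-class loss weights (default
#'   inverse-frequency, normalised to mean 1).
#' @param hidden attention hidden width (default 128).
#' @param entropy_weight weight of an attention-sharpness penalty
#'   (negative attention entropy) added to the loss; 0 disables (default).
#' @param instance_weight weight of the mean-pooled instance-level
#'   auxiliary cross-entropy that trains the instance-evidence term of the
#'   attention score (default 1).  This pins the attention ranking to the
#'   instances whose presence actually predicts the bag label; without it
#'   the ranking is unidentified (see `mil_init` internals).  Set 0 to
#'   train a pure bag-level gated-attention head.
#' @param gate_decay optional per-epoch multiplicative weight decay on the
#'   gated branch (`V`, `U`, `w`); 0 disables (default), since the
#'   multiplicative gate is sign-safe by construction.
#' @param psi_decay per-epoch multiplicative weight decay on the
#'   instance-evidence matrix `Psi` (default 0.2).  With few bags, Adam's
#'   per-coordinate normalisation inflates `Psi` along pure-noise feature
#'   dimensions as fast as along class signatures; a mild decay lets the
#'   persistently reinforced signal dimensions dominate the ranking.
#' @return object of class `thymil_mil`: list with `par` (best parameters),
#'   `n_classes`, `history` (per-epoch data frame), `best_epoch`,
#'   `val_accuracy`.
#' @export
train_mil <- function(bags, labels, config = train_config(),
                      val_bags = NULL, val_labels = NULL,
                      n_classes = max(labels), class_weights = NULL,
                      hidden = 128L, entropy_weight = 0,
                      instance_weight = 1, gate_decay = 0, psi_decay = 0.2) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("train_mil requires at least 2 classes present in labels")
  }
  stopifnot(length(bags) == length(labels))
  D <- ncol(bags[[1]])
  if (is.null(class_weights)) {
    freq <- tabulate(labels, n_classes)
    class_weights <- ifelse(freq > 0, mean(freq[freq > 0]) / freq, 0)
  }
  par <- mil_init(D, n_classes, hidden = hidden, seed = config$seed)
  st <- adam_init(par)
  seeds <- derive_seeds(config$seed + 1L, config$epochs)
  has_val <- !is.null(val_bags) && length(val_bags) > 0
  best <- list(par = par, val = -Inf, val_loss = Inf, epoch = 0L)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     train_acc = numeric(0), val_acc = numeric(0),
                     val_loss = numeric(0))
  wait <- 0L
  for (ep in seq_len(config$epochs)) {
    lr <- decayed_lr(config$mil_lr, ep, config$lr_decay, config$decay_every)
    ord <- with_seed(seeds[ep], sample.int(length(bags)))
    loss <- 0; correct <- 0L
    for (i in ord) {
      Z <- bags[[i]]; y <- labels[i]
      fw <- mil_forward(Z, par, keep = TRUE)
      wgt <- class_weights[y]
      loss <- loss - wgt * log(max(fw$probs[y], 1e-12))
      if (which.max(fw$probs) == y) correct <- correct + 1L
      gr <- mil_backward(Z, y, par, fw, weight = wgt,
                         entropy_weight = entropy_weight,
                         instance_weight = instance_weight)
      upd <- adam_step(par, gr, st, lr)
      par <- upd$par; st <- upd$state
    }
    if (gate_decay > 0) {
      for (nm in c("V", "U", "w")) {
        par[[nm]] <- par[[nm]] * (1 - gate_decay)
      }
    }
    if (psi_decay > 0) par$Psi <- par$Psi * (1 - psi_decay)
    val_acc <- val_loss <- NA_real_
    if (has_val) {
      vprob <- lapply(val_bags, function(Z) mil_forward(Z, par)$probs)
      vp <- vapply(vprob, which.max, integer(1))
      val_acc <- mean(vp == val_labels)
      val_loss <- -mean(log(pmax(mapply(function(p, y) p[y], vprob,
                                        val_labels), 1e-12)))
      ## validation loss governs checkpoint selection and early stopping:
      ## with the small validation sets typical of slide cohorts, accuracy
      ## is too coarse (a single slide flips it) and tends to freeze a
      ## barely-trained head whose attention is still uninformative
      if (val_loss < best$val_loss - 1e-9) {
        best <- list(par = par, val = val_acc, val_loss = val_loss,
                     epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = loss / length(bags),
                                   train_acc = correct / length(bags),
                                   val_acc = val_acc, val_loss = val_loss))
    if (has_val && wait >= config$patience) break
  }
  if (!has_val) best <- list(par = par, val = NA_real_, epoch = nrow(hist))
  structure(list(par = best$par, n_classes = n_classes, history = hist,
                 best_epoch = best$epoch, val_accuracy = best$val,
                 hidden = hidden),
            class = "thymil_mil")
}

#' Predict bag class probabilities
#'
#' @param model a fitted [train_mil()] object.
#' @param bags list of feature matrices.
#' @return matrix of probabilities, one row per bag.
#' @export
predict_mil <- function(model, bags) {
  stopifnot(inherits(model, "thymil_mil"))
  t(vapply(bags, function(Z) mil_forward(Z, model$par)$probs,
           numeric(model$n_classes)))
}

#' Classification metrics for slide predictions
#'
#' Computes the confusion matrix, overall accuracy, and macro-averaged
#' one-vs-rest precision, recall, and F1 (per class: `TP/(TP+FP)`,
#' `TP/(TP+FN)`, and their harmonic mean), plus the macro-averaged
#' one-vs-rest ROC AUC when class scores are supplied.  Classes absent from
#' the truth are excluded from the macro averages with a warning.
#'
#' @param pred integer predicted labels.
#' @param truth integer true labels.
#' @param scores optional score matrix (rows sum to 1) for AUC.
#' @param n_classes number of classes.
#' @return list with `confusion`, `accuracy`, `precision`, `recall`, `f1`,
#'   `macro_auc`, and a `per_class` data frame.
#' @export
evaluate_predictions <- function(pred, truth, scores = NULL,
                                 n_classes = max(c(pred, truth))) {
  stopifnot(length(pred) == length(truth))
  lev <- seq_len(n_classes)
  cm <- table(factor(truth, lev), factor(pred, lev))
  acc <- sum(diag(cm)) / sum(cm)
  present <- which(rowSums(cm) > 0)
  if (length(present) < n_classes) {
    warning("classes absent from truth excluded from macro averages: ",
            paste(setdiff(lev, present), collapse = ", "))
  }
  prec <- rec <- f1 <- auc <- rep(NA_real_, n_classes)
  for (c in present) {
    tp <- cm[c, c]; fp <- sum(cm[-c, c]); fn <- sum(cm[c, -c])
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- tp / (tp + fn)
    f1[c] <- if (prec[c] + rec[c] > 0) {
      2 * prec[c] * rec[c] / (prec[c] + rec[c])
    } else 0
    if (!is.null(scores) && length(unique(truth == c)) == 2L) {
      auc[c] <- as.numeric(pROC::auc(pROC::roc(
        response = as.integer(truth == c), predictor = scores[, c],
        quiet = TRUE, direction = "<", levels = c(0L, 1L))))
    }
  }
  list(confusion = unclass(cm),
       accuracy = acc,
       precision = mean(prec[present]),
       recall = mean(rec[present]),
       f1 = mean(f1[present]),
       macro_auc = if (all(is.na(auc))) NA_real_ else mean(auc, na.rm = TRUE),
       per_class = data.frame(class = lev, precision = prec, recall = rec,
                              f1 = f1, auc = auc))
}
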
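#' Patch confidence score
#'
#' The confidence of a patch for a category is the product of its attention
#' score (from the MIL head, for that category) and its category score from
#' the auxiliary patch classifier: `s = a * p`.
#'
#' @param attention attention score(s) in \[0, 1\].
#' @param patch_score patch-classifier category score(s) in \[0, 1\].
#' @return numeric confidence(s) `attention * patch_score`.
#' @export
patch_confidence <- function(attention, patch_score) {
  if (any(attention < 0 | attention > 1, na.rm = FALSE) ||
      any(patch_score < 0 | patch_score > 1)) {
    stop("attention and patch_score must lie in [0, 1]")
  }
  attention * patch_score
}

#' Select top-k / bottom-k pseudo-labels for one slide
#'
#' Patches are sorted by descending confidence for the slide's category
#' (ties broken by ascending `patch_id`, a stable documented rule); the top
#' `k` receive the slide's class as pseudo-label, the bottom `k` the
#' background class `C + 1`.  If `2k > N`, `k` shrinks to `floor(N / 2)`
#' with a warning.
#'
#' @param confidences data frame with columns `patch_id` and `s`
#'   (confidence for the slide's category).
#' @param slide_class integer slide class in `1..C`.
#' @param k patches per side (> 0).
#' @param n_classes total number of slide classes C (background is C + 1).
#' @return list with `positives`, `negatives` (patch id vectors), `labels`
#'   (named integer vector over selected patches) and the effective `k`.
#' @export
select_pseudo_labels <- function(confidences, slide_class, k,
                                 n_classes = slide_class) {
  stopifnot(is.data.frame(confidences),
            all(c("patch_id", "s") %in% names(confidences)))
  if (k <= 0) stop("k must be positive")
  n <- nrow(confidences)
  if (n < 2L) stop("need at least 2 patches to pseudo-label")
  k <- as.integer(k)
  if (2L * k > n) {
    k <- n %/% 2L
    warning("k shrunk to floor(N/2) = ", k)
    if (k == 0L) stop("bag too small for any pseudo-labels")
  }
  ord <- order(-confidences$s, confidences$patch_id)
  pos <- confidences$patch_id[ord[seq_len(k)]]
  neg <- confidences$patch_id[ord[(n - k + 1L):n]]
  labels <- c(stats::setNames(rep.int(as.integer(slide_class), k), pos),
              stats::setNames(rep.int(as.integer(n_classes) + 1L, k), neg))
  list(positives = pos, negatives = neg, labels = labels, k = k)
}

#' Create an auxiliary patch classifier sharing the MIL encoder
#'
#' The patch classifier is a softmax head over `{1..C+1}` (slide classes
#' plus background) on top of the *shared* encoder: the `encoder` argument
#' is stored by reference, so training the patch classifier updates the
#' encoder used for bag feature extraction (the weight-sharing contract of
#' the refinement loop).
#'
#' @param encoder a [encoder_spec()] object (shared, not copied).
#' @param input_dim raw patch input dimension.
#' @param n_out number of output classes (C + 1).
#' @param seed seed for head initialisation.
#' @return object of class `thymil_patch_classifier`.
#' @export
patch_classifier <- function(encoder, input_dim, n_out, seed = 1L) {
  d <- if (encoder$kind == "identity") input_dim else encoder$output_dim
  ## zero-initialised softmax head (standard for linear probe heads)
  head <- list(W = matrix(0, d, n_out), b = numeric(n_out))
  structure(list(encoder = encoder, head = head, n_out = as.integer(n_out),
                 input_dim = as.integer(input_dim)),
            class = "thymil_patch_classifier")
}

#' Predict patch class probabilities
#'
#' @param classifier a [patch_classifier()].
#' @param x matrix of raw patch inputs (one per row).
#' @return probability matrix, one row per patch, `n_out` columns.
#' @export
predict_patch <- function(classifier, x) {
  stopifnot(inherits(classifier, "thymil_patch_classifier"))
  z <- encode(x, classifier$encoder)
  row_softmax(sweep(z %*% classifier$head$W, 2L, classifier$head$b, "+"))
}

#' Train the auxiliary patch classifier (and shared encoder)
#'
#' Cross-entropy minimisation with Adam over minibatches; gradients flow
#' into the classification head *and* the shared encoder (if the encoder is
#' trainable), so the MIL feature extractor is refined in place.
#'
#' @param classifier a [patch_classifier()]; modified in place (the encoder
#'   is an environment) and also returned.
#' @param x matrix of raw pseudo-labelled patch inputs.
#' @param y integer labels in `1..n_out`.
#' @param config a [train_config()] (uses `patch_batch_size`, `patch_lr`,
#'   `lr_decay`, `decay_every`, `epochs`).
#' @param epochs optional override of `config$epochs`.
#' @param class_weights per-class loss weights; default inverse-frequency
#'   (normalised to mean 1), since pseudo-label sets are dominated by the
#'   background class.
#' @return the classifier, with a `history` attribute of per-epoch losses.
#' @export
train_patch_classifier <- function(classifier, x, y, config = train_config(),
                                   epochs = NULL, class_weights = NULL) {
  stopifnot(inherits(classifier, "thymil_patch_classifier"))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("patch classifier training requires at least 2 classes present")
  }
  stopifnot(nrow(x) == length(y))
  n_out <- classifier$n_out
  if (is.null(class_weights)) {
    freq <- tabulate(y, n_out)
    class_weights <- ifelse(freq > 0, mean(freq[freq > 0]) / freq, 0)
  }
  enc <- classifier$encoder
  trainable_enc <- !is.null(encoder_params(enc))
  par <- classifier$head
  if (trainable_enc) par <- c(par, encoder_params(enc))
  use_adam <- identical(config$patch_optimizer, "adam")
  st <- adam_init(par)
  if (is.null(epochs)) epochs <- config$epochs
  seeds <- derive_seeds(config$seed + 7L, epochs)
  losses <- numeric(epochs)
  n <- nrow(x)
  bs <- min(config$patch_batch_size, n)
  for (ep in seq_len(epochs)) {
    lr <- decayed_lr(config$patch_lr, ep, config$lr_decay, config$decay_every)
    ord <- with_seed(seeds[ep], sample.int(n))
    ep_loss <- 0
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      cache <- encode_cached(xb, enc)
      logits <- sweep(cache$z %*% par$W, 2L, par$b, "+")
      P <- row_softmax(logits)
      wb <- class_weights[yb]
      ep_loss <- ep_loss -
        sum(wb * log(pmax(P[cbind(seq_along(yb), yb)], 1e-12)))
      dlogits <- P
      dlogits[cbind(seq_along(yb), yb)] <-
        dlogits[cbind(seq_along(yb), yb)] - 1
      dlogits <- dlogits * wb / length(yb)
      gr <- list(W = crossprod(cache$z, dlogits), b = colSums(dlogits))
      if (trainable_enc) {
        dz <- dlogits %*% t(par$W)
        gr <- c(gr, encoder_grad(xb, cache, dz, enc))
      }
      if (use_adam) {
        upd <- adam_step(par, gr, st, lr)
        par <- upd$par; st <- upd$state
      } else {
        for (nm in names(par)) par[[nm]] <- par[[nm]] - lr * gr[[nm]]
      }
      if (trainable_enc) {
        encoder_set_params(enc, par[c("W1", "b1", "W2", "b2")])
      }
    }
    losses[ep] <- ep_loss / n
  }
  classifier$head <- list(W = par$W, b = par$b)
  attr(classifier, "history") <- losses
  classifier
}

## per-slide confidence records for the slide's own category
slide_confidences <- function(Z_enc, slide_class, mil_par, classifier = NULL,
                              x_raw = NULL) {
  fw <- mil_forward(Z_enc, mil_par)
  a <- fw$attention[, slide_class]
  p <- if (is.null(classifier)) {
    rep.int(1, nrow(Z_enc))  # bootstrap round: no patch classifier yet
  } else {
    predict_patch(classifier, x_raw)[, slide_class]
  }
  data.frame(patch_id = seq_len(nrow(Z_enc)),
             category = slide_class,
             attention = a, patch_score = p,
             s = patch_confidence(a, p))
}

#' Pseudo-label refinement loop
#'
#' Alternating optimisation: per round, (1) train/refresh the MIL head on
#' current encoded features, (2) score per-patch confidences with the
#' current-best MIL head and current-best patch classifier (in the first
#' round there is no patch classifier yet, so the category score is taken
#' as 1 and the confidence reduces to the attention score), (3) select
#' per-slide top-k/bottom-k pseudo-labels, (4) train the patch classifier /
#' shared encoder on them, (5) re-extract all bag features.  Pseudo-labels
#' are regenerated from scratch each round.  "Current best" means highest
#' validation bag accuracy seen so far (ties resolve to the earlier round).
#'
#' @param bags_raw list of raw (pre-encoder) N_i x D0 patch matrices.
#' @param labels integer bag labels in `1..n_classes`.
#' @param val_bags_raw,val_labels validation bags/labels.
#' @param n_classes number of bag classes C.
#' @param config a [train_config()].
#' @param n_rounds maximum refinement rounds (>= 1; default 3).
#' @param k pseudo-labels per side per slide; `NULL` for the scale-free
#'   default `max(1, ceiling(0.1 * N))`.
#' @param encoder shared encoder (default: a fresh MLP refiner); pass an
#'   identity encoder to disable feature refinement, in which case one round
#'   degenerates to plain MIL training.
#' @param patience_rounds stop after this many rounds without validation
#'   improvement (default 1).
#' @param class_weights optional MIL loss class weights.
#' @return object of class `thymil_bundle`: list with `mil` (best MIL
#'   model), `encoder` (snapshot of the best encoder state), `patch_model`
#'   (last patch classifier), `log` (per-round data frame with
#'   `round`, `val_acc`, `best`), `best_round`, `n_classes`.
#' @export
refine_loop <- function(bags_raw, labels, val_bags_raw = NULL,
                        val_labels = NULL, n_classes = max(labels),
                        config = train_config(), n_rounds = 3L, k = NULL,
                        encoder = NULL, patience_rounds = 1L,
                        class_weights = NULL) {
  stopifnot(n_rounds >= 1L)
  labels <- as.integer(labels)
  D0 <- ncol(bags_raw[[1]])
  if (is.null(encoder)) {
    encoder <- encoder_spec("mlp", input_dim = D0, seed = config$seed + 97L)
  }
  classifier <- NULL
  best <- list(val = -Inf, round = 0L, mil = NULL, encoder = NULL)
  log <- data.frame(round = integer(0), val_acc = numeric(0),
                    best = logical(0))
  wait <- 0L
  for (r in seq_len(n_rounds)) {
    Zs <- lapply(bags_raw, encode, encoder = encoder)
    vZs <- if (!is.null(val_bags_raw)) {
      lapply(val_bags_raw, encode, encoder = encoder)
    }
    cfg_r <- config
    cfg_r$seed <- config$seed + r
    mil <- train_mil(Zs, labels, cfg_r, vZs, val_labels,
                     n_classes = n_classes, class_weights = class_weights)
    val_acc <- mil$val_accuracy
    improved <- is.na(val_acc) || val_acc > best$val + 1e-12
    if (improved) {
      best <- list(val = if (is.na(val_acc)) -Inf else val_acc, round = r,
                   mil = mil, encoder = encoder_snapshot(encoder))
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    log <- rbind(log, data.frame(round = r, val_acc = val_acc,
                                 best = improved))
    if (r == n_rounds || (!improved && wait >= patience_rounds)) break

    ## (2)-(4): pseudo-label with the current-best scorer, retrain the
    ## patch classifier / encoder, then features are re-extracted at the
    ## top of the next round
    best_enc <- encoder_restore(best$encoder)
    px <- list(); py <- list()
    for (i in seq_along(bags_raw)) {
      Zb <- encode(bags_raw[[i]], best_enc)
      conf <- slide_confidences(Zb, labels[i], best$mil$par, classifier,
                                bags_raw[[i]])
      ki <- if (is.null(k)) max(1L, ceiling(0.1 * nrow(Zb))) else k
      sel <- select_pseudo_labels(conf, labels[i], ki, n_classes)
      ids <- as.integer(names(sel$labels))
      px[[i]] <- bags_raw[[i]][ids, , drop = FALSE]
      py[[i]] <- unname(sel$labels)
    }
    X <- do.call(rbind, px)
    Y <- unlist(py)
    if (length(unique(Y)) < 2L) {
      warning("pseudo-label set collapsed to one class; stopping refinement")
      break
    }
    if (is.null(classifier)) {
      classifier <- patch_classifier(encoder, D0, n_classes + 1L,
                                     seed = config$seed + 11L)
    }
    cfg_p <- config
    cfg_p$seed <- config$seed + 100L + r
    classifier <- train_patch_classifier(classifier, X, Y, cfg_p)
  }
  structure(list(mil = best$mil, encoder = best$encoder,
                 patch_model = classifier, log = log,
                 best_round = best$round, n_classes = n_classes),
            class = "thymil_bundle")
}

#' Predict bag probabilities with a refined bundle
#'
#' @param bundle a [refine_loop()] result.
#' @param bags_raw list of raw patch matrices.
#' @return probability matrix, one row per bag.
#' @export
predict_bundle <- function(bundle, bags_raw) {
  stopifnot(inherits(bundle, "thymil_bundle"))
  enc <- encoder_restore(bundle$encoder)
  Zs <- lapply(bags_raw, encode, encoder = enc)
  predict_mil(bundle$mil, Zs)
}
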
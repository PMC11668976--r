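#' Create a patch-feature encoder
#'
#' The encoder `E(.)` maps raw per-patch inputs to the feature vectors the
#' MIL head aggregates.  It is deliberately decoupled from the bag classifier
#' so it can be refined with pseudo-labelled patches while the rest of the
#' pipeline is untouched, and so alternative backbones (e.g. a pretrained
#' CNN applied offline) can be plugged in by supplying precomputed features
#' with the `"identity"` kind.
#'
#' Kinds:
#' * `"identity"` — passes precomputed feature vectors through unchanged
#'   (feature-bag mode; has no trainable weights, so refinement is a no-op).
#' * `"mlp"` — a small one-hidden-layer perceptron (tanh hidden layer); this
#'   is the trainable refiner used by the pseudo-label loop at desk scale.
#'
#' Encoders are environments: the pseudo-label patch classifier *shares* the
#' encoder weights by reference, so training the patch classifier updates the
#' encoder seen by the MIL stage (the weight-sharing contract).
#'
#' @param kind `"identity"` or `"mlp"`.
#' @param input_dim dimension of raw inputs (required for `"mlp"`).
#' @param output_dim encoder output dimension (`"mlp"` only; default 32).
#' @param hidden_dim hidden width of the MLP (default 48).
#' @param seed integer seed for weight initialisation.
#' @return an object of class `thymil_encoder` (an environment).
#' @export
encoder_spec <- function(kind = c("identity", "mlp"), input_dim = NULL,
                         output_dim = 32L, hidden_dim = 48L, seed = 1L) {
  kind <- match.arg(kind)
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  if (kind == "mlp") {
    if (is.null(input_dim)) stop("input_dim is required for an mlp encoder")
    e$input_dim <- as.integer(input_dim)
    e$output_dim <- as.integer(output_dim)
    with_seed(seed, {
      s1 <- sqrt(1 / input_dim)
      s2 <- sqrt(1 / hidden_dim)
      e$W1 <- matrix(stats::rnorm(input_dim * hidden_dim, 0, s1), input_dim)
      e$b1 <- numeric(hidden_dim)
      e$W2 <- matrix(stats::rnorm(hidden_dim * output_dim, 0, s2), hidden_dim)
      e$b2 <- numeric(output_dim)
    })
  }
  class(e) <- "thymil_encoder"
  e
}

#' Encode a matrix of raw patch inputs
#'
#' @param x numeric matrix, one patch per row.
#' @param encoder a [encoder_spec()] object.
#' @return numeric matrix of encoded features, one row per patch, order
#'   preserved.
#' @export
encode <- function(x, encoder) {
  stopifnot(inherits(encoder, "thymil_encoder"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (encoder$kind == "identity") return(x)
  if (ncol(x) != encoder$input_dim) {
    stop("encoder input dimension mismatch: got ", ncol(x), ", expected ",
         encoder$input_dim)
  }
  h <- tanh(sweep(x %*% encoder$W1, 2L, encoder$b1, "+"))
  sweep(h %*% encoder$W2, 2L, encoder$b2, "+")
}

## forward pass keeping the hidden activations (for backprop)
encode_cached <- function(x, encoder) {
  if (encoder$kind == "identity") return(list(z = x, h = NULL))
  h <- tanh(sweep(x %*% encoder$W1, 2L, encoder$b1, "+"))
  list(z = sweep(h %*% encoder$W2, 2L, encoder$b2, "+"), h = h)
}

## backprop dL/dz into encoder parameter gradients (NULL for identity)
encoder_grad <- function(x, cache, dz, encoder) {
  if (encoder$kind == "identity") return(NULL)
  h <- cache$h
  dW2 <- crossprod(h, dz)
  db2 <- colSums(dz)
  dh <- (dz %*% t(encoder$W2)) * (1 - h * h)
  dW1 <- crossprod(x, dh)
  db1 <- colSums(dh)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

encoder_params <- function(encoder) {
  if (encoder$kind == "identity") return(NULL)
  list(W1 = encoder$W1, b1 = encoder$b1, W2 = encoder$W2, b2 = encoder$b2)
}

encoder_set_params <- function(encoder, par) {
  if (encoder$kind == "identity") return(invisible(encoder))
  encoder$W1 <- par$W1; encoder$b1 <- par$b1
  encoder$W2 <- par$W2; encoder$b2 <- par$b2
  invisible(encoder)
}

#' Snapshot / restore an encoder
#'
#' `encoder_snapshot()` converts an encoder environment into a plain list
#' (safe to copy or serialize); `encoder_restore()` rebuilds an independent
#' encoder environment from such a snapshot.
#'
#' @param encoder a `thymil_encoder`.
#' @return `encoder_snapshot()`: a list; `encoder_restore()`: a new
#'   `thymil_encoder` not sharing state with the original.
#' @export
encoder_snapshot <- function(encoder) {
  out <- mget(ls(envir = encoder), envir = encoder)
  out$class <- "thymil_encoder_snapshot"
  out
}

#' @rdname encoder_snapshot
#' @param snapshot a list produced by `encoder_snapshot()`.
#' @export
encoder_restore <- function(snapshot) {
  e <- new.env(parent = emptyenv())
  for (nm in setdiff(names(snapshot), "class")) assign(nm, snapshot[[nm]], envir = e)
  class(e) <- "thymil_encoder"
  e
}

#' Summary-statistics descriptor for RGB image tiles
#'
#' A deterministic, parameter-free image featurizer used in image mode: each
#' tile is divided into a `blocks` x `blocks` grid and the per-block mean and
#' standard deviation of each RGB channel are concatenated
#' (`blocks^2 * 3 * 2` features).  It carries colour and coarse spatial
#' texture, which is what the phantom encodes; a CNN backbone can replace it
#' via precomputed features and the identity encoder.
#'
#' @param tiles list of H x W x 3 arrays in \[0, 1\].
#' @param blocks grid subdivisions per side (default 4).
#' @return numeric matrix, one row per tile.
#' @export
featurize_tiles <- function(tiles, blocks = 4L) {
  stopifnot(length(tiles) >= 1L)
  feat_one <- function(img) {
    stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
    h <- dim(img)[1]; w <- dim(img)[2]
    ri <- pmin(blocks, ceiling(seq_len(h) / (h / blocks)))
    ci <- pmin(blocks, ceiling(seq_len(w) / (w / blocks)))
    out <- numeric(0)
    for (ch in 1:3) {
      m <- img[, , ch]
      grp <- (rep(ri, times = w) - 1L) * blocks + rep(ci, each = h)
      mu <- tapply(as.vector(m), grp, mean)
      sd_ <- tapply(as.vector(m), grp, stats::sd)
      sd_[is.na(sd_)] <- 0
      out <- c(out, as.numeric(mu), as.numeric(sd_))
    }
    out
  }
  do.call(rbind, lapply(tiles, feat_one))
}
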
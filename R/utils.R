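#' @keywords internal
"_PACKAGE"

## Numeric helpers shared across the training code.

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

## column-wise softmax of a matrix (softmax over rows, per column)
col_softmax <- function(E) {
  E <- sweep(E, 2L, apply(E, 2L, max), "-")
  E <- exp(E)
  sweep(E, 2L, colSums(E), "/")
}

## row-wise softmax (per-observation class probabilities)
row_softmax <- function(E) {
  E <- sweep(E, 1L, apply(E, 1L, max), "-")
  E <- exp(E)
  sweep(E, 1L, rowSums(E), "/")
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG streams are untouched.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

## Derive n reproducible child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## ---- Adam optimizer over a named list of numeric arrays -------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

## learning rate with step decay
decayed_lr <- function(lr0, epoch, decay = 0.5, every = 10L) {
  lr0 * decay^(floor((epoch - 1L) / every))
}
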
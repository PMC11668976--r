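# Shared fixtures, built in code.

two_class_config <- function(separation = 5, seed = 1L, counts = c(20L, 20L)) {
  phantom_config(class_labels = c("A", "B3"), class_counts = counts,
                 signature_separation = separation,
                 cell_params = default_cell_params(c("A", "B3")),
                 seed = seed)
}

## small cohort as bags + integer labels
cohort_bags <- function(cohort) {
  list(bags = lapply(cohort, `[[`, "features"),
       labels = vapply(cohort, `[[`, integer(1), "slide_label"),
       subtypes = vapply(cohort, `[[`, character(1), "subtype"))
}

## desk-scale training settings used throughout the phantom experiments;
## tiny cohorts take fewer optimizer steps per epoch, so they use a larger
## learning rate and a slower decay schedule
phantom_train_config <- function(seed = 0L, epochs = 30L, mil_lr = 1e-3,
                                 decay_every = 10L, patience = 8L) {
  train_config(mil_lr = mil_lr, patch_lr = 0.02, epochs = epochs,
               decay_every = decay_every, patience = patience, seed = seed)
}

## grid indices (1-based, row-major) within +/-1 tile of a tile block
dilate_block <- function(block, grid_rows, grid_cols) {
  unique(unlist(lapply(block, function(g) {
    r <- (g - 1) %/% grid_cols
    cc <- (g - 1) %% grid_cols
    cand <- expand.grid(r = r + (-1:1), cc = cc + (-1:1))
    cand <- cand[cand$r >= 0 & cand$r < grid_rows &
                   cand$cc >= 0 & cand$cc < grid_cols, ]
    cand$r * grid_cols + cand$cc + 1
  })))
}
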
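#' Build the default divide-and-conquer hierarchy
#'
#' Root binary split of the five WHO thymoma subtypes into the
#' lymphocyte-poor pair `{A, B3}` versus the lymphocyte-rich triple
#' `{AB, B1, B2}`, then an A-vs-B3 binary node and an AB/B1/B2 ternary
#' node.  Three classifier nodes, five leaves, each label reachable by
#' exactly one root-to-leaf path.
#'
#' @return a `hierarchy_node`: nested list with `name`, `class_subsets`
#'   (one label set per branch), `model` (NULL until fitted), and
#'   `children` (one per branch with more than one label, named by branch
#'   index).
#' @export
build_default_hierarchy <- function() {
  node <- function(name, subsets, children = list()) {
    structure(list(name = name, class_subsets = subsets, model = NULL,
                   children = children),
              class = "hierarchy_node")
  }
  node("root", list(c("A", "B3"), c("AB", "B1", "B2")),
       children = list(
         "1" = node("A_vs_B3", list("A", "B3")),
         "2" = node("AB_B1_B2", list("AB", "B1", "B2"))))
}

#' All leaf labels of a hierarchy, in branch order
#' @param tree a `hierarchy_node`.
#' @return character vector of leaf labels.
#' @export
hierarchy_leaves <- function(tree) {
  out <- character(0)
  for (b in seq_along(tree$class_subsets)) {
    subset <- tree$class_subsets[[b]]
    if (length(subset) == 1L) {
      out <- c(out, subset)
    } else {
      out <- c(out, hierarchy_leaves(tree$children[[as.character(b)]]))
    }
  }
  out
}

## count internal classifier nodes
hierarchy_n_nodes <- function(tree) {
  1L + sum(vapply(tree$children, hierarchy_n_nodes, integer(1)))
}

#' Fit every node of a divide-and-conquer hierarchy
#'
#' Each node's bag classifier is trained only on slides whose label lies in
#' that node's class subsets, with the branch index as the node-local label
#' and inverse-frequency class weights (the node-local class sizes are
#' imbalanced, e.g. 21 vs 83 slides at the ternary node).  With
#' `refine = TRUE` the pseudo-label [refine_loop()] runs per node (each node
#' gets its own encoder copy); otherwise a plain identity-encoder MIL fit is
#' used.
#'
#' @param tree a [build_default_hierarchy()] (or compatible) node.
#' @param bags_raw named list of raw patch matrices (names = slide ids).
#' @param labels named character vector of subtype labels per slide.
#' @param split list with `train` and `val` slide-id vectors.
#' @param config a [train_config()].
#' @param refine logical; run pseudo-label refinement per node.
#' @param n_rounds refinement rounds per node.
#' @param k pseudo-labels per side (NULL = auto).
#' @return the tree with a fitted `model` (`thymil_bundle`) at every
#'   internal node.
#' @export
fit_hierarchy <- function(tree, bags_raw, labels, split,
                          config = train_config(), refine = TRUE,
                          n_rounds = 3L, k = NULL) {
  stopifnot(inherits(tree, "hierarchy_node"))
  node_labels <- function(ids) {
    lab <- labels[ids]
    branch <- rep(NA_integer_, length(ids))
    for (b in seq_along(tree$class_subsets)) {
      branch[lab %in% tree$class_subsets[[b]]] <- b
    }
    branch
  }
  tr_ids <- split$train[labels[split$train] %in% unlist(tree$class_subsets)]
  va_ids <- split$val[labels[split$val] %in% unlist(tree$class_subsets)]
  tr_y <- node_labels(tr_ids)
  va_y <- node_labels(va_ids)
  for (b in seq_along(tree$class_subsets)) {
    if (!any(tr_y == b)) {
      stop("node '", tree$name, "': empty training set for branch ", b,
           " {", paste(tree$class_subsets[[b]], collapse = ","), "}")
    }
  }
  n_branch <- length(tree$class_subsets)
  if (refine) {
    tree$model <- refine_loop(bags_raw[tr_ids], tr_y,
                              bags_raw[va_ids], va_y,
                              n_classes = n_branch, config = config,
                              n_rounds = n_rounds, k = k)
  } else {
    enc <- encoder_spec("identity")
    Zs <- bags_raw[tr_ids]
    mil <- train_mil(Zs, tr_y, config, bags_raw[va_ids], va_y,
                     n_classes = n_branch)
    tree$model <- structure(list(mil = mil, encoder = encoder_snapshot(enc),
                                 patch_model = NULL,
                                 log = data.frame(round = 1L,
                                                  val_acc = mil$val_accuracy,
                                                  best = TRUE),
                                 best_round = 1L, n_classes = n_branch),
                            class = "thymil_bundle")
  }
  for (b in names(tree$children)) {
    tree$children[[b]] <- fit_hierarchy(tree$children[[b]], bags_raw, labels,
                                        split, config, refine, n_rounds, k)
  }
  tree
}

#' Predict a five-class distribution for one slide
#'
#' `hard` mode follows the argmax branch at each node and returns the
#' reached leaf (probability mass 1 on that leaf), along with the product of
#' traversed branch probabilities as `path_prob`.  `soft` mode assigns each
#' leaf the product of branch probabilities along its root-to-leaf path, a
#' proper distribution over the five labels.  The routing trace lists every
#' visited node with its branch probabilities.
#'
#' @param tree a fitted hierarchy.
#' @param bag_raw raw patch matrix for the slide.
#' @param mode `"hard"` or `"soft"`.
#' @return list with `probs` (named over leaf labels), `label` (argmax),
#'   `path_prob` (hard mode), and `trace`.
#' @export
predict_slide <- function(tree, bag_raw, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  leaves <- hierarchy_leaves(tree)
  trace <- list()
  descend_soft <- function(node, mass) {
    if (is.null(node$model)) stop("node '", node$name, "' is not fitted")
    p <- as.numeric(predict_bundle(node$model, list(bag_raw)))
    trace[[length(trace) + 1L]] <<- list(node = node$name, branch_probs = p)
    out <- stats::setNames(numeric(length(leaves)), leaves)
    for (b in seq_along(node$class_subsets)) {
      subset <- node$class_subsets[[b]]
      if (length(subset) == 1L) {
        out[subset] <- out[subset] + mass * p[b]
      } else {
        out <- out + descend_soft(node$children[[as.character(b)]],
                                  mass * p[b])
      }
    }
    out
  }
  descend_hard <- function(node, mass) {
    if (is.null(node$model)) stop("node '", node$name, "' is not fitted")
    p <- as.numeric(predict_bundle(node$model, list(bag_raw)))
    trace[[length(trace) + 1L]] <<- list(node = node$name, branch_probs = p)
    b <- which.max(p)
    subset <- node$class_subsets[[b]]
    if (length(subset) == 1L) {
      list(leaf = subset, mass = mass * p[b])
    } else {
      descend_hard(node$children[[as.character(b)]], mass * p[b])
    }
  }
  if (mode == "soft") {
    probs <- descend_soft(tree, 1)
    probs <- probs / sum(probs)
    list(probs = probs, label = names(probs)[which.max(probs)],
         path_prob = NA_real_, trace = trace)
  } else {
    hit <- descend_hard(tree, 1)
    probs <- stats::setNames(numeric(length(leaves)), leaves)
    probs[hit$leaf] <- 1
    list(probs = probs, label = hit$leaf, path_prob = hit$mass,
         trace = trace)
  }
}

#' Predict a cohort of slides through the hierarchy
#'
#' @param tree fitted hierarchy.
#' @param bags_raw named list of raw patch matrices.
#' @param mode `"hard"` or `"soft"`.
#' @return matrix of five-class probabilities, one row per slide.
#' @export
predict_hierarchy <- function(tree, bags_raw, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  leaves <- hierarchy_leaves(tree)
  out <- t(vapply(bags_raw,
                  function(b) predict_slide(tree, b, mode)$probs,
                  stats::setNames(numeric(length(leaves)), leaves)))
  rownames(out) <- names(bags_raw)
  out
}

#' Pack / unpack a fitted hierarchy for serialization
#'
#' `hierarchy_pack()` replaces encoder environments with plain snapshot
#' lists so the tree round-trips through `saveRDS()`/`readRDS()` (or any
#' serializer) to identical predictions; `hierarchy_unpack()` is currently
#' the identity followed by validation, since bundles already store encoder
#' snapshots.
#'
#' @param tree fitted hierarchy.
#' @return a plain list safe to serialize / a `hierarchy_node`.
#' @export
hierarchy_pack <- function(tree) {
  tree$children <- lapply(tree$children, hierarchy_pack)
  tree
}

#' @rdname hierarchy_pack
#' @param packed result of `hierarchy_pack()`.
#' @export
hierarchy_unpack <- function(packed) {
  stopifnot(inherits(packed, "hierarchy_node"))
  packed
}
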
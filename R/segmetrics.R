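## Instance-segmentation evaluation metrics (Dice, AJI variants, panoptic
## quality, detection F1).  Instance maps are integer matrices with 0 =
## background and positive instance ids.

## pairwise intersection counts between truth and prediction instances
pair_intersections <- function(truth, pred) {
  t_ids <- sort(setdiff(unique(as.vector(truth)), 0L))
  p_ids <- sort(setdiff(unique(as.vector(pred)), 0L))
  inter <- matrix(0, length(t_ids), length(p_ids),
                  dimnames = list(t_ids, p_ids))
  both <- truth > 0 & pred > 0
  if (any(both)) {
    tab <- table(factor(truth[both], levels = t_ids),
                 factor(pred[both], levels = p_ids))
    inter[] <- as.numeric(tab)
  }
  t_area <- vapply(t_ids, function(i) sum(truth == i), numeric(1))
  p_area <- vapply(p_ids, function(i) sum(pred == i), numeric(1))
  list(inter = inter, t_area = t_area, p_area = p_area,
       t_ids = t_ids, p_ids = p_ids)
}

iou_matrix <- function(pp) {
  if (length(pp$t_ids) == 0L || length(pp$p_ids) == 0L) {
    return(matrix(0, length(pp$t_ids), length(pp$p_ids)))
  }
  uni <- outer(pp$t_area, pp$p_area, "+") - pp$inter
  ifelse(uni > 0, pp$inter / uni, 0)
}

## exact maximum-total-IoU one-to-one assignment by branch and bound over
## truth instances (feasible for the small instance counts of evaluation
## tiles); greedy fallback for large problems
optimal_assignment <- function(iou, max_exact = 10L) {
  nt <- nrow(iou); np <- ncol(iou)
  if (nt == 0L || np == 0L) return(integer(0))
  if (min(nt, np) <= max_exact && nt <= 12L) {
    best <- list(score = -1, assign = rep.int(0L, nt))
    assign <- rep.int(0L, nt)
    recurse <- function(i, used, score) {
      if (i > nt) {
        if (score > best$score) best <<- list(score = score, assign = assign)
        return(invisible())
      }
      ## upper bound: remaining rows take their row maximum
      ub <- score + sum(apply(iou[i:nt, , drop = FALSE], 1L, max))
      if (ub <= best$score) return(invisible())
      for (j in c(0L, seq_len(np))) {
        if (j > 0L && (used[j] || iou[i, j] <= 0)) next
        assign[i] <<- j
        if (j > 0L) used[j] <- TRUE
        recurse(i + 1L, used, score + if (j > 0L) iou[i, j] else 0)
        if (j > 0L) used[j] <- FALSE
      }
      assign[i] <<- 0L
    }
    recurse(1L, rep(FALSE, np), 0)
    return(best$assign)
  }
  ## greedy on globally sorted IoU
  assign <- rep.int(0L, nt)
  used <- rep(FALSE, np)
  ord <- order(iou, decreasing = TRUE)
  for (o in ord) {
    if (iou[o] <= 0) break
    i <- (o - 1L) %% nt + 1L
    j <- (o - 1L) %/% nt + 1L
    if (assign[i] == 0L && !used[j]) {
      assign[i] <- j
      used[j] <- TRUE
    }
  }
  assign
}

#' Instance segmentation evaluation metrics
#'
#' Computes, between a predicted and a ground-truth instance map:
#' * `dice` — pixel-level Dice on the binarized masks;
#' * `fast_aji` — aggregated Jaccard index with per-truth-instance greedy
#'   IoU-argmax matching (predictions may be claimed by several truth
#'   instances, the fast variant's known over-penalisation);
#' * `aji_plus` — AJI with a one-to-one maximum-total-IoU matching;
#' * `dq`, `sq`, `pq` — detection quality `TP / (TP + FP/2 + FN/2)` with
#'   matches at IoU > 0.5, segmentation quality (mean matched IoU), and
#'   panoptic quality `DQ * SQ`;
#' * when `truth_types`/`pred_types` are given, per-type and micro-average
#'   detection-classification F1 with centroid matching within 12 px.
#'
#' @param pred,truth integer instance maps of identical shape (0 =
#'   background).
#' @param pred_types,truth_types optional named character vectors mapping
#'   instance id to cell type.
#' @param match_radius centroid matching radius in pixels (default 12).
#' @return list of metrics (and a `per_type` data frame when types are
#'   supplied).
#' @export
seg_metrics <- function(pred, truth, pred_types = NULL, truth_types = NULL,
                        match_radius = 12) {
  if (!all(dim(pred) == dim(truth))) stop("pred/truth shape mismatch")
  pb <- pred > 0; tb <- truth > 0
  dice <- if (sum(pb) + sum(tb) == 0) 1 else {
    2 * sum(pb & tb) / (sum(pb) + sum(tb))
  }
  pp <- pair_intersections(truth, pred)
  iou <- iou_matrix(pp)
  nt <- length(pp$t_ids); np <- length(pp$p_ids)

  ## fast AJI: each truth instance claims its IoU-argmax prediction
  C_sum <- 0; U_sum <- 0
  claimed <- rep(FALSE, np)
  if (nt > 0L) {
    for (i in seq_len(nt)) {
      if (np > 0L && max(iou[i, ]) > 0) {
        j <- which.max(iou[i, ])
        claimed[j] <- TRUE
        C_sum <- C_sum + pp$inter[i, j]
        U_sum <- U_sum + pp$t_area[i] + pp$p_area[j] - pp$inter[i, j]
      } else {
        U_sum <- U_sum + pp$t_area[i]
      }
    }
  }
  if (np > 0L) U_sum <- U_sum + sum(pp$p_area[!claimed])
  fast_aji <- if (U_sum > 0) C_sum / U_sum else 1

  ## AJI+: optimal one-to-one matching
  assign <- optimal_assignment(iou)
  C2 <- 0; U2 <- 0
  used <- rep(FALSE, np)
  if (nt > 0L) {
    for (i in seq_len(nt)) {
      j <- assign[i]
      if (j > 0L) {
        used[j] <- TRUE
        C2 <- C2 + pp$inter[i, j]
        U2 <- U2 + pp$t_area[i] + pp$p_area[j] - pp$inter[i, j]
      } else {
        U2 <- U2 + pp$t_area[i]
      }
    }
  }
  if (np > 0L) U2 <- U2 + sum(pp$p_area[!used])
  aji_plus <- if (U2 > 0) C2 / U2 else 1

  ## panoptic quality at IoU > 0.5 (matches are unique by construction)
  tp_pairs <- which(iou > 0.5, arr.ind = TRUE)
  TP <- nrow(tp_pairs)
  FP <- np - TP; FN <- nt - TP
  dq <- if (TP + FP / 2 + FN / 2 > 0) TP / (TP + FP / 2 + FN / 2) else 1
  sq <- if (TP > 0) mean(iou[tp_pairs]) else 0
  if (TP == 0 && FP == 0 && FN == 0) sq <- 1
  out <- list(dice = dice, fast_aji = fast_aji, aji_plus = aji_plus,
              dq = dq, sq = sq, pq = dq * sq)

  if (!is.null(pred_types) && !is.null(truth_types)) {
    out <- c(out, detection_f1(pred, truth, pred_types, truth_types,
                               match_radius))
  }
  out
}

instance_centroids <- function(map) {
  ids <- sort(setdiff(unique(as.vector(map)), 0L))
  t(vapply(ids, function(i) {
    w <- which(map == i, arr.ind = TRUE)
    c(x = mean(w[, 2]), y = mean(w[, 1]))
  }, c(x = 0, y = 0))) -> xy
  rownames(xy) <- ids
  xy
}

## centroid-matched per-type and micro-average detection F1
detection_f1 <- function(pred, truth, pred_types, truth_types,
                         match_radius = 12) {
  tc <- instance_centroids(truth)
  pc <- instance_centroids(pred)
  nt <- nrow(tc); np <- nrow(pc)
  pairs <- NULL
  if (nt > 0 && np > 0) {
    d <- outer(seq_len(nt), seq_len(np), function(i, j) {
      sqrt((tc[i, 1] - pc[j, 1])^2 + (tc[i, 2] - pc[j, 2])^2)
    })
    ## greedy nearest-centroid pairing within the radius
    t_used <- rep(FALSE, nt); p_used <- rep(FALSE, np)
    ord <- order(d)
    for (o in ord) {
      if (d[o] > match_radius) break
      i <- (o - 1L) %% nt + 1L
      j <- (o - 1L) %/% nt + 1L
      if (!t_used[i] && !p_used[j]) {
        t_used[i] <- p_used[j] <- TRUE
        pairs <- rbind(pairs, c(i, j))
      }
    }
  }
  types <- sort(unique(c(truth_types, pred_types)))
  tp <- fp <- fn <- stats::setNames(numeric(length(types)), types)
  t_type <- truth_types[rownames(tc)]
  p_type <- pred_types[rownames(pc)]
  matched_t <- if (is.null(pairs)) integer(0) else pairs[, 1]
  matched_p <- if (is.null(pairs)) integer(0) else pairs[, 2]
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ti <- t_type[pairs[r, 1]]; pj <- p_type[pairs[r, 2]]
      if (identical(ti, pj)) {
        tp[ti] <- tp[ti] + 1
      } else {
        fn[ti] <- fn[ti] + 1
        fp[pj] <- fp[pj] + 1
      }
    }
  }
  for (i in setdiff(seq_len(nt), matched_t)) fn[t_type[i]] <- fn[t_type[i]] + 1
  for (j in setdiff(seq_len(np), matched_p)) fp[p_type[j]] <- fp[p_type[j]] + 1
  f1 <- function(tp, fp, fn) {
    if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  }
  per_type <- data.frame(type = types,
                         f1 = mapply(f1, tp, fp, fn),
                         tp = tp, fp = fp, fn = fn)
  list(per_type = per_type,
       micro_f1 = f1(sum(tp), sum(fp), sum(fn)))
}
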
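## Evaluation metrics: confusion-table semantic scores, instance-level
## precision/recall at IoU > 0.5, the F-score at a distance threshold, and
## the correlation statistics of the phenotype comparison.

#' Per-class accuracy, IoU and mean IoU
#'
#' Builds a one-vs-rest confusion table for each class:
#' `ACC_i = (TP+TN)/(TP+FP+FN+TN)` and `IoU_i = TP/(TP+FP+FN)`; `mIoU` is
#' the mean IoU over classes. A class absent from both prediction and truth
#' has undefined IoU and is excluded from the mean with a warning. Points
#' with truth label -1 are ignored.
#'
#' @param pred_labels,true_labels integer vectors of 0-based class labels.
#' @param n_classes number of classes.
#' @return list with `acc`, `iou` (per class, NA where undefined), `miou`
#'   and the per-class confusion counts.
#' @export
semantic_scores <- function(pred_labels, true_labels, n_classes) {
  stopifnot(length(pred_labels) == length(true_labels))
  keep <- true_labels >= 0L
  p <- pred_labels[keep]
  y <- true_labels[keep]
  total <- length(y)
  acc <- iou <- rep(NA_real_, n_classes)
  conf <- matrix(0L, n_classes, 4L,
                 dimnames = list(NULL, c("TP", "FP", "FN", "TN")))
  for (i in seq_len(n_classes)) {
    cls <- i - 1L
    tp <- sum(p == cls & y == cls)
    fp <- sum(p == cls & y != cls)
    fn <- sum(p != cls & y == cls)
    tn <- total - tp - fp - fn
    conf[i, ] <- c(tp, fp, fn, tn)
    acc[i] <- (tp + tn) / total
    if (tp + fp + fn > 0) iou[i] <- tp / (tp + fp + fn)
  }
  if (anyNA(iou))
    warning("class absent from prediction and truth excluded from mIoU")
  list(acc = acc, iou = iou, miou = mean(iou, na.rm = TRUE), confusion = conf)
}

#' Instance-level mean precision and recall
#'
#' A predicted instance is a true positive if its point-set IoU with an
#' unmatched ground-truth instance of the same semantic class (stem or leaf)
#' exceeds 0.5; matching is greedy by descending IoU. `mPrec` averages
#' `TP / #predicted` over the two classes and `mRec` averages `TP / #GT`; a
#' class with no predicted instances contributes precision 0.
#'
#' @param pred_instances,gt_instances per-point instance ids (>= 0; -1
#'   ignored) on the same point set.
#' @param pred_sem,gt_sem per-point semantic labels (0 = stem, 1 = leaf)
#'   used to derive each instance's class by majority vote.
#' @return list with `mprec`, `mrec` and the per-class counts.
#' @export
instance_prec_rec <- function(pred_instances, gt_instances, pred_sem,
                              gt_sem) {
  n <- length(gt_instances)
  stopifnot(length(pred_instances) == n, length(pred_sem) == n,
            length(gt_sem) == n)
  inst_sets <- function(inst, sem) {
    ids <- sort(unique(inst[inst >= 0L]))
    lapply(ids, function(id) {
      rows <- which(inst == id)
      cls <- as.integer(names(which.max(table(sem[rows]))))
      list(rows = rows, class = cls)
    })
  }
  preds <- inst_sets(pred_instances, pred_sem)
  gts <- inst_sets(gt_instances, gt_sem)
  per_class <- lapply(0:1, function(cls) {
    pc <- Filter(function(x) x$class == cls, preds)
    gc_ <- Filter(function(x) x$class == cls, gts)
    if (!length(pc) || !length(gc_)) {
      return(list(tp = 0L, np = length(pc), ng = length(gc_)))
    }
    iou_m <- matrix(0, length(pc), length(gc_))
    for (i in seq_along(pc)) {
      for (j in seq_along(gc_)) {
        inter <- length(intersect(pc[[i]]$rows, gc_[[j]]$rows))
        uni <- length(union(pc[[i]]$rows, gc_[[j]]$rows))
        iou_m[i, j] <- inter / uni
      }
    }
    tp <- 0L
    used_p <- logical(length(pc)); used_g <- logical(length(gc_))
    ord <- order(-iou_m)
    for (o in ord) {
      i <- (o - 1L) %% nrow(iou_m) + 1L
      j <- (o - 1L) %/% nrow(iou_m) + 1L
      if (iou_m[i, j] <= 0.5) break
      if (used_p[i] || used_g[j]) next
      used_p[i] <- TRUE; used_g[j] <- TRUE
      tp <- tp + 1L
    }
    list(tp = tp, np = length(pc), ng = length(gc_))
  })
  prec <- vapply(per_class, function(x) if (x$np > 0) x$tp / x$np else 0, 0)
  rec <- vapply(per_class, function(x) if (x$ng > 0) x$tp / x$ng else 0, 0)
  list(mprec = mean(prec), mrec = mean(rec),
       per_class = per_class)
}

#' F-score at a distance threshold
#'
#' Precision is the fraction of predicted points within `tau` of a
#' ground-truth point; recall the fraction of ground-truth points within
#' `tau` of a prediction; F is their harmonic mean (0 when both vanish).
#' `tau = 0.01` corresponds to 1 percent of the normalized extent.
#'
#' @param S_pred,S_gt non-empty point sets (normalized frame).
#' @param tau distance threshold.
#' @return list with `fscore`, `precision`, `recall`.
#' @export
fscore_at <- function(S_pred, S_gt, tau = 0.01) {
  A <- .as_points(S_pred); B <- .as_points(S_gt)
  if (!nrow(A) || !nrow(B)) stop("F-score needs non-empty sets")
  P <- mean(cpp_nn_dist(A, B)$dist <= tau)
  R <- mean(cpp_nn_dist(B, A)$dist <= tau)
  f <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(fscore = f, precision = P, recall = R)
}

#' Coefficient of determination and (root) mean squared error
#'
#' `R^2 = 1 - sum (v - v')^2 / sum (v - vbar)^2` for manual measurements `v`
#' against predictions `v'`; both `MSE = sum (v - v')^2 / m` and its square
#' root are returned with explicit labels.
#'
#' @param v numeric vector of reference (manual) values, variance > 0.
#' @param v_pred numeric vector of predicted values, same length, `m >= 2`.
#' @return list with `r2`, `mse`, `rmse`, `m`.
#' @export
r2_mse <- function(v, v_pred) {
  stopifnot(length(v) == length(v_pred), length(v) >= 2L)
  ss_tot <- sum((v - mean(v))^2)
  if (ss_tot <= 0) stop("reference values have zero variance")
  ss_res <- sum((v - v_pred)^2)
  mse <- ss_res / length(v)
  list(r2 = 1 - ss_res / ss_tot, mse = mse, rmse = sqrt(mse),
       m = length(v))
}
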
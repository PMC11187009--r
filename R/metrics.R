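# ---------------------------------------------------------------------------
# Detection evaluation: greedy matching, precision/recall, per-class AP with
# the monotone precision envelope (all-point interpolation), mAP@0.5 and
# mAP@0.5:0.95.
# ---------------------------------------------------------------------------

#' Match detections to ground truth
#'
#' Greedy one-to-one matching within one image: detections are taken in
#' descending score order, and each matches the highest-IoU not-yet-matched
#' ground truth of the same class with IoU at or above the threshold;
#' everything else is a false positive, and unmatched ground truths count
#' as false negatives.
#'
#' @param dets Data frame with `x1, y1, x2, y2, class_id, score`.
#' @param gts Data frame with `x1, y1, x2, y2, class_id`.
#' @param iou_thr IoU threshold for a match.
#' @return `list(tp = logical per detection (score-descending order),
#'   order = the ordering used, fn = unmatched ground-truth count)`.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  ord <- order(dets$score, decreasing = TRUE)
  tp <- logical(nrow(dets))
  used <- rep(FALSE, nrow(gts))
  if (nrow(dets) > 0 && nrow(gts) > 0) {
    gb <- as_box_matrix(gts)
    db <- as_box_matrix(dets)
    for (k in seq_along(ord)) {
      i <- ord[k]
      cand <- which(!used & gts$class_id == dets$class_id[i])
      if (length(cand) == 0) next
      ious <- iou(matrix(db[i, ], length(cand), 4, byrow = TRUE),
                  gb[cand, , drop = FALSE])
      j <- which.max(ious)
      if (ious[j] >= iou_thr) {
        tp[k] <- TRUE
        used[cand[j]] <- TRUE
      }
    }
  }
  list(tp = tp, order = ord, fn = sum(!used))
}

#' Precision and recall from counts
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`, both defined
#' as 0 when their denominator is 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return `list(precision, recall)`.
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

#' Average precision from scored match flags
#'
#' Area under the precision-recall curve using the monotone precision
#' envelope over all recall points (all-point interpolation). Flags must be
#' globally sorted by descending score across images.
#'
#' @param tp Logical vector of per-detection true-positive flags, sorted by
#'   descending score.
#' @param n_gt Number of ground-truth instances of the class.
#' @return AP in `[0, 1]`; `NA` if `n_gt == 0`.
#' @export
average_precision <- function(tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  prec <- cum_tp / (cum_tp + cum_fp)
  rec <- cum_tp / n_gt
  # monotone envelope from the right
  env <- rev(cummax(rev(prec)))
  r_prev <- c(0, rec[-length(rec)])
  sum((rec - r_prev) * env)
}

#' Evaluate detections against ground truth
#'
#' Computes per-class AP at each IoU threshold, mAP@0.5 (and over the given
#' threshold set), plus aggregate precision/recall at the point of maximum
#' F1 on the 0.5-threshold PR sweep. Classes with no ground truth are
#' excluded from the mean.
#'
#' @param dets A list (per image) of detection data frames
#'   (`x1, y1, x2, y2, class_id, score`).
#' @param gts A list (per image) of ground-truth data frames
#'   (`x1, y1, x2, y2, class_id`).
#' @param thresholds IoU thresholds; default `seq(0.5, 0.95, by = 0.05)`.
#' @param num_classes Number of classes (class ids `0..num_classes-1`).
#' @return An object of class `cdd_eval`: per-class tibble, aggregates,
#'   counts at IoU 0.5.
#' @export
map_at <- function(dets, gts, thresholds = seq(0.5, 0.95, by = 0.05),
                   num_classes = 3L) {
  stopifnot(length(thresholds) > 0, length(dets) == length(gts))
  thresholds <- round(thresholds, 6)  # guard seq() floating-point dust
  ap <- matrix(NA_real_, num_classes, length(thresholds))
  counts <- list(tp = 0, fp = 0, fn = 0)
  agg_pr <- list(precision = 0, recall = 0)
  for (ci in seq_len(num_classes) - 1L) {
    n_gt <- sum(vapply(gts, function(g) sum(g$class_id == ci), 0))
    for (ti in seq_along(thresholds)) {
      scores <- numeric(); flags <- logical()
      for (k in seq_along(dets)) {
        d <- dets[[k]]
        d <- d[d$class_id == ci, , drop = FALSE]
        g <- gts[[k]]
        g <- g[g$class_id == ci, , drop = FALSE]
        m <- match_detections(d, g, thresholds[ti])
        scores <- c(scores, d$score[m$order])
        flags <- c(flags, m$tp)
      }
      ord <- order(scores, decreasing = TRUE)
      ap[ci + 1L, ti] <- average_precision(flags[ord], n_gt)
      if (abs(thresholds[ti] - 0.5) < 1e-12) {
        tp <- sum(flags)
        counts$tp <- counts$tp + tp
        counts$fp <- counts$fp + sum(!flags)
        counts$fn <- counts$fn + (n_gt - tp)
      }
    }
  }
  # aggregate P/R at max-F1 over the pooled 0.5-threshold sweep
  t05 <- which.min(abs(thresholds - 0.5))
  scores <- numeric(); flags <- logical(); tot_gt <- 0
  for (ci in seq_len(num_classes) - 1L) {
    for (k in seq_along(dets)) {
      d <- dets[[k]][dets[[k]]$class_id == ci, , drop = FALSE]
      g <- gts[[k]][gts[[k]]$class_id == ci, , drop = FALSE]
      m <- match_detections(d, g, thresholds[t05])
      scores <- c(scores, d$score[m$order])
      flags <- c(flags, m$tp)
      tot_gt <- tot_gt + nrow(g)
    }
  }
  if (length(flags) > 0 && tot_gt > 0) {
    ord <- order(scores, decreasing = TRUE)
    f <- flags[ord]
    prec <- cumsum(f) / seq_along(f)
    rec <- cumsum(f) / tot_gt
    f1 <- 2 * prec * rec / pmax(prec + rec, EPS)
    best <- which.max(f1)
    agg_pr <- list(precision = prec[best], recall = rec[best])
  }
  valid <- !is.na(ap[, 1])
  per_class <- tibble::tibble(
    class_id = seq_len(num_classes) - 1L,
    n_gt = vapply(seq_len(num_classes) - 1L,
                  function(ci) sum(vapply(gts, function(g)
                    sum(g$class_id == ci), 0)), 0),
    ap50 = ap[, which.min(abs(thresholds - 0.5))],
    ap = rowMeans(ap)
  )
  structure(list(
    per_class = per_class,
    thresholds = thresholds,
    map50 = mean(ap[valid, which.min(abs(thresholds - 0.5))]),
    map = mean(rowMeans(ap[valid, , drop = FALSE])),
    precision = agg_pr$precision, recall = agg_pr$recall,
    tp = counts$tp, fp = counts$fp, fn = counts$fn
  ), class = "cdd_eval")
}

#' @export
print.cdd_eval <- function(x, ...) {
  cat(sprintf("<cdd_eval>  mAP@0.5 = %.4f   mAP@%.2f:%.2f = %.4f\n",
              x$map50, min(x$thresholds), max(x$thresholds), x$map))
  cat(sprintf("  precision = %.4f  recall = %.4f  (TP %d / FP %d / FN %d)\n",
              x$precision, x$recall, x$tp, x$fp, x$fn))
  print(x$per_class)
  invisible(x)
}
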
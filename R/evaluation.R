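# ---------------------------------------------------------------------------
# Instance-segmentation metrics: mask IoU, greedy score-ordered matching,
# 101-point interpolated average precision at one IoU threshold, and the
# headline AP averaged over thresholds 0.5:0.05:0.95 (COCO protocol,
# single category).
# ---------------------------------------------------------------------------

#' Mask intersection-over-union
#'
#' @param a,b binary masks of identical shape
#' @return IoU in `[0, 1]`; 0 when both masks are empty (by convention)
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  ai <- a > 0; bi <- b > 0
  un <- sum(ai | bi)
  if (un == 0) return(0)
  sum(ai & bi) / un
}

#' Match detections to ground truth on one image
#'
#' Detections are taken in descending score order; each is matched to the
#' not-yet-matched ground-truth mask of highest IoU provided that IoU
#' reaches `iou_thr`. Each ground truth matches at most once; unmatched
#' detections are false positives, unmatched ground truths false negatives.
#'
#' @param det_masks list of detection masks (score-sorted or not; sorted
#'   internally by `scores`)
#' @param scores detection scores
#' @param gt_masks list of ground-truth masks
#' @param iou_thr matching IoU threshold
#' @return list: `tp` logical per detection (in score order), `order` the
#'   score ordering used, `matched_gt` gt index per detection (NA if FP),
#'   `fn` count of unmatched ground truths
#' @export
match_predictions <- function(det_masks, scores, gt_masks, iou_thr = 0.5) {
  ord <- order(scores, decreasing = TRUE)
  n <- length(det_masks); m <- length(gt_masks)
  tp <- logical(n); matched_gt <- rep(NA_integer_, n)
  gt_used <- logical(m)
  for (ii in seq_len(n)) {
    d <- det_masks[[ord[ii]]]
    best <- 0; best_j <- 0L
    for (j in seq_len(m)) {
      if (gt_used[j]) next
      iou <- mask_iou(d, gt_masks[[j]])
      if (iou > best) { best <- iou; best_j <- j }
    }
    if (best_j > 0L && best >= iou_thr) {
      tp[ii] <- TRUE; matched_gt[ii] <- best_j; gt_used[best_j] <- TRUE
    }
  }
  list(tp = tp, order = ord, matched_gt = matched_gt, fn = sum(!gt_used))
}

#' Average precision at one IoU threshold (101-point interpolation)
#'
#' Pools detections over all images, sorts by score, matches per image, and
#' integrates the precision-recall curve at 101 equally spaced recall
#' points with the usual right-to-left precision envelope.
#'
#' @param preds per-image list: `list(masks = <list>, scores = <numeric>)`
#' @param gts per-image list of ground-truth mask lists
#' @param iou_thr IoU threshold
#' @return AP in `[0, 1]`; `NaN` with a warning when there are no ground
#'   truths and no detections
#' @export
average_precision <- function(preds, gts, iou_thr = 0.5) {
  stopifnot(length(preds) == length(gts))
  n_gt <- sum(vapply(gts, length, numeric(1)))
  all_scores <- numeric(0); all_tp <- logical(0)
  for (i in seq_along(preds)) {
    p <- preds[[i]]
    if (!length(p$masks)) next
    mm <- match_predictions(p$masks, p$scores, gts[[i]], iou_thr)
    all_scores <- c(all_scores, p$scores[mm$order])
    all_tp <- c(all_tp, mm$tp)
  }
  if (n_gt == 0 && !length(all_scores)) {
    warning("no ground truths and no detections; AP undefined")
    return(NaN)
  }
  if (n_gt == 0) return(0)
  if (!length(all_scores)) return(0)
  ord <- order(all_scores, decreasing = TRUE)
  tp <- cumsum(all_tp[ord])
  fp <- cumsum(!all_tp[ord])
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # precision envelope, then sample at 101 recall points
  for (i in rev(seq_along(precision))[-1])
    precision[i] <- max(precision[i], precision[i + 1])
  rc <- seq(0, 1, by = 0.01)
  ap <- mean(vapply(rc, function(r) {
    j <- which(recall >= r - 1e-12)
    if (!length(j)) 0 else precision[j[1]]
  }, numeric(1)))
  ap
}

#' Evaluate instance segmentation over a test set
#'
#' @param preds per-image list: `list(masks, scores)`
#' @param gts per-image list of ground-truth mask lists
#' @param iou_thrs thresholds for the headline AP (default 0.5 to 0.95,
#'   step 0.05)
#' @return `wbc_eval` list: `AP`, `AP50`, `AP75` (percent), `precision` and
#'   `recall` at IoU 0.5 (all pooled detections), `per_threshold` AP table,
#'   and the pooled PR curve at IoU 0.5
#' @export
evaluate_detections <- function(preds, gts,
                                iou_thrs = seq(0.5, 0.95, by = 0.05)) {
  aps <- vapply(iou_thrs, function(t) average_precision(preds, gts, t),
                numeric(1))
  # pooled precision/recall and PR curve at 0.5
  n_gt <- sum(vapply(gts, length, numeric(1)))
  all_scores <- numeric(0); all_tp <- logical(0)
  for (i in seq_along(preds)) {
    p <- preds[[i]]
    if (!length(p$masks)) next
    mm <- match_predictions(p$masks, p$scores, gts[[i]], 0.5)
    all_scores <- c(all_scores, p$scores[mm$order])
    all_tp <- c(all_tp, mm$tp)
  }
  if (length(all_scores)) {
    ord <- order(all_scores, decreasing = TRUE)
    tp <- cumsum(all_tp[ord]); fp <- cumsum(!all_tp[ord])
    pr <- data.frame(score = all_scores[ord], recall = tp / max(1, n_gt),
                     precision = tp / (tp + fp))
    precision <- pr$precision[nrow(pr)]
    recall <- pr$recall[nrow(pr)]
  } else {
    pr <- data.frame(score = numeric(0), recall = numeric(0),
                     precision = numeric(0))
    precision <- NA_real_; recall <- if (n_gt > 0) 0 else NA_real_
  }
  structure(list(
    AP = 100 * mean(aps), AP50 = 100 * aps[1],
    AP75 = 100 * aps[which.min(abs(iou_thrs - 0.75))],
    precision = precision, recall = recall,
    per_threshold = data.frame(iou_thr = iou_thrs, AP = 100 * aps),
    pr_curve = pr, n_gt = n_gt), class = "wbc_eval")
}

#' @export
print.wbc_eval <- function(x, ...) {
  cat(sprintf("AP %.2f | AP50 %.2f | AP75 %.2f  (%d ground truths)\n",
              x$AP, x$AP50, x$AP75, x$n_gt))
  invisible(x)
}

#' Evaluate a results file against a ground-truth COCO JSON
#'
#' @param gt_path ground-truth COCO instance JSON
#' @param pred_path results JSON: array of
#'   `{image_id, category_id, segmentation (RLE), score}`
#' @param iou_thrs AP thresholds
#' @return `wbc_eval` object
#' @export
evaluate_coco_files <- function(gt_path, pred_path,
                                iou_thrs = seq(0.5, 0.95, by = 0.05)) {
  gt <- read_coco(gt_path)
  pred <- jsonlite::read_json(pred_path, simplifyVector = FALSE)
  img_ids <- vapply(gt$images, function(im) im$id, numeric(1))
  gts <- lapply(img_ids, function(id) {
    lapply(Filter(function(a) a$image_id == id, gt$annotations),
           function(a) rle_decode(a$segmentation))
  })
  preds <- lapply(img_ids, function(id) {
    ps <- Filter(function(p) p$image_id == id, pred)
    list(masks = lapply(ps, function(p) {
      p$segmentation$counts <- as.integer(unlist(p$segmentation$counts))
      p$segmentation$size <- as.integer(unlist(p$segmentation$size))
      rle_decode(p$segmentation)
    }),
    scores = vapply(ps, function(p) p$score, numeric(1)))
  })
  evaluate_detections(preds, gts, iou_thrs)
}

#' Write detection results as COCO-style results JSON
#'
#' @param dets per-image list of `predict_image()` outputs
#' @param image_ids matching image ids
#' @param path output path
#' @export
write_results_json <- function(dets, image_ids, path) {
  out <- list()
  for (i in seq_along(dets)) {
    d <- dets[[i]]
    for (j in seq_along(d$masks)) {
      out[[length(out) + 1L]] <- list(
        image_id = image_ids[i], category_id = 1L,
        segmentation = rle_encode(d$masks[[j]]),
        bbox = {
          b <- d$boxes[j, ]
          c(b[1], b[2], b[3] - b[1], b[4] - b[2])
        },
        score = d$scores[j])
    }
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
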
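# Independent oracles and small fixtures used across the suite. Each oracle
# is a deliberately plain-loop implementation, separate from the package's
# vectorized code paths.

# central finite differences of a scalar function
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# brute-force unnormalized 2D DCT-II coefficient of one channel by double sum
brute_dct <- function(channel, h, w) {
  H <- nrow(channel); W <- ncol(channel)
  acc <- 0
  for (i in 0:(H - 1)) for (j in 0:(W - 1))
    acc <- acc + channel[i + 1, j + 1] *
      cos(pi * h / H * (i + 0.5)) * cos(pi * w / W * (j + 0.5))
  acc
}

# O(n^2) greedy NMS oracle
brute_nms <- function(boxes, scores, iou_thr, score_thr, top_k = Inf) {
  one_iou <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
    if (ua <= 0) 0 else inter / ua
  }
  alive <- which(scores >= score_thr)
  alive <- alive[order(scores[alive], decreasing = TRUE)]
  keep <- integer(0)
  while (length(alive) && length(keep) < top_k) {
    i <- alive[1]
    keep <- c(keep, i)
    alive <- alive[-1]
    drop <- logical(length(alive))
    for (jj in seq_along(alive))
      if (one_iou(boxes[i, ], boxes[alive[jj], ]) >= iou_thr) drop[jj] <- TRUE
    alive <- alive[!drop]
  }
  keep
}

# exhaustive anchor-matching oracle over the full IoU matrix
brute_match <- function(gt_boxes, anchors_cxcywh, pos_thr, neg_thr) {
  n <- nrow(anchors_cxcywh)
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0) return(integer(n))
  a <- cbind(anchors_cxcywh[, 1] - anchors_cxcywh[, 3] / 2,
             anchors_cxcywh[, 2] - anchors_cxcywh[, 4] / 2,
             anchors_cxcywh[, 1] + anchors_cxcywh[, 3] / 2,
             anchors_cxcywh[, 2] + anchors_cxcywh[, 4] / 2)
  iou <- matrix(0, n, nrow(gt_boxes))
  for (i in seq_len(n)) for (j in seq_len(nrow(gt_boxes))) {
    ix <- max(0, min(a[i, 3], gt_boxes[j, 3]) - max(a[i, 1], gt_boxes[j, 1]))
    iy <- max(0, min(a[i, 4], gt_boxes[j, 4]) - max(a[i, 2], gt_boxes[j, 2]))
    inter <- ix * iy
    un <- (a[i, 3] - a[i, 1]) * (a[i, 4] - a[i, 2]) +
      (gt_boxes[j, 3] - gt_boxes[j, 1]) * (gt_boxes[j, 4] - gt_boxes[j, 2]) - inter
    iou[i, j] <- if (un > 0) inter / un else 0
  }
  lab <- integer(n)
  for (i in seq_len(n)) {
    best <- which.max(iou[i, ])
    if (iou[i, best] >= pos_thr) lab[i] <- best
    else if (iou[i, best] >= neg_thr) lab[i] <- -1L
  }
  for (j in seq_len(ncol(iou))) lab[which.max(iou[, j])] <- j
  lab
}

# Reference single-category mask-AP evaluator following the COCO protocol:
# per-image greedy matching of score-sorted detections to the best-IoU
# unmatched ground truth, pooled PR curve, precision envelope, 101-point
# interpolation. Straight loops throughout.
ref_coco_ap <- function(preds, gts, iou_thr) {
  mask_iou_ref <- function(a, b) {
    inter <- 0; uni <- 0
    av <- a > 0; bv <- b > 0
    inter <- sum(av & bv); uni <- sum(av | bv)
    if (uni == 0) 0 else inter / uni
  }
  n_gt <- 0
  for (g in gts) n_gt <- n_gt + length(g)
  scores <- c(); is_tp <- c()
  for (i in seq_along(preds)) {
    p <- preds[[i]]
    if (length(p$masks) == 0) next
    ord <- order(p$scores, decreasing = TRUE)
    used <- rep(FALSE, length(gts[[i]]))
    for (d in ord) {
      best_iou <- 0; best_j <- 0
      for (j in seq_along(gts[[i]])) {
        if (used[j]) next
        v <- mask_iou_ref(p$masks[[d]], gts[[i]][[j]])
        if (v > best_iou) { best_iou <- v; best_j <- j }
      }
      hit <- best_j > 0 && best_iou >= iou_thr
      if (hit) used[best_j] <- TRUE
      scores <- c(scores, p$scores[d])
      is_tp <- c(is_tp, hit)
    }
  }
  if (n_gt == 0) return(NaN)
  if (length(scores) == 0) return(0)
  ord <- order(scores, decreasing = TRUE)
  is_tp <- is_tp[ord]
  tp <- 0; fp <- 0
  prec <- numeric(length(is_tp)); rec <- numeric(length(is_tp))
  for (i in seq_along(is_tp)) {
    if (is_tp[i]) tp <- tp + 1 else fp <- fp + 1
    prec[i] <- tp / (tp + fp)
    rec[i] <- tp / n_gt
  }
  for (i in rev(seq_along(prec))[-1]) prec[i] <- max(prec[i], prec[i + 1])
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    pbest <- 0
    for (i in seq_along(rec)) if (rec[i] >= r - 1e-12) { pbest <- prec[i]; break }
    total <- total + pbest
  }
  total / 101
}

# tiny detector used by several tests (fast to build and run)
tiny_config <- function(...) {
  cfg <- default_config("desk")
  merge_config(cfg, list(...))
}

# random binary blob mask fixture
random_mask <- function(hw, n_px, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0L, hw[1], hw[2])
  m[sample(length(m), n_px)] <- 1L
  m
}

# set every parameter of a module to zero
zero_all_params <- function(model) {
  ps <- wbcseg:::collect_params(wbcseg:::model_layers(model))
  for (p in ps) p$value[] <- 0
  invisible(model)
}
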
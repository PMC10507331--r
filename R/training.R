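# ---------------------------------------------------------------------------
# Anchor matching, multi-task loss (softmax CE with 3:1 hard-negative
# mining, smooth-L1 box regression on encoded offsets, per-instance BCE on
# assembled masks cropped to the ground-truth box), SGD with momentum, and
# conventional augmentation.
# ---------------------------------------------------------------------------

#' Match anchors to ground-truth boxes
#'
#' An anchor is positive when its best IoU reaches `pos_thr` or when it is
#' the argmax anchor of a ground truth; negative below `neg_thr`; ignored in
#' between.
#'
#' @param gt_boxes `m x 4` normalized `(x1, y1, x2, y2)` boxes (0 rows ok)
#' @param anchors anchor matrix from [gen_anchors()] (`cx, cy, w, h`)
#' @param pos_thr,neg_thr matching thresholds
#' @return integer vector per anchor: `j > 0` = matched gt index, `0` =
#'   negative, `-1` = ignored
#' @export
match_anchors <- function(gt_boxes, anchors, pos_thr = 0.5, neg_thr = 0.4) {
  n <- nrow(anchors)
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0L) return(integer(n))
  a_xyxy <- cbind(anchors[, 1] - anchors[, 3] / 2,
                  anchors[, 2] - anchors[, 4] / 2,
                  anchors[, 1] + anchors[, 3] / 2,
                  anchors[, 2] + anchors[, 4] / 2)
  iou <- box_iou(a_xyxy, gt_boxes)            # n x m
  best_gt <- max.col(iou, ties.method = "first")
  best_iou <- iou[cbind(seq_len(n), best_gt)]
  lab <- integer(n)
  lab[best_iou < neg_thr] <- 0L
  lab[best_iou >= neg_thr & best_iou < pos_thr] <- -1L
  lab[best_iou >= pos_thr] <- best_gt[best_iou >= pos_thr]
  # force each gt's argmax anchor positive
  for (j in seq_len(ncol(iou))) {
    i <- which.max(iou[, j])
    lab[i] <- j
  }
  lab
}

# terminal loss nodes (analytic gradients) ----------------------------------

# softmax cross-entropy over selected rows; labels 0-based class ids;
# normalized by `norm`
softmax_ce_node <- function(logits, rows, labels, norm) {
  sel <- logits$value[rows, , drop = FALSE]
  mx <- apply(sel, 1, max)
  lse <- mx + log(rowSums(exp(sel - mx)))
  picked <- sel[cbind(seq_along(rows), labels + 1L)]
  val <- sum(lse - picked) / norm
  new_node(val, list(logits), function(g) {
    p <- exp(sel - lse)  # softmax rows
    p[cbind(seq_along(rows), labels + 1L)] <-
      p[cbind(seq_along(rows), labels + 1L)] - 1
    gl <- matrix(0, nrow(logits$value), ncol(logits$value))
    gl[rows, ] <- g * p / norm
    list(gl)
  })
}

# smooth L1 (Huber, delta = 1) between selected rows and a constant target
smooth_l1_node <- function(pred, rows, target, norm) {
  d <- pred$value[rows, , drop = FALSE] - target
  a <- abs(d)
  val <- sum(ifelse(a < 1, 0.5 * d^2, a - 0.5)) / norm
  new_node(val, list(pred), function(g) {
    gd <- ifelse(a < 1, d, sign(d))
    gp <- matrix(0, nrow(pred$value), ncol(pred$value))
    gp[rows, ] <- g * gd / norm
    list(gp)
  })
}

# binary cross-entropy with logits, element weights w, normalizer per column
bce_logits_node <- function(logits, target, w, norm) {
  x <- logits$value
  p <- 1 / (1 + exp(-x))
  eps <- 1e-7
  val <- -sum(w * (target * log(p + eps) + (1 - target) * log(1 - p + eps))) / norm
  new_node(val, list(logits), function(g)
    list(g * w * (p - target) / norm))
}

#' Compute the multi-task detection loss for one image
#'
#' @param out forward outputs from [detector_forward()] (training mode)
#' @param model the detector (for anchors and config)
#' @param gt list with `boxes` (`m x 4` normalized xyxy) and `masks`
#'   (list of full-resolution 0/1 matrices)
#' @param max_masks cap on the number of positives used for the mask loss
#' @return list: `total` (node) and numeric `cls`, `box`, `mask`, plus the
#'   positive count
#' @export
compute_losses <- function(out, model, gt, max_masks = 32L) {
  cfg <- model$config$train
  anchors <- model$anchors
  lw <- cfg$loss_weights
  lab <- match_anchors(gt$boxes, anchors, cfg$pos_thr, cfg$neg_thr)
  pos <- which(lab > 0L)
  n_pos <- length(pos)
  norm <- max(1L, n_pos)

  # classification: positives + 3:1 hardest negatives (highest foreground
  # evidence = largest logit-gap loss among negatives)
  neg_pool <- which(lab == 0L)
  cls_logits <- out$cls$value
  mx <- apply(cls_logits, 1, max)
  neg_loss <- mx + log(rowSums(exp(cls_logits - mx))) - cls_logits[, 1]
  n_neg <- min(length(neg_pool), max(cfg$ohem_ratio * n_pos, 8L))
  hard_neg <- neg_pool[order(neg_loss[neg_pool], decreasing = TRUE)[seq_len(n_neg)]]
  rows <- c(pos, hard_neg)
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))  # single foreground class
  cls_node <- softmax_ce_node(out$cls, rows, labels, norm)

  if (n_pos > 0L) {
    targets <- encode_boxes(gt$boxes[lab[pos], , drop = FALSE],
                            anchors[pos, , drop = FALSE])
    box_node <- smooth_l1_node(out$box, pos, targets, norm)

    # mask loss on assembled prototypes, cropped to the gt box
    pv <- out$protos$value
    pd <- dim(pv)
    mask_pos <- if (n_pos > max_masks) sort(sample(pos, max_masks)) else pos
    proto_flat <- tn_flatten_hw(out$protos)          # (P*P) x k
    coef_rows <- new_node(t(out$coef$value[mask_pos, , drop = FALSE]),
                          list(out$coef), function(g) {
                            gc <- matrix(0, nrow(out$coef$value), ncol(out$coef$value))
                            gc[mask_pos, ] <- t(g)
                            list(gc)
                          })
    logits <- tn_matmul(proto_flat, coef_rows)       # (P*P) x npos
    tgt <- matrix(0, pd[1] * pd[2], length(mask_pos))
    wgt <- matrix(0, pd[1] * pd[2], length(mask_pos))
    for (ii in seq_along(mask_pos)) {
      j <- lab[mask_pos[ii]]
      gm <- resize_mask(gt$masks[[j]], pd[1:2])
      tgt[, ii] <- as.vector(gm)
      b <- gt$boxes[j, ]
      x1 <- max(1L, floor(b[1] * pd[2]) + 1L); x2 <- min(pd[2], ceiling(b[3] * pd[2]))
      y1 <- max(1L, floor(b[2] * pd[1]) + 1L); y2 <- min(pd[1], ceiling(b[4] * pd[1]))
      wm <- matrix(0, pd[1], pd[2])
      if (x2 >= x1 && y2 >= y1) {
        area <- (x2 - x1 + 1) * (y2 - y1 + 1)
        wm[y1:y2, x1:x2] <- 1 / area
      }
      wgt[, ii] <- as.vector(wm)
    }
    mask_node <- bce_logits_node(logits, tgt, wgt, length(mask_pos))
  } else {
    box_node <- tn_const(0)
    mask_node <- tn_const(0)
  }

  total <- tn_add(tn_scale(cls_node, lw[["cls"]]),
                  tn_add(tn_scale(box_node, lw[["box"]]),
                         tn_scale(mask_node, lw[["mask"]])))
  if (!is.finite(total$value))
    stop(sprintf("non-finite loss (cls %.4g box %.4g mask %.4g)",
                 cls_node$value, box_node$value, mask_node$value))
  list(total = total, cls = cls_node$value, box = box_node$value,
       mask = mask_node$value, n_pos = n_pos)
}

# --- optimizer -------------------------------------------------------------

sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 0,
                     clip_norm = 0) {
  if (clip_norm > 0) {
    sq <- 0
    for (p in params) if (!is.null(p$grad)) sq <- sq + sum(p$grad^2)
    gn <- sqrt(sq)
    if (is.finite(gn) && gn > clip_norm) {
      sc <- clip_norm / gn
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
    }
  }
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (weight_decay > 0) g <- g + weight_decay * p$value
    v <- if (is.null(p$mom)) g else momentum * p$mom + g
    p$mom <- v
    p$value <- p$value - lr * v
  }
  invisible(NULL)
}

# --- augmentation ----------------------------------------------------------

#' Conventional augmentation of an image/annotation pair
#'
#' Horizontal/vertical flips, photometric jitter and a random scale-crop,
#' applied consistently to masks and boxes. An instance whose mask becomes
#' empty (or falls below `keep_frac` of its area after cropping) is dropped.
#'
#' @param image `H x W x 3` array
#' @param annotations instance list (as from [generate_smear()])
#' @param flags list: `hflip`, `vflip`, `photometric`, `crop` (each a
#'   probability or logical), `crop_range` scale range
#' @param keep_frac minimum surviving area fraction under cropping
#' @return list `image`, `annotations`
#' @export
augment <- function(image, annotations,
                    flags = list(hflip = 0.5, vflip = 0.5, photometric = 0.5,
                                 crop = 0.3, crop_range = c(0.7, 0.95)),
                    keep_frac = 0.25) {
  do_p <- function(f) isTRUE(f) || (is.numeric(f) && stats::runif(1) < f)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (do_p(flags$hflip)) {
    image <- image[, W:1, , drop = FALSE]
    annotations <- lapply(annotations, function(a) {
      a$mask <- a$mask[, W:1, drop = FALSE]
      a$bbox <- mask_to_bbox(a$mask); a
    })
  }
  if (do_p(flags$vflip)) {
    image <- image[H:1, , , drop = FALSE]
    annotations <- lapply(annotations, function(a) {
      a$mask <- a$mask[H:1, , drop = FALSE]
      a$bbox <- mask_to_bbox(a$mask); a
    })
  }
  if (do_p(flags$photometric)) {
    gain <- stats::runif(3, 0.9, 1.1)
    bias <- stats::runif(1, -0.05, 0.05)
    for (ch in 1:3) image[, , ch] <- image[, , ch] * gain[ch] + bias
    image[image < 0] <- 0
    image[image > 1] <- 1
  }
  if (do_p(flags$crop)) {
    rng <- if (is.null(flags$crop_range)) c(0.7, 0.95) else flags$crop_range
    s <- stats::runif(1, rng[1], rng[2])
    ch_ <- max(16L, floor(H * s)); cw <- max(16L, floor(W * s))
    y0 <- sample.int(H - ch_ + 1L, 1L); x0 <- sample.int(W - cw + 1L, 1L)
    sub <- image[y0:(y0 + ch_ - 1L), x0:(x0 + cw - 1L), , drop = FALSE]
    image <- resize_image(sub, c(H, W))
    annotations <- Filter(Negate(is.null), lapply(annotations, function(a) {
      m <- a$mask[y0:(y0 + ch_ - 1L), x0:(x0 + cw - 1L), drop = FALSE]
      if (sum(m) < keep_frac * a$area || sum(m) == 0) return(NULL)
      m <- resize_mask(m, c(H, W))
      if (sum(m) == 0) return(NULL)
      list(mask = m, bbox = mask_to_bbox(m), area = sum(m),
           category = a$category)
    }))
  }
  list(image = image, annotations = annotations)
}

# annotations -> training targets at model resolution
anns_to_targets <- function(annotations, in_hw, out_size) {
  m <- length(annotations)
  if (!m) return(list(boxes = matrix(0, 0, 4), masks = list()))
  boxes <- matrix(0, m, 4)
  masks <- vector("list", m)
  for (i in seq_len(m)) {
    a <- annotations[[i]]
    mk <- a$mask
    if (!identical(dim(mk), c(out_size, out_size)))
      mk <- resize_mask(mk, c(out_size, out_size))
    masks[[i]] <- mk
    b <- a$bbox  # 0-based x,y,w,h in source pixels
    boxes[i, ] <- c(b[1] / in_hw[2], b[2] / in_hw[1],
                    (b[1] + b[3]) / in_hw[2], (b[2] + b[4]) / in_hw[1])
  }
  list(boxes = boxes, masks = masks)
}

#' Train the detector
#'
#' SGD with momentum on the multi-task loss, gradient accumulation over the
#' batch. The loss trajectory is reproducible on CPU under the configured
#' seed. Aborts if the loss diverges to a non-finite value.
#'
#' @param model detector from [build_detector()]
#' @param smears training set: list of `list(image, annotations)` (images
#'   are resized to the model input size)
#' @param epochs,lr,batch_size optional overrides of `model$config$train`
#' @param log_every print a progress line every this many iterations
#'   (0 = silent)
#' @param checkpoint_path optional path; a checkpoint is written after every
#'   epoch
#' @param log_path optional JSON-lines metric log
#' @return data.frame history with per-iteration loss breakdown
#' @export
train_detector <- function(model, smears, epochs = NULL, lr = NULL,
                           batch_size = NULL, log_every = 0L,
                           checkpoint_path = NULL, log_path = NULL) {
  tc <- model$config$train
  if (is.null(epochs)) epochs <- tc$epochs
  if (is.null(lr)) lr <- tc$learning_rate
  if (is.null(batch_size)) batch_size <- tc$batch_size
  set.seed(tc$seed)
  sz <- model$config$input_size
  params <- collect_params(model$layers)
  # pre-resize images/targets once
  data <- lapply(smears, function(s) {
    img <- s$image
    in_hw <- dim(img)[1:2]
    if (!identical(in_hw, c(sz, sz))) img <- resize_image(img, c(sz, sz))
    list(image = img, annotations = s$annotations, in_hw = in_hw)
  })
  hist <- list()
  it <- 0L
  log_con <- if (!is.null(log_path)) file(log_path, open = "w") else NULL
  on.exit(if (!is.null(log_con)) close(log_con), add = TRUE)
  for (ep in seq_len(epochs)) {
    idx <- sample(length(data))
    for (b0 in seq(1, length(idx), by = batch_size)) {
      batch <- idx[b0:min(b0 + batch_size - 1L, length(idx))]
      zero_grads(params)
      acc <- c(total = 0, cls = 0, box = 0, mask = 0)
      for (i in batch) {
        d <- data[[i]]
        anns <- d$annotations
        img <- d$image
        if (isTRUE(tc$augment)) {
          aug <- augment(d$image, d$annotations)
          img <- aug$image; anns <- aug$annotations
        }
        gt <- anns_to_targets(anns, dim(img)[1:2], sz)
        out <- detector_forward(model, img, train = TRUE)
        ls <- compute_losses(out, model, gt)
        tape_backward(tn_scale(ls$total, 1 / length(batch)))
        acc <- acc + c(ls$total$value, ls$cls, ls$box, ls$mask) / length(batch)
      }
      sgd_step(params, lr, tc$momentum, tc$weight_decay,
               clip_norm = if (is.null(tc$grad_clip)) 5 else tc$grad_clip)
      it <- it + 1L
      hist[[it]] <- data.frame(epoch = ep, iter = it, total = acc[["total"]],
                               cls = acc[["cls"]], box = acc[["box"]],
                               mask = acc[["mask"]])
      if (!is.null(log_con))
        writeLines(jsonlite::toJSON(hist[[it]], auto_unbox = TRUE), log_con)
      if (log_every > 0L && it %% log_every == 0L)
        message(sprintf("epoch %d iter %d loss %.4f (cls %.3f box %.3f mask %.3f)",
                        ep, it, acc[["total"]], acc[["cls"]], acc[["box"]],
                        acc[["mask"]]))
    }
    if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  }
  do.call(rbind, hist)
}
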
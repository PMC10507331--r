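# ---------------------------------------------------------------------------
# Prototype network, shared per-anchor prediction head, box decoding,
# greedy NMS and prototype-mask assembly.
# ---------------------------------------------------------------------------

#' Anchor set over the fused pyramid
#'
#' Three aspect ratios (1, 1/2, 2) and one scale per level. Boxes are
#' normalized `(cx, cy, w, h)` in [0,1] of the input image. Row ordering
#' matches the head output reshape: spatial position column-major (row index
#' fastest), anchor slot fastest within a position.
#'
#' @param level_hw list of `c(H, W)` grid sizes for the five levels
#' @param scales anchor side length in pixels, one per level
#' @param img_size input image side length in pixels
#' @param aspects aspect ratios (width/height)
#' @return matrix `n x 4` of `(cx, cy, w, h)`; attribute `level` gives the
#'   pyramid level of each anchor
#' @export
gen_anchors <- function(level_hw, scales, img_size,
                        aspects = c(1, 0.5, 2)) {
  stopifnot(length(level_hw) == length(scales))
  out <- vector("list", length(level_hw))
  lev <- vector("list", length(level_hw))
  for (i in seq_along(level_hw)) {
    H <- level_hw[[i]][1]; W <- level_hw[[i]][2]
    s <- scales[i] / img_size
    per <- cbind(w = s * sqrt(aspects), h = s / sqrt(aspects))
    rows <- matrix(0, H * W * length(aspects), 4)
    r <- 1L
    for (x in seq_len(W)) for (y in seq_len(H)) for (a in seq_along(aspects)) {
      rows[r, ] <- c((x - 0.5) / W, (y - 0.5) / H, per[a, 1], per[a, 2])
      r <- r + 1L
    }
    out[[i]] <- rows
    lev[[i]] <- rep(i, nrow(rows))
  }
  anchors <- do.call(rbind, out)
  colnames(anchors) <- c("cx", "cy", "w", "h")
  stopifnot(all(is.finite(anchors)))
  attr(anchors, "level") <- unlist(lev)
  anchors
}

#' Build the prototype network
#'
#' Several 3x3 conv+ReLU layers on the highest-resolution fused level, one
#' x2 upsample, a further 3x3 conv+ReLU, and a final 1x1 convolution to `k`
#' prototype logit maps at a quarter of the input resolution.
#'
#' @param channels input channel width (the fused pyramid width)
#' @param k number of prototypes (default 32)
#' @param n_convs number of pre-upsample 3x3 convolutions
#' @return protonet module
#' @export
build_protonet <- function(channels, k = 32L, n_convs = 3L) {
  lay <- list()
  for (i in seq_len(n_convs))
    lay[[paste0("conv", i)]] <- layer_conv2d(channels, channels, 3L,
                                             bias = TRUE,
                                             name = paste0("proto.conv", i))
  lay$post <- layer_conv2d(channels, channels, 3L, bias = TRUE,
                           name = "proto.post")
  lay$out <- layer_conv2d(channels, k, 1L, bias = TRUE, name = "proto.out",
                          gain = 0.5)
  e <- new.env(parent = emptyenv())
  e$layers <- lay
  e$meta <- list(type = "protonet", k = k, channels = channels,
                 n_convs = n_convs)
  class(e) <- c("wbc_protonet", "wbc_module")
  e
}

#' Prototype maps from the stride-8 fused level
#'
#' @param protonet module from [build_protonet()]
#' @param n3 stride-8 feature node
#' @param train training mode flag
#' @return node with `ceil(H/4) x ceil(W/4)`-sized `k` prototype logit maps
#'   (given an input at stride 8, the x2 upsample lands at stride 4)
#' @export
protonet_forward <- function(protonet, n3, train = TRUE) {
  l <- protonet$layers
  x <- n3
  for (i in seq_len(protonet$meta$n_convs))
    x <- tn_relu(l[[paste0("conv", i)]]$forward(x, train))
  x <- tn_upsample(x, 2L * dim(x$value)[1:2])
  x <- tn_relu(l$post$forward(x, train))
  l$out$forward(x, train)
}

#' Build the shared per-anchor prediction head
#'
#' One tower whose weights are shared across the five pyramid levels; per
#' anchor it emits class logits (background + cell classes), 4 box offsets,
#' and `k` mask coefficients squashed by tanh.
#'
#' @param channels pyramid channel width
#' @param k number of mask coefficients (= prototypes)
#' @param n_classes number of foreground classes (1 for the single
#'   white-blood-cell category)
#' @param n_anchors anchors per position (3 aspect ratios)
#' @param tower_convs shared 3x3 conv+ReLU layers before the three branches
#' @return head module
#' @export
build_pred_head <- function(channels, k = 32L, n_classes = 1L,
                            n_anchors = 3L, tower_convs = 1L) {
  lay <- list()
  for (i in seq_len(tower_convs))
    lay[[paste0("tower", i)]] <- layer_conv2d(channels, channels, 3L,
                                              bias = TRUE,
                                              name = paste0("head.tower", i))
  # small init on the output branches keeps initial logits near zero
  lay$cls <- layer_conv2d(channels, n_anchors * (n_classes + 1L), 3L,
                          bias = TRUE, name = "head.cls", gain = 0.1)
  lay$box <- layer_conv2d(channels, n_anchors * 4L, 3L, bias = TRUE,
                          name = "head.box", gain = 0.1)
  lay$coef <- layer_conv2d(channels, n_anchors * k, 3L, bias = TRUE,
                           name = "head.coef", gain = 0.1)
  e <- new.env(parent = emptyenv())
  e$layers <- lay
  e$meta <- list(type = "pred_head", channels = channels, k = k,
                 n_classes = n_classes, n_anchors = n_anchors,
                 tower_convs = tower_convs)
  class(e) <- c("wbc_pred_head", "wbc_module")
  e
}

#' Run the prediction head over the five fused levels
#'
#' @param head module from [build_pred_head()]
#' @param levels list of five feature nodes (N3..N7, post-attention)
#' @param train training mode flag
#' @return list of nodes: `cls` (`n x (n_classes+1)` logits), `box`
#'   (`n x 4` offsets), `coef` (`n x k`, tanh-bounded), rows ordered as
#'   [gen_anchors()]
#' @export
predict_heads <- function(head, levels, train = TRUE) {
  if (length(levels) != 5L) stop("expected 5 pyramid levels")
  m <- head$meta
  cls <- list(); box <- list(); coef <- list()
  for (i in seq_along(levels)) {
    x <- levels[[i]]
    for (t in seq_len(m$tower_convs))
      x <- tn_relu(head$layers[[paste0("tower", t)]]$forward(x, train))
    cls[[i]] <- tn_head_reshape(head$layers$cls$forward(x, train),
                                m$n_anchors, m$n_classes + 1L)
    box[[i]] <- tn_head_reshape(head$layers$box$forward(x, train),
                                m$n_anchors, 4L)
    coef[[i]] <- tn_tanh(tn_head_reshape(head$layers$coef$forward(x, train),
                                         m$n_anchors, m$k))
  }
  list(cls = tn_rbind(cls), box = tn_rbind(box), coef = tn_rbind(coef))
}

# --- boxes -----------------------------------------------------------------

# SSD-style decode with variances (0.1, 0.2); returns x1,y1,x2,y2 clipped
decode_boxes <- function(loc, anchors, variances = c(0.1, 0.2)) {
  cx <- anchors[, 1] + loc[, 1] * variances[1] * anchors[, 3]
  cy <- anchors[, 2] + loc[, 2] * variances[1] * anchors[, 4]
  w <- anchors[, 3] * exp(pmin(loc[, 3] * variances[2], 10))
  h <- anchors[, 4] * exp(pmin(loc[, 4] * variances[2], 10))
  b <- cbind(x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2)
  b[] <- pmin(pmax(b, 0), 1)
  b
}

encode_boxes <- function(gt_xyxy, anchors, variances = c(0.1, 0.2)) {
  gw <- pmax(gt_xyxy[, 3] - gt_xyxy[, 1], 1e-8)
  gh <- pmax(gt_xyxy[, 4] - gt_xyxy[, 2], 1e-8)
  gcx <- (gt_xyxy[, 1] + gt_xyxy[, 3]) / 2
  gcy <- (gt_xyxy[, 2] + gt_xyxy[, 4]) / 2
  cbind((gcx - anchors[, 1]) / (anchors[, 3] * variances[1]),
        (gcy - anchors[, 2]) / (anchors[, 4] * variances[1]),
        log(gw / anchors[, 3]) / variances[2],
        log(gh / anchors[, 4]) / variances[2])
}

#' Pairwise IoU of axis-aligned boxes
#'
#' @param a,b matrices `n x 4` / `m x 4` in `(x1, y1, x2, y2)`
#' @return `n x m` IoU matrix
#' @export
box_iou <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  ix1 <- pmax(matrix(a[, 1], n, m), matrix(b[, 1], n, m, byrow = TRUE))
  iy1 <- pmax(matrix(a[, 2], n, m), matrix(b[, 2], n, m, byrow = TRUE))
  ix2 <- pmin(matrix(a[, 3], n, m), matrix(b[, 3], n, m, byrow = TRUE))
  iy2 <- pmin(matrix(a[, 4], n, m), matrix(b[, 4], n, m, byrow = TRUE))
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  area_a <- pmax(a[, 3] - a[, 1], 0) * pmax(a[, 4] - a[, 2], 0)
  area_b <- pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
  un <- matrix(area_a, n, m) + matrix(area_b, n, m, byrow = TRUE) - inter
  ifelse(un > 0, inter / un, 0)
}

#' Greedy non-maximum suppression
#'
#' @param boxes `n x 4` decoded boxes `(x1, y1, x2, y2)`
#' @param scores length-`n` scores
#' @param iou_thr suppression IoU threshold
#' @param score_thr minimum score to consider
#' @param top_k maximum number of survivors
#' @return integer indices of kept detections, in descending score order
#' @export
nms <- function(boxes, scores, iou_thr = 0.5, score_thr = 0.05, top_k = 200L) {
  keep <- integer(0)
  cand <- which(scores >= score_thr)
  if (!length(cand)) return(keep)
  cand <- cand[order(scores[cand], decreasing = TRUE)]
  while (length(cand) && length(keep) < top_k) {
    i <- cand[1]
    keep <- c(keep, i)
    cand <- cand[-1]
    if (length(cand)) {
      ious <- box_iou(boxes[i, , drop = FALSE], boxes[cand, , drop = FALSE])
      cand <- cand[ious[1, ] < iou_thr]
    }
  }
  keep
}

# --- mask assembly ---------------------------------------------------------

# bilinear resize of a single-channel matrix
resize_bilinear <- function(m, out_hw) {
  img <- EBImage::resize(EBImage::Image(t(m)), w = out_hw[2], h = out_hw[1])
  t(EBImage::imageData(img))
}

#' Assemble instance masks from prototypes and coefficients
#'
#' Each instance mask is `sigmoid(sum_j coef_j * prototype_j)`, resized to
#' the output resolution, zeroed outside the (optionally padded) predicted
#' box, and thresholded strictly above `threshold`.
#'
#' @param protos `P x P x k` prototype logit array (or node)
#' @param coefs `n x k` coefficient matrix, one row per kept detection
#' @param boxes `n x 4` normalized boxes `(x1, y1, x2, y2)` used for cropping
#' @param out_hw output `c(H, W)` in pixels
#' @param pad fractional padding of the crop box on each side (0 = tight)
#' @param threshold mask binarization threshold (strict `>`)
#' @return list of `H x W` integer (0/1) matrices
#' @export
assemble_masks <- function(protos, coefs, boxes, out_hw, pad = 0,
                           threshold = 0.5) {
  pv <- if (is_node(protos)) protos$value else protos
  n <- nrow(coefs)
  if (is.null(n) || n == 0L) return(list())
  d <- dim(pv)
  pm <- pv; dim(pm) <- c(d[1] * d[2], d[3])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    logit <- matrix(pm %*% coefs[i, ], d[1], d[2])
    prob <- 1 / (1 + exp(-resize_bilinear(logit, out_hw)))
    b <- boxes[i, ]
    bw <- b[3] - b[1]; bh <- b[4] - b[2]
    x1 <- max(1L, floor((b[1] - pad * bw) * out_hw[2]) + 1L)
    x2 <- min(out_hw[2], ceiling((b[3] + pad * bw) * out_hw[2]))
    y1 <- max(1L, floor((b[2] - pad * bh) * out_hw[1]) + 1L)
    y2 <- min(out_hw[1], ceiling((b[4] + pad * bh) * out_hw[1]))
    mask <- matrix(0L, out_hw[1], out_hw[2])
    if (x2 >= x1 && y2 >= y1)
      mask[y1:y2, x1:x2] <- (prob[y1:y2, x1:x2] > threshold) * 1L
    out[[i]] <- mask
  }
  out
}
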
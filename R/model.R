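# ---------------------------------------------------------------------------
# Detector assembly: backbone -> fusion neck -> per-level attention ->
# (prototype network from N3 before attention; prediction head on attended
# N3..N7) -> decode / NMS / mask assembly.
# ---------------------------------------------------------------------------

# output side of a stride-2 conv/pool with k=3 (or 7 for the stem), pad (k-1)/2
conv_down <- function(n) (n - 1L) %/% 2L + 1L

# grid sizes of the five pyramid levels for a square input
pyramid_sizes <- function(input_size) {
  s2 <- conv_down(as.integer(input_size))  # stem
  s4 <- conv_down(s2)                      # max-pool
  c3 <- conv_down(s4)
  c4 <- conv_down(c3)
  c5 <- conv_down(c4)
  n6 <- conv_down(c5)
  n7 <- conv_down(n6)
  list(N3 = c(c3, c3), N4 = c(c4, c4), N5 = c(c5, c5),
       N6 = c(n6, n6), N7 = c(n7, n7))
}

#' Build the full instance-segmentation detector
#'
#' @param cfg configuration from [default_config()] (possibly merged with
#'   overrides); `cfg$backbone$arch = "standard_resnet50"`,
#'   `cfg$neck$type = "fpn"` and `cfg$attention$kind = "none"` together give
#'   the plain single-stage baseline
#' @return detector of class `wbc_detector`
#' @export
build_detector <- function(cfg = default_config("paper")) {
  bk <- cfg$backbone
  gcfg <- ghost_config(bk$S, bk$cheap_kernel, bk$replace_stem)
  backbone <- build_backbone(bk$arch, gcfg, include_classifier = FALSE,
                             width_mult = bk$width_mult,
                             stage_blocks = bk$stage_blocks)
  neck <- build_neck(backbone$meta$feature_channels, cfg$neck$channels,
                     cfg$neck$type)
  attn <- NULL
  if (cfg$attention$kind != "none") {
    attn <- lapply(3:7, function(i)
      build_attention(cfg$attention$kind, cfg$neck$channels,
                      cfg$attention$r, cfg$attention$components,
                      name = paste0("att.n", i)))
    names(attn) <- paste0("N", 3:7)
  }
  protonet <- build_protonet(cfg$neck$channels, cfg$heads$k,
                             cfg$heads$proto_convs)
  head <- build_pred_head(cfg$neck$channels, cfg$heads$k,
                          cfg$heads$n_classes,
                          length(cfg$heads$aspects), cfg$heads$tower_convs)
  sizes <- pyramid_sizes(cfg$input_size)
  anchors <- gen_anchors(sizes, cfg$heads$scales, cfg$input_size,
                         cfg$heads$aspects)
  e <- new.env(parent = emptyenv())
  e$layers <- c(list(backbone = backbone, neck = neck),
                if (!is.null(attn)) list(attn = attn),
                list(protonet = protonet, head = head))
  e$config <- cfg
  e$anchors <- anchors
  e$meta <- list(type = "detector", input_size = cfg$input_size,
                 pyramid = sizes)
  class(e) <- c("wbc_detector", "wbc_module")
  e
}

#' Detector forward pass
#'
#' @param model detector from [build_detector()]
#' @param image `H x W x 3` array in `[0,1]` (resized to the configured
#'   input size by the caller) or a tape node of the normalized image
#' @param train training mode flag
#' @return list with nodes `cls`, `box`, `coef` (per-anchor outputs),
#'   `protos` (prototype logits) and the fused `levels`
#' @export
detector_forward <- function(model, image, train = TRUE) {
  cfg <- model$config
  x <- if (is_node(image)) image else
    tn_const(normalize_image(image, cfg$normalize$mean, cfg$normalize$sd))
  feats <- model$layers$backbone$forward_features(x, train)
  levels <- neck_forward(model$layers$neck, feats, train)
  protos <- protonet_forward(model$layers$protonet, levels$N3, train)
  if (!is.null(model$layers$attn))
    levels <- lapply(stats::setNames(names(levels), names(levels)), function(nm)
      ddam_forward(model$layers$attn[[nm]], levels[[nm]], train))
  out <- predict_heads(model$layers$head, levels, train)
  out$protos <- protos
  out$levels <- levels
  out
}

#' Run inference on one image
#'
#' Forward pass in evaluation mode, softmax scores, box decoding, greedy
#' NMS, and prototype-mask assembly at image resolution.
#'
#' @param model detector
#' @param image `H x W x 3` array in `[0,1]`; resized to the model input
#'   size if needed
#' @return list with `boxes` (pixel `x1,y1,x2,y2` at model resolution),
#'   `scores`, `masks` (list of 0/1 matrices), `coefs`
#' @export
predict_image <- function(model, image) {
  cfg <- model$config
  sz <- cfg$input_size
  if (!identical(dim(image)[1:2], c(sz, sz)))
    image <- resize_image(image, c(sz, sz))
  out <- detector_forward(model, image, train = FALSE)
  scores_all <- softmax_rows(out$cls$value)
  fg <- 1 - scores_all[, 1]  # foreground = 1 - background probability
  boxes <- decode_boxes(out$box$value, model$anchors)
  keep <- nms(boxes, fg, cfg$predict$nms_iou, cfg$predict$score_thr,
              cfg$predict$top_k)
  if (!length(keep))
    return(list(boxes = matrix(0, 0, 4), scores = numeric(0),
                masks = list(), coefs = matrix(0, 0, cfg$heads$k)))
  masks <- assemble_masks(out$protos, out$coef$value[keep, , drop = FALSE],
                          boxes[keep, , drop = FALSE], c(sz, sz),
                          pad = cfg$predict$crop_pad,
                          threshold = cfg$predict$mask_threshold)
  nonempty <- vapply(masks, function(m) sum(m) > 0, logical(1))
  keep <- keep[nonempty]
  masks <- masks[nonempty]
  list(boxes = boxes[keep, , drop = FALSE] * sz,
       scores = fg[keep],
       masks = masks,
       coefs = out$coef$value[keep, , drop = FALSE])
}

softmax_rows <- function(m) {
  mx <- apply(m, 1, max)
  ex <- exp(m - mx)
  ex / rowSums(ex)
}

#' Resize an RGB image array
#'
#' Bilinear for images; use [resize_mask()] for label masks.
#' @param image `H x W x 3` array
#' @param out_hw target `c(H, W)`
#' @return resized array
#' @export
resize_image <- function(image, out_hw) {
  img <- EBImage::resize(EBImage::Image(aperm(image, c(2, 1, 3)),
                                        colormode = "Color"),
                         w = out_hw[2], h = out_hw[1])
  aperm(EBImage::imageData(img), c(2, 1, 3))
}

#' Resize a binary mask (nearest neighbour)
#'
#' @param mask `H x W` 0/1 matrix
#' @param out_hw target `c(H, W)`
#' @return resized 0/1 matrix
#' @export
resize_mask <- function(mask, out_hw) {
  storage.mode(mask) <- "double"
  r <- upsample_nearest_fwd(array(mask, dim = c(dim(mask), 1L)),
                            out_hw[1], out_hw[2])
  (r[, , 1] > 0.5) * 1L
}

# --- checkpointing ---------------------------------------------------------

#' Save a detector checkpoint
#'
#' Serializes the configuration, every parameter array and the normalization
#' running statistics (R native serialization).
#' @param model detector
#' @param path output file
#' @export
save_checkpoint <- function(model, path) {
  ps <- collect_params(model$layers)
  ls <- collect_layers(model$layers)
  run <- list()
  for (nm in names(ls)) {
    l <- ls[[nm]]
    if (identical(l$meta$type, "batchnorm2d"))
      run[[nm]] <- list(mean = l$run_mean, var = l$run_var)
  }
  saveRDS(list(config = model$config,
               params = lapply(ps, function(p) p$value),
               running = run), path)
  invisible(path)
}

#' Load a detector checkpoint
#'
#' @param path file written by [save_checkpoint()]
#' @return detector with restored weights
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_detector(ck$config)
  ps <- collect_params(model$layers)
  stopifnot(identical(sort(names(ps)), sort(names(ck$params))))
  for (nm in names(ps)) ps[[nm]]$value <- ck$params[[nm]]
  ls <- collect_layers(model$layers)
  for (nm in names(ck$running)) {
    ls[[nm]]$run_mean <- ck$running[[nm]]$mean
    ls[[nm]]$run_var <- ck$running[[nm]]$var
  }
  model
}

#' @export
print.wbc_detector <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<wbc_detector> %s(S=%d) + %s + attention:%s | input %d, k=%d, %s anchors\n",
    cfg$backbone$arch, cfg$backbone$S, cfg$neck$type, cfg$attention$kind,
    cfg$input_size, cfg$heads$k, format(nrow(x$anchors), big.mark = ",")))
  invisible(x)
}
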
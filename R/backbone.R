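# ---------------------------------------------------------------------------
# Ghost-module ResNet-50 backbone.
#
# A Ghost module replaces a standard convolution producing c_out channels by
# (1) a "primary" convolution with the original kernel and stride producing
#     m intrinsic channels, where m is c_out/S rounded to the nearest integer
#     (at least 1), and
# (2) a "cheap" 3x3 depthwise convolution generating the remaining c_out - m
#     channels from the intrinsic maps (round-robin over intrinsic maps),
# followed by channel concatenation. Each branch carries its own channel
# normalization. S = 1 degenerates exactly to the standard convolution.
#
# Replacement scope: the 1x1 and 3x3 convolutions inside residual bottlenecks.
# The 7x7 stem and the 1x1 downsample shortcuts stay standard convolutions
# (replace_stem = TRUE swaps the stem too, off by default).
# ---------------------------------------------------------------------------

#' Ghost module configuration
#'
#' @param S positive integer adjustment factor: the fraction of output
#'   channels produced by the full (primary) convolution is roughly `1/S`.
#'   `S = 1` is a standard convolution.
#' @param cheap_kernel odd kernel size of the cheap depthwise operation.
#' @param replace_stem replace the 7x7 stem convolution as well (default
#'   `FALSE`: only residual-block convolutions are replaced).
#' @return an object of class `ghost_config`
#' @export
ghost_config <- function(S = 4L, cheap_kernel = 3L, replace_stem = FALSE) {
  S <- as.integer(S)
  cheap_kernel <- as.integer(cheap_kernel)
  if (is.na(S) || S < 1L) stop("S must be a positive integer")
  if (cheap_kernel %% 2L == 0L) stop("cheap_kernel must be odd")
  structure(list(S = S, cheap_kernel = cheap_kernel,
                 replace_stem = isTRUE(replace_stem)),
            class = "ghost_config")
}

# intrinsic channel count of a Ghost module
ghost_intrinsic <- function(c_out, S) max(1L, as.integer(floor(c_out / S + 0.5)))

#' Ghost convolution module
#'
#' @param c_in,c_out input/output channel counts
#' @param k primary kernel size
#' @param stride primary stride
#' @param cfg a [ghost_config()]
#' @param relu apply ReLU after each branch (disabled for the expansion
#'   convolution of a bottleneck so the residual sum stays signed)
#' @param name parameter name prefix
#' @return a module whose `$forward(x, train)` maps an `H x W x c_in` node to
#'   `H' x W' x c_out`
#' @export
ghost_module <- function(c_in, c_out, k = 3L, stride = 1L, cfg = ghost_config(),
                         relu = TRUE, name = "ghost") {
  if (c_out < cfg$S)
    stop("c_out (", c_out, ") must be >= S (", cfg$S, ")")
  m <- ghost_intrinsic(c_out, cfg$S)
  n_cheap <- c_out - m
  layers <- list(
    primary = layer_conv2d(c_in, m, k, stride, (k - 1L) %/% 2L,
                           name = paste0(name, ".primary")),
    primary_bn = layer_batchnorm2d(m, name = paste0(name, ".primary_bn")))
  if (n_cheap > 0L) {
    ck <- cfg$cheap_kernel
    layers$cheap <- layer_conv2d(n_cheap, n_cheap, ck, 1L, (ck - 1L) %/% 2L,
                                 groups = n_cheap,
                                 name = paste0(name, ".cheap"))
    layers$cheap_bn <- layer_batchnorm2d(n_cheap, name = paste0(name, ".cheap_bn"))
  }
  gather_idx <- if (n_cheap > 0L) ((seq_len(n_cheap) - 1L) %% m) + 1L else integer(0)
  fwd <- function(x, train = TRUE) {
    y <- layers$primary_bn$forward(layers$primary$forward(x, train), train)
    if (relu) y <- tn_relu(y)
    if (n_cheap == 0L) return(y)
    z <- tn_channel_gather(y, gather_idx)
    z <- layers$cheap_bn$forward(layers$cheap$forward(z, train), train)
    if (relu) z <- tn_relu(z)
    tn_cat_channels(list(y, z))
  }
  new_module(layers, fwd, meta = list(type = "ghost", c_in = c_in, c_out = c_out,
                                      k = k, stride = stride, S = cfg$S,
                                      m = m, n_cheap = n_cheap))
}

# standard conv + BN (+ ReLU) block
conv_bn <- function(c_in, c_out, k, stride = 1L, relu = TRUE, name = "cb") {
  layers <- list(conv = layer_conv2d(c_in, c_out, k, stride, (k - 1L) %/% 2L,
                                     name = paste0(name, ".conv")),
                 bn = layer_batchnorm2d(c_out, name = paste0(name, ".bn")))
  fwd <- function(x, train = TRUE) {
    y <- layers$bn$forward(layers$conv$forward(x, train), train)
    if (relu) tn_relu(y) else y
  }
  new_module(layers, fwd)
}

# residual bottleneck: 1x1 reduce -> 3x3 -> 1x1 expand (x4), ghost or standard
bottleneck <- function(c_in, w, stride = 1L, cfg = NULL, name = "blk") {
  c_out <- 4L * w
  mk <- function(ci, co, k, s, relu, nm) {
    if (is.null(cfg)) conv_bn(ci, co, k, s, relu, nm)
    else ghost_module(ci, co, k, s, cfg, relu, nm)
  }
  layers <- list(
    conv1 = mk(c_in, w, 1L, 1L, TRUE, paste0(name, ".c1")),
    conv2 = mk(w, w, 3L, stride, TRUE, paste0(name, ".c2")),
    conv3 = mk(w, c_out, 1L, 1L, FALSE, paste0(name, ".c3")))
  has_short <- (stride != 1L || c_in != c_out)
  if (has_short)
    layers$short <- conv_bn(c_in, c_out, 1L, stride, relu = FALSE,
                            name = paste0(name, ".short"))
  fwd <- function(x, train = TRUE) {
    y <- layers$conv3$forward(
      layers$conv2$forward(
        layers$conv1$forward(x, train), train), train)
    s <- if (has_short) layers$short$forward(x, train) else x
    tn_relu(tn_add(y, s))
  }
  new_module(layers, fwd)
}

#' Build a ResNet-50 backbone (standard or Ghost)
#'
#' Spatial sizes follow `floor((n + 2*pad - k)/stride) + 1` at every
#' convolution and the stem max-pool, so a 550x550 input yields stage maps of
#' 69, 35 and 18 pixels at strides 8, 16 and 32.
#'
#' @param arch `"standard_resnet50"` or `"ghost_resnet50"`
#' @param cfg [ghost_config()] used when `arch = "ghost_resnet50"`
#' @param include_classifier attach the 1000-way classification layer
#'   (global average pooling + linear head); the detector uses `FALSE`
#' @param width_mult channel width multiplier (the reduced test-scale profile
#'   uses 1/8); channel counts are scaled and rounded up to at least 1
#' @param stage_blocks bottleneck counts of the four stages
#' @return a backbone model of class `wbc_backbone`
#' @export
build_backbone <- function(arch = c("ghost_resnet50", "standard_resnet50"),
                           cfg = ghost_config(4L),
                           include_classifier = FALSE,
                           width_mult = 1,
                           stage_blocks = c(3L, 4L, 6L, 3L)) {
  arch <- match.arg(arch)
  gcfg <- if (arch == "ghost_resnet50") cfg else NULL
  ch <- function(c) max(1L, as.integer(round(c * width_mult)))
  stem_c <- ch(64L)
  widths <- vapply(c(64L, 128L, 256L, 512L), ch, integer(1))
  stem <- if (!is.null(gcfg) && gcfg$replace_stem)
    ghost_module(3L, stem_c, 7L, 2L, gcfg, TRUE, "stem")
  else conv_bn(3L, stem_c, 7L, 2L, TRUE, "stem")
  pool <- layer_maxpool2d(3L, 2L, 1L)
  stages <- list()
  c_in <- stem_c
  for (i in seq_along(widths)) {
    blocks <- list()
    for (b in seq_len(stage_blocks[i])) {
      stride <- if (i > 1L && b == 1L) 2L else 1L
      blocks[[paste0("b", b)]] <- bottleneck(
        c_in, widths[i], stride, gcfg, sprintf("s%d.b%d", i, b))
      c_in <- 4L * widths[i]
    }
    stages[[paste0("s", i)]] <- blocks
  }
  layers <- list(stem = stem, stages = stages)
  if (include_classifier)
    layers$fc <- layer_linear(4L * widths[4], 1000L, bias = TRUE, name = "fc")
  e <- new.env(parent = emptyenv())
  e$layers <- layers
  e$pool <- pool
  e$meta <- list(arch = arch, S = if (is.null(gcfg)) 1L else gcfg$S,
                 include_classifier = include_classifier,
                 width_mult = width_mult, stage_blocks = stage_blocks,
                 widths = widths,
                 feature_channels = 4L * widths[2:4])
  e$forward_features <- function(x, train = TRUE) {
    y <- pool$forward(layers$stem$forward(x, train), train)
    feats <- list()
    for (i in seq_along(layers$stages)) {
      for (blk in layers$stages[[i]]) y <- blk$forward(y, train)
      if (i >= 2L) feats[[paste0("C", i + 1L)]] <- y
    }
    feats
  }
  e$forward_classifier <- function(x, train = TRUE) {
    if (is.null(layers$fc)) stop("backbone built without classifier")
    f <- e$forward_features(x, train)
    g <- tn_gap(f$C5)
    gm <- new_node(matrix(g$value, 1L), list(g), function(gr) list(as.numeric(gr)))
    layers$fc$forward(gm, train)
  }
  class(e) <- c("wbc_backbone", "wbc_module")
  e
}

#' Extract pyramid features from an image
#'
#' @param backbone a model from [build_backbone()]
#' @param image `H x W x 3` numeric array (values in `[0,1]`) or a tape node
#' @param train propagate training-mode normalization statistics
#' @return list with `C3`, `C4`, `C5` feature-map nodes at strides 8/16/32
#' @export
extract_features <- function(backbone, image, train = FALSE) {
  x <- if (is_node(image)) image else tn_const(normalize_image(image))
  d <- dim(x$value)
  if (length(d) != 3L || d[3] != 3L) stop("image must be H x W x 3")
  if (d[1] < 64L || d[2] < 64L) stop("image must be at least 64 x 64")
  backbone$forward_features(x, train)
}

# per-channel standardization used before the backbone
normalize_image <- function(image, mean = 0.5, sd = 0.25) {
  (image - mean) / sd
}

#' @export
print.wbc_backbone <- function(x, ...) {
  cat(sprintf("<%s> S=%d width_mult=%g classifier=%s params=%s\n",
              x$meta$arch, x$meta$S, x$meta$width_mult,
              x$meta$include_classifier,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
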
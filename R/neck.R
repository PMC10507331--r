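# ---------------------------------------------------------------------------
# Feature-fusion neck.
#
# Top-down path (classic FPN): P5 = 1x1(C5); P_k = 1x1(C_k) + up2(P_{k+1}).
# Bottom-up path (the dual-stream fusion): N3 = P3; M_k = 3x3 stride-2
# conv(N_k); N_{k+1} = 3x3 conv(P_{k+1} + M_k) for k = 3,4; N6 and N7 by
# further stride-2 convolutions from N5 and N6. All levels carry the same
# channel width (256 at paper scale).
#
# The plain-FPN baseline is the same module with the bottom-up path disabled:
# it emits P3..P5 (3x3-smoothed) plus P6/P7 downsampled from P5/P6.
# ---------------------------------------------------------------------------

#' Build the feature-fusion neck
#'
#' @param in_channels channel counts of C3/C4/C5
#' @param channels output width of every pyramid level
#' @param type `"dffn"` (top-down + bottom-up dual stream) or `"fpn"`
#'   (top-down only baseline)
#' @return a neck module
#' @export
build_neck <- function(in_channels = c(512L, 1024L, 2048L), channels = 256L,
                       type = c("dffn", "fpn")) {
  type <- match.arg(type)
  lay <- list(
    lat3 = layer_conv2d(in_channels[1], channels, 1L, bias = TRUE, name = "lat3"),
    lat4 = layer_conv2d(in_channels[2], channels, 1L, bias = TRUE, name = "lat4"),
    lat5 = layer_conv2d(in_channels[3], channels, 1L, bias = TRUE, name = "lat5"))
  if (type == "dffn") {
    lay$down3 <- layer_conv2d(channels, channels, 3L, 2L, 1L, bias = TRUE, name = "down3")
    lay$down4 <- layer_conv2d(channels, channels, 3L, 2L, 1L, bias = TRUE, name = "down4")
    lay$fuse4 <- layer_conv2d(channels, channels, 3L, bias = TRUE, name = "fuse4")
    lay$fuse5 <- layer_conv2d(channels, channels, 3L, bias = TRUE, name = "fuse5")
  } else {
    lay$smooth3 <- layer_conv2d(channels, channels, 3L, bias = TRUE, name = "smooth3")
    lay$smooth4 <- layer_conv2d(channels, channels, 3L, bias = TRUE, name = "smooth4")
    lay$smooth5 <- layer_conv2d(channels, channels, 3L, bias = TRUE, name = "smooth5")
  }
  lay$extra6 <- layer_conv2d(channels, channels, 3L, 2L, 1L, bias = TRUE, name = "extra6")
  lay$extra7 <- layer_conv2d(channels, channels, 3L, 2L, 1L, bias = TRUE, name = "extra7")
  e <- new.env(parent = emptyenv())
  e$layers <- lay
  e$meta <- list(type = type, channels = channels, in_channels = in_channels)
  class(e) <- c("wbc_neck", "wbc_module")
  e
}

# element-wise fusion with an explicit shape assertion; spatial mismatches
# after x2 upsampling are resolved by resizing to the lateral map's size
fuse_add <- function(a, b) {
  stopifnot(identical(dim(a$value), dim(b$value)))
  tn_add(a, b)
}

#' Top-down pyramid from backbone features
#'
#' @param neck module from [build_neck()]
#' @param feats list with `C3`, `C4`, `C5` nodes
#' @param train training mode flag
#' @return list with `P3`, `P4`, `P5` nodes (equal channel width)
#' @export
neck_top_down <- function(neck, feats, train = TRUE) {
  l <- neck$layers
  P5 <- l$lat5$forward(feats$C5, train)
  Y4 <- l$lat4$forward(feats$C4, train)
  P4 <- fuse_add(Y4, tn_upsample(P5, dim(Y4$value)[1:2]))
  Y3 <- l$lat3$forward(feats$C3, train)
  P3 <- fuse_add(Y3, tn_upsample(P4, dim(Y3$value)[1:2]))
  list(P3 = P3, P4 = P4, P5 = P5)
}

#' Bottom-up fusion producing the five-level pyramid
#'
#' @param neck module from [build_neck()] with `type = "dffn"`
#' @param p top-down pyramid from [neck_top_down()]
#' @param train training mode flag
#' @return list with `N3`..`N7` nodes
#' @export
neck_bottom_up <- function(neck, p, train = TRUE) {
  if (neck$meta$type != "dffn") stop("bottom_up requires a dffn neck")
  l <- neck$layers
  N3 <- p$P3
  M3 <- tn_relu(l$down3$forward(N3, train))
  N4 <- tn_relu(l$fuse4$forward(fuse_add(p$P4, M3), train))
  M4 <- tn_relu(l$down4$forward(N4, train))
  N5 <- tn_relu(l$fuse5$forward(fuse_add(p$P5, M4), train))
  N6 <- l$extra6$forward(N5, train)
  N7 <- l$extra7$forward(N6, train)
  list(N3 = N3, N4 = N4, N5 = N5, N6 = N6, N7 = N7)
}

#' Full neck forward pass
#'
#' For the `"fpn"` baseline the five levels are the smoothed P3..P5 plus
#' P6/P7 obtained by stride-2 convolutions from P5 and P6; for `"dffn"` the
#' bottom-up fusion is applied. Either way five same-width levels come back
#' under the names `N3`..`N7`.
#' @inheritParams neck_top_down
#' @return list of five feature-map nodes `N3`..`N7`
#' @export
neck_forward <- function(neck, feats, train = TRUE) {
  p <- neck_top_down(neck, feats, train)
  if (neck$meta$type == "dffn") return(neck_bottom_up(neck, p, train))
  l <- neck$layers
  P3 <- tn_relu(l$smooth3$forward(p$P3, train))
  P4 <- tn_relu(l$smooth4$forward(p$P4, train))
  P5 <- tn_relu(l$smooth5$forward(p$P5, train))
  P6 <- l$extra6$forward(P5, train)
  P7 <- l$extra7$forward(P6, train)
  list(N3 = P3, N4 = P4, N5 = P5, N6 = P6, N7 = P7)
}
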
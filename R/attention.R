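# ---------------------------------------------------------------------------
# Dual-domain attention: frequency-domain channel attention (spectral
# components of the unnormalized 2D-DCT through a shared two-layer MLP,
# summed, sigmoid) in series with CBAM-style spatial attention.
# ---------------------------------------------------------------------------

# unnormalized DCT-II basis vector of length n at frequency h:
# cos(pi * h / n * (i + 1/2)), i = 0..n-1
dct_basis <- function(n, h) cos(pi * h / n * (seq_len(n) - 0.5))

#' Spectral component of each channel
#'
#' Computes the unnormalized type-II DCT coefficient at frequency position
#' `(h, w)` of every channel of a feature map:
#' `Y_hw = sum_ij F(i,j) cos(pi*h*(i+1/2)/H) cos(pi*w*(j+1/2)/W)`.
#' The `(0,0)` component equals `H*W` times the global average pooling of the
#' channel.
#'
#' @param f feature map, `H x W x C` numeric array (or tape node)
#' @param h,w integer frequency indices, `0 <= h < H`, `0 <= w < W`
#' @return length-`C` numeric vector (or a `1 x C` node when `f` is a node)
#' @export
dct_component <- function(f, h, w) {
  val <- if (is_node(f)) f$value else f
  d <- dim(val)
  if (length(d) != 3L) stop("f must be H x W x C")
  if (h < 0L || h >= d[1] || w < 0L || w >= d[2])
    stop("frequency indices out of range: need 0 <= h < H, 0 <= w < W")
  basis <- as.numeric(outer(dct_basis(d[1], h), dct_basis(d[2], w)))
  if (is_node(f))
    return(tn_basis_project(tn_flatten_hw(f), matrix(basis, 1L)))
  fm <- val; dim(fm) <- c(d[1] * d[2], d[3])
  as.numeric(basis %*% fm)
}

#' Build a frequency-domain channel attention module
#'
#' The configured spectral components of the input are each passed through
#' one shared MLP (`C -> ceil(C/r)` with ReLU, then back to `C`), summed, and
#' squashed by a sigmoid into per-channel weights in (0,1).
#'
#' @param channels number of channels `C`
#' @param r reduction ratio of the shared MLP (default 16)
#' @param components list of `c(h, w)` integer pairs; the default uses the
#'   three lowest components (0,0), (0,1), (1,0)
#' @param use_gmp also feed the global-max-pool vector through the MLP (the
#'   CBAM-style channel attention is `components = list(c(0,0))` with
#'   `use_gmp = TRUE`)
#' @param name parameter prefix
#' @return attention module
#' @export
build_fcam <- function(channels, r = 16L,
                       components = list(c(0L, 0L), c(0L, 1L), c(1L, 0L)),
                       use_gmp = FALSE, name = "fcam") {
  hidden <- max(1L, as.integer(ceiling(channels / r)))
  lay <- list(fc1 = layer_linear(channels, hidden, bias = FALSE,
                                 name = paste0(name, ".fc1")),
              fc2 = layer_linear(hidden, channels, bias = FALSE,
                                 name = paste0(name, ".fc2")))
  e <- new.env(parent = emptyenv())
  e$layers <- lay
  e$meta <- list(type = "fcam", channels = channels, r = r,
                 components = components, use_gmp = use_gmp)
  class(e) <- c("wbc_fcam", "wbc_module")
  e
}

# shared MLP: C -> C/r -> C with ReLU between (input/output as 1 x C nodes)
fcam_mlp <- function(fcam, v, train) {
  fcam$layers$fc2$forward(tn_relu(fcam$layers$fc1$forward(v, train)), train)
}

#' Frequency-domain channel weights
#'
#' @param fcam module from [build_fcam()]
#' @param f feature map node (`H x W x C`)
#' @param train training mode flag
#' @return node holding a `1 x C` matrix of weights strictly inside (0,1)
#' @export
fcam_weights <- function(fcam, f, train = TRUE) {
  d <- dim(f$value)
  acc <- NULL
  for (cmp in fcam$meta$components) {
    # a level smaller than the requested frequency has no such component
    # (relevant only for the tiny top pyramid levels of reduced profiles)
    if (cmp[1] >= d[1] || cmp[2] >= d[2]) next
    y <- dct_component(f, cmp[1], cmp[2])
    m <- fcam_mlp(fcam, y, train)
    acc <- if (is.null(acc)) m else tn_add(acc, m)
  }
  if (fcam$meta$use_gmp) {
    gm <- tn_gmp(f)
    gmrow <- new_node(matrix(gm$value, 1L), list(gm),
                      function(g) list(as.numeric(g)))
    m <- fcam_mlp(fcam, gmrow, train)
    acc <- if (is.null(acc)) m else tn_add(acc, m)
  }
  if (is.null(acc)) stop("no components configured")
  tn_sigmoid(acc)
}

#' Build a spatial attention module
#'
#' Channel-wise mean and max maps are stacked and passed through a single
#' 7x7 convolution and a sigmoid, giving one attention value per pixel.
#'
#' @param kernel convolution kernel size (odd; default 7)
#' @param name parameter prefix
#' @return attention module
#' @export
build_spatial_attention <- function(kernel = 7L, name = "sam") {
  if (kernel %% 2L == 0L) stop("kernel must be odd")
  lay <- list(conv = layer_conv2d(2L, 1L, kernel, 1L, (kernel - 1L) %/% 2L,
                                  bias = TRUE, name = paste0(name, ".conv")))
  e <- new.env(parent = emptyenv())
  e$layers <- lay
  e$meta <- list(type = "sam", kernel = kernel)
  class(e) <- c("wbc_sam", "wbc_module")
  e
}

#' Spatial attention map
#'
#' @param sam module from [build_spatial_attention()]
#' @param f feature map node (`H x W x C`)
#' @param train training mode flag
#' @return node holding an `H x W x 1` map with values in (0,1)
#' @export
spatial_attention <- function(sam, f, train = TRUE) {
  mean_map <- tn_expand1(tn_channel_mean(f))
  max_map <- tn_expand1(tn_channel_max(f))
  stacked <- tn_cat_channels(list(mean_map, max_map))
  tn_sigmoid(sam$layers$conv$forward(stacked, train))
}

#' Build a dual-domain attention module
#'
#' Channel attention from the frequency domain followed in series by spatial
#' attention: `F' = F (.) M_F` (per-channel weights broadcast over space),
#' then `F'' = F' (.) M_S` (per-pixel weights broadcast over channels).
#'
#' @param channels number of channels of the attended level
#' @param r MLP reduction ratio
#' @param components spectral component list, as in [build_fcam()]
#' @param use_gmp include the global-max-pool path (CBAM variant)
#' @param name parameter prefix
#' @return attention module
#' @export
build_ddam <- function(channels, r = 16L,
                       components = list(c(0L, 0L), c(0L, 1L), c(1L, 0L)),
                       use_gmp = FALSE, name = "ddam") {
  lay <- list(fcam = build_fcam(channels, r, components, use_gmp,
                                paste0(name, ".fcam")),
              sam = build_spatial_attention(7L, paste0(name, ".sam")))
  e <- new.env(parent = emptyenv())
  e$layers <- lay
  e$meta <- list(type = "ddam", channels = channels, r = r,
                 components = components, use_gmp = use_gmp)
  class(e) <- c("wbc_ddam", "wbc_module")
  e
}

#' Apply dual-domain attention
#'
#' @param ddam module from [build_ddam()]
#' @param f feature map node (`H x W x C`)
#' @param train training mode flag
#' @return attended feature map node of identical shape
#' @export
ddam_forward <- function(ddam, f, train = TRUE) {
  mf <- fcam_weights(ddam$layers$fcam, f, train)
  mfv <- new_node(as.numeric(mf$value), list(mf),
                  function(g) list(matrix(g, 1L)))
  f1 <- tn_mul_channel(f, mfv)
  ms <- spatial_attention(ddam$layers$sam, f1, train)
  msm <- new_node(matrix(ms$value, dim(ms$value)[1], dim(ms$value)[2]),
                  list(ms), function(g) list(array(g, dim = dim(ms$value))))
  tn_mul_spatial(f1, msm)
}

# resolve the per-level attention configuration string to a builder
# ("none", "cbam", "fcam_sam")
build_attention <- function(kind, channels, r = 16L, components = NULL,
                            name = "att") {
  switch(kind,
    none = NULL,
    cbam = build_ddam(channels, r, components = list(c(0L, 0L)),
                      use_gmp = TRUE, name = name),
    fcam_sam = build_ddam(
      channels, r,
      components = if (is.null(components))
        list(c(0L, 0L), c(0L, 1L), c(1L, 0L)) else components,
      use_gmp = FALSE, name = name),
    stop("unknown attention kind: ", kind))
}
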
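# ---------------------------------------------------------------------------
# Trainable layers. A layer is an environment with:
#   $forward(x, train)  node -> node
#   $params             named list of parameter environments
#   $meta               list describing the layer (for parameter/FLOP audits)
# ---------------------------------------------------------------------------

#' 2-D convolution layer
#'
#' Weights are stored as a `(k^2 * c_in / groups) x c_out` matrix so the
#' forward pass is a single GEMM per group on the im2col expansion. Output
#' spatial size follows `floor((n + 2*pad - k)/stride) + 1` (the package-wide
#' rounding convention).
#' @keywords internal
layer_conv2d <- function(c_in, c_out, k, stride = 1L, pad = (k - 1L) %/% 2L,
                         groups = 1L, bias = FALSE, name = "conv",
                         gain = sqrt(2)) {
  stopifnot(c_in %% groups == 0, c_out %% groups == 0)
  fan_in <- k * k * c_in / groups
  params <- list(w = new_param(init_kaiming(c(fan_in, c_out), fan_in, gain),
                               paste0(name, ".w")))
  if (bias) params$b <- new_param(numeric(c_out), paste0(name, ".b"))
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$meta <- list(type = "conv2d", k = k, c_in = c_in, c_out = c_out,
                 stride = stride, pad = pad, groups = groups, bias = bias)
  e$forward <- function(x, train = TRUE) {
    wp <- params$w
    wn <- tn_leaf(wp)
    bn_ <- if (bias) tn_leaf(params$b) else NULL
    bval <- if (bias) params$b$value else numeric(0)
    out <- conv2d_fwd(x$value, wp$value, bval, bias, k, stride, pad, groups)
    if (!is.null(.wbc$flop_counter))
      .wbc$flop_counter$macs <- .wbc$flop_counter$macs +
        prod(dim(out)[1:2]) * k * k * (c_in / groups) * c_out
    parents <- c(list(x, wn), if (bias) list(bn_))
    new_node(out, parents, function(g) {
      r <- conv2d_bwd(x$value, wp$value, g, k, stride, pad, groups, bias)
      c(list(r$gx, r$gw), if (bias) list(as.numeric(r$gb)))
    })
  }
  class(e) <- "wbc_layer"
  e
}

#' Channel normalization layer (batch-norm bookkeeping)
#'
#' Affine scale/shift per channel with running mean/variance for inference.
#' Training statistics are computed over the spatial extent of the current
#' image, which makes training deterministic and independent of how a batch
#' is split for gradient accumulation (equivalent to batch norm at batch
#' size one).
#' @keywords internal
layer_batchnorm2d <- function(c, eps = 1e-5, momentum = 0.1, name = "bn") {
  params <- list(gamma = new_param(rep(1, c), paste0(name, ".gamma")),
                 beta  = new_param(numeric(c), paste0(name, ".beta")))
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$run_mean <- numeric(c)
  e$run_var <- rep(1, c)
  e$meta <- list(type = "batchnorm2d", c = c)
  e$forward <- function(x, train = TRUE) {
    d <- dim(x$value)
    n <- d[1] * d[2]
    gn <- tn_leaf(params$gamma); bn_ <- tn_leaf(params$beta)
    if (train) {
      xm <- x$value; dim(xm) <- c(n, d[3])
      mu <- colMeans(xm)
      v <- colMeans(xm^2) - mu^2
      e$run_mean <- (1 - momentum) * e$run_mean + momentum * mu
      e$run_var <- (1 - momentum) * e$run_var + momentum * v * n / max(1, n - 1)
    } else {
      mu <- e$run_mean; v <- e$run_var
    }
    istd <- 1 / sqrt(v + eps)
    expand <- function(vec) aperm(array(vec, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
    xhat <- (x$value - expand(mu)) * expand(istd)
    out <- xhat * expand(params$gamma$value) + expand(params$beta$value)
    new_node(out, list(x, gn, bn_), function(g) {
      gm <- g; dim(gm) <- c(n, d[3])
      xh <- xhat; dim(xh) <- c(n, d[3])
      dgamma <- colSums(gm * xh)
      dbeta <- colSums(gm)
      gg <- params$gamma$value * istd
      if (train) {
        dx <- (gm - matrix(dbeta / n, n, d[3], byrow = TRUE) -
                 xh * matrix(dgamma / n, n, d[3], byrow = TRUE)) *
          matrix(gg, n, d[3], byrow = TRUE)
      } else {
        dx <- gm * matrix(gg, n, d[3], byrow = TRUE)
      }
      dim(dx) <- d
      list(dx, dgamma, dbeta)
    })
  }
  class(e) <- "wbc_layer"
  e
}

#' @keywords internal
layer_maxpool2d <- function(k, stride, pad = 0L) {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$meta <- list(type = "maxpool2d", k = k, stride = stride, pad = pad)
  e$forward <- function(x, train = TRUE) {
    r <- maxpool2d_fwd(x$value, k, stride, pad)
    d <- dim(x$value)
    new_node(r$out, list(x), function(g) list(maxpool2d_bwd(r$arg, g, d[1], d[2])))
  }
  class(e) <- "wbc_layer"
  e
}

# functional resize (no params)
tn_upsample <- function(x, out_hw) {
  d <- dim(x$value)
  new_node(upsample_nearest_fwd(x$value, out_hw[1], out_hw[2]), list(x),
           function(g) list(upsample_nearest_bwd(g, d[1], d[2])))
}

#' @keywords internal
layer_linear <- function(n_in, n_out, bias = TRUE, name = "fc") {
  params <- list(w = new_param(init_kaiming(c(n_in, n_out), n_in, gain = 1),
                               paste0(name, ".w")))
  if (bias) params$b <- new_param(numeric(n_out), paste0(name, ".b"))
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$meta <- list(type = "linear", n_in = n_in, n_out = n_out, bias = bias)
  e$forward <- function(x, train = TRUE) {  # x: node with 1 x n_in matrix
    out <- tn_matmul(x, tn_leaf(params$w))
    if (bias) {
      bn_ <- tn_leaf(params$b)
      out <- new_node(out$value + matrix(params$b$value, nrow(out$value),
                                         length(params$b$value), byrow = TRUE),
                      list(out, bn_), function(g) list(g, colSums(g)))
    }
    if (!is.null(.wbc$flop_counter))
      .wbc$flop_counter$macs <- .wbc$flop_counter$macs + n_in * n_out
    out
  }
  class(e) <- "wbc_layer"
  e
}

# --- module plumbing --------------------------------------------------------

# Flatten the parameter environments of a (nested) module structure.
collect_params <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "wbc_layer")) {
    for (nm in names(x$params)) out[[paste0(prefix, nm)]] <- x$params[[nm]]
    return(out)
  }
  if (inherits(x, "wbc_module")) return(collect_params(x$layers, prefix))
  if (is.list(x)) {
    for (nm in names(x)) {
      sub <- collect_params(x[[nm]], paste0(prefix, nm, "."))
      out <- c(out, sub)
    }
  }
  out
}

# Flatten all layer environments of a (nested) module structure, named.
collect_layers <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "wbc_layer")) {
    out[[sub("\\.$", "", prefix)]] <- x
    return(out)
  }
  if (inherits(x, "wbc_module")) return(collect_layers(x$layers, prefix))
  if (is.list(x)) {
    for (nm in names(x))
      out <- c(out, collect_layers(x[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

new_module <- function(layers, forward, meta = list()) {
  e <- new.env(parent = emptyenv())
  e$layers <- layers
  e$forward <- forward
  e$meta <- meta
  class(e) <- "wbc_module"
  e
}

seq_forward <- function(layers, x, train = TRUE) {
  for (l in layers) x <- l$forward(x, train)
  x
}
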
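#' @useDynLib wbcseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Reverse-mode autodiff tape.
#
# A node is an environment holding:
#   value    numeric array / matrix / vector / scalar
#   parents  list of parent nodes
#   backward function(grad) -> list of gradients, one per parent (or NULL)
#   param    for leaf nodes, the parameter environment to accumulate into
#   id       monotone counter used for reverse-topological traversal
#
# Heavy kernels (conv, pooling, resize) live in src/ops.cpp; everything else
# is vectorised base R. Graphs here are small (hundreds of nodes per image),
# so environment overhead is negligible next to the matrix work.
# ---------------------------------------------------------------------------

.wbc <- new.env(parent = emptyenv())
.wbc$node_id <- 0L

new_node <- function(value, parents = list(), backward = NULL, param = NULL) {
  # force args first: with lazy evaluation a nested constructor call must
  # finish (and take its id) before this node claims the next id, so a node's
  # id is always strictly greater than its parents'
  force(value); force(parents); force(backward); force(param)
  .wbc$node_id <- .wbc$node_id + 1L
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$param <- param
  e$grad <- NULL
  e$id <- .wbc$node_id
  class(e) <- "wbc_node"
  e
}

is_node <- function(x) inherits(x, "wbc_node")

tn_const <- function(value) new_node(value)

#' @noRd
tn_leaf <- function(param) new_node(param$value, param = param)

# Accumulate `g` into node's grad slot (shapes already agree).
acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Run reverse-mode backpropagation from a scalar loss node.
#'
#' Gradients accumulate into the `$grad` field of every parameter reached by
#' the graph (added to any gradient already there, so gradient accumulation
#' over a batch is the default behaviour).
#' @param loss scalar output node
#' @keywords internal
tape_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  # iterative DFS postorder: reversing it processes every node before any of
  # its parents regardless of construction order
  seen <- new.env(parent = emptyenv())
  post <- list()
  stack <- list(list(node = loss, expanded = FALSE))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    n <- top$node
    key <- as.character(n$id)
    if (top$expanded) {
      post[[length(post) + 1L]] <- n
      next
    }
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    stack[[length(stack) + 1L]] <- list(node = n, expanded = TRUE)
    for (p in n$parents)
      stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
  }
  loss$grad <- 1
  for (i in rev(seq_along(post))) {
    n <- post[[i]]
    if (is.null(n$grad)) next
    if (!is.null(n$param)) {
      if (is.null(n$param$grad)) n$param$grad <- n$grad else
        n$param$grad <- n$param$grad + n$grad
    }
    if (!is.null(n$backward) && length(n$parents)) {
      gs <- n$backward(n$grad)
      for (j in seq_along(n$parents))
        if (!is.null(gs[[j]])) acc_grad(n$parents[[j]], gs[[j]])
    }
    if (length(n$parents)) n$grad <- NULL  # free intermediates as we go
  }
  invisible(NULL)
}

# --- parameters -------------------------------------------------------------

new_param <- function(value, name = "") {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$name <- name
  class(e) <- "wbc_param"
  e
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# He-style fan-in scaled Gaussian init (zero-filled under with_zero_init())
init_kaiming <- function(dims, fan_in, gain = sqrt(2)) {
  if (isTRUE(.wbc$zero_init)) return(array(0, dim = dims))
  array(stats::rnorm(prod(dims), sd = gain / sqrt(fan_in)), dim = dims)
}

# --- elementwise / structural ops ------------------------------------------

tn_add <- function(a, b) {
  new_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

tn_scale <- function(a, s) {  # s plain numeric scalar
  new_node(a$value * s, list(a), function(g) list(g * s))
}

tn_relu <- function(a) {
  m <- a$value > 0
  new_node(a$value * m, list(a), function(g) list(g * m))
}

tn_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  new_node(y, list(a), function(g) list(g * y * (1 - y)))
}

tn_tanh <- function(a) {
  y <- tanh(a$value)
  new_node(y, list(a), function(g) list(g * (1 - y^2)))
}

tn_matmul <- function(a, b) {  # plain matrix product
  new_node(a$value %*% b$value, list(a, b), function(g)
    list(g %*% t(b$value), t(a$value) %*% g))
}

tn_sum <- function(a) {
  new_node(sum(a$value), list(a), function(g) {
    gv <- a$value; gv[] <- g; list(gv)
  })
}

# concatenate feature maps along channels
tn_cat_channels <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  ends <- cumsum(cs); starts <- ends - cs + 1
  out <- array(0, dim = c(dim(vals[[1]])[1:2], sum(cs)))
  for (i in seq_along(vals)) out[, , starts[i]:ends[i]] <- vals[[i]]
  new_node(out, nodes, function(g)
    lapply(seq_along(nodes), function(i) g[, , starts[i]:ends[i], drop = FALSE]))
}

# x: H x W x C map, w: length-C vector -> x[,,c] * w[c]
tn_mul_channel <- function(x, w) {
  d <- dim(x$value)
  wfull <- aperm(array(w$value, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  new_node(x$value * wfull, list(x, w), function(g)
    list(g * wfull, apply(g * x$value, 3, sum)))
}

# x: H x W x C map, m: H x W matrix -> x[,,c] * m
tn_mul_spatial <- function(x, m) {
  d <- dim(x$value)
  mfull <- array(m$value, dim = d)  # recycles over channels
  new_node(x$value * mfull, list(x, m), function(g)
    list(g * mfull, {
      gm <- g * x$value
      dim(gm) <- c(d[1] * d[2], d[3])
      matrix(rowSums(gm), d[1], d[2])
    }))
}

# channel-wise mean over space: H x W x C -> length-C vector
tn_gap <- function(x) {
  d <- dim(x$value)
  new_node(apply(x$value, 3, mean), list(x), function(g) {
    gfull <- aperm(array(g / (d[1] * d[2]), dim = c(d[3], d[1], d[2])), c(2, 3, 1))
    list(gfull)
  })
}

# channel-wise max over space: H x W x C -> length-C vector
tn_gmp <- function(x) {
  d <- dim(x$value)
  xm <- x$value; dim(xm) <- c(d[1] * d[2], d[3])
  idx <- max.col(t(xm), ties.method = "first")
  val <- xm[cbind(idx, seq_len(d[3]))]
  new_node(val, list(x), function(g) {
    gx <- array(0, dim = d); dim(gx) <- c(d[1] * d[2], d[3])
    gx[cbind(idx, seq_len(d[3]))] <- g
    dim(gx) <- d
    list(gx)
  })
}

# pixelwise mean / max across channels: H x W x C -> H x W
tn_channel_mean <- function(x) {
  d <- dim(x$value)
  new_node(apply(x$value, c(1, 2), mean), list(x), function(g)
    list(array(rep(g / d[3], d[3]), dim = d)))
}

tn_channel_max <- function(x) {
  d <- dim(x$value)
  xm <- x$value; dim(xm) <- c(d[1] * d[2], d[3])
  idx <- max.col(xm, ties.method = "first")
  val <- matrix(xm[cbind(seq_len(d[1] * d[2]), idx)], d[1], d[2])
  new_node(val, list(x), function(g) {
    gx <- matrix(0, d[1] * d[2], d[3])
    gx[cbind(seq_len(d[1] * d[2]), idx)] <- as.vector(g)
    dim(gx) <- d
    list(gx)
  })
}

# promote an H x W matrix to H x W x 1
tn_expand1 <- function(x) {
  d <- dim(x$value)
  new_node(array(x$value, dim = c(d, 1L)), list(x), function(g)
    list(matrix(g, d[1], d[2])))
}

# flatten H x W x C -> (H*W) x C matrix (column-major over H then W)
tn_flatten_hw <- function(x) {
  d <- dim(x$value)
  v <- x$value; dim(v) <- c(d[1] * d[2], d[3])
  new_node(v, list(x), function(g) { dim(g) <- d; list(g) })
}

# fixed linear map of a flattened map: basis (1 x HW) %*% flat (HW x C) -> 1 x C
# (used for DCT spectral components; basis is constant)
tn_basis_project <- function(xflat, basis) {
  new_node(basis %*% xflat$value, list(xflat), function(g)
    list(t(basis) %*% g))
}

# Reshape a head output map H x W x (A*d) into an anchor-major matrix
# (H*W*A) x d. Channel layout: slice (a-1)*d + j is feature j of anchor slot a.
# Row ordering matches the anchor grid: spatial position p = (x-1)*H + y
# (column-major), anchor slot fastest within a position.
tn_head_reshape <- function(x, A, d) {
  dm <- dim(x$value)
  H <- dm[1]; W <- dm[2]
  stopifnot(dm[3] == A * d)
  arr <- array(x$value, dim = c(H * W, d, A))  # arr[p, j, a] = x[p, (a-1)*d + j]
  out <- matrix(0, H * W * A, d)
  for (a in seq_len(A))
    out[seq.int(a, by = A, length.out = H * W), ] <- arr[, , a]
  new_node(out, list(x), function(g) {
    garr <- array(0, dim = c(H * W, d, A))
    for (a in seq_len(A))
      garr[, , a] <- g[seq.int(a, by = A, length.out = H * W), ]
    dim(garr) <- c(H, W, A * d)
    list(garr)
  })
}

# gather channels by index (with repetition): out[,,j] = x[,,idx[j]]
tn_channel_gather <- function(x, idx) {
  d <- dim(x$value)
  new_node(x$value[, , idx, drop = FALSE], list(x), function(g) {
    gx <- array(0, dim = d)
    for (j in seq_along(idx))
      gx[, , idx[j]] <- gx[, , idx[j]] + g[, , j]
    list(gx)
  })
}

# stack a list of matrices by rows (for multi-level head outputs)
tn_rbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  nr <- vapply(vals, nrow, numeric(1))
  ends <- cumsum(nr); starts <- ends - nr + 1
  new_node(do.call(rbind, vals), nodes, function(g)
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE]))
}
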
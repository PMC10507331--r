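# Reverse-mode tape: every differentiable op agrees with central finite
# differences on small random inputs.

sum_sq_loss <- function(node) {
  wbcseg:::tn_sum(wbcseg:::new_node(node$value^2, list(node),
                                    function(g) list(2 * g * node$value)))
}

test_that("convolution forward matches a naive loop and gradients match finite differences", {
  set.seed(41)
  cv <- wbcseg:::layer_conv2d(4L, 6L, 3L, stride = 2L, pad = 1L, groups = 2L,
                              bias = TRUE)
  x <- array(rnorm(5 * 7 * 4), c(5, 7, 4))

  # naive forward oracle
  w <- cv$params$w$value; b <- cv$params$b$value
  naive <- array(0, c(3, 4, 6))
  for (oc in 1:6) {
    g <- (oc - 1) %/% 3  # group of this output channel (2 groups x 3)
    for (oy in 1:3) for (ox in 1:4) {
      acc <- b[oc]
      for (dy in 0:2) for (dx in 0:2) for (ci in 1:2) {
        iy <- (oy - 1) * 2 - 1 + dy + 1
        ix <- (ox - 1) * 2 - 1 + dx + 1
        if (iy >= 1 && iy <= 5 && ix >= 1 && ix <= 7) {
          row <- (dy * 3 + dx) * 2 + ci
          acc <- acc + x[iy, ix, g * 2 + ci] * w[row, oc]
        }
      }
      naive[oy, ox, oc] <- acc
    }
  }
  out <- cv$forward(wbcseg:::tn_const(x))
  expect_equal(out$value, naive, tolerance = 1e-10)

  xn <- wbcseg:::tn_const(x)
  wbcseg:::zero_grads(cv$params)
  wbcseg:::tape_backward(sum_sq_loss(cv$forward(xn)))
  f_x <- function(v) sum(cv$forward(wbcseg:::tn_const(array(v, dim(x))))$value^2)
  expect_equal(xn$grad, array(num_grad(f_x, as.vector(x)), dim(x)),
               tolerance = 1e-6)
  f_w <- function(v) {
    old <- cv$params$w$value
    cv$params$w$value <- matrix(v, nrow(old))
    on.exit(cv$params$w$value <- old)
    sum(cv$forward(wbcseg:::tn_const(x))$value^2)
  }
  expect_equal(cv$params$w$grad,
               matrix(num_grad(f_w, as.vector(cv$params$w$value)),
                      nrow(cv$params$w$value)),
               tolerance = 1e-6)
})

test_that("normalization, pooling, resize and reduction ops are exact gradients", {
  set.seed(42)
  checks <- list(
    bn = {
      bn <- wbcseg:::layer_batchnorm2d(3L)
      bn$params$gamma$value <- runif(3, 0.5, 1.5)
      list(dims = c(4, 4, 3), fwd = function(n) bn$forward(n, train = TRUE))
    },
    maxpool = {
      mp <- wbcseg:::layer_maxpool2d(3L, 2L, 1L)
      list(dims = c(6, 6, 2), fwd = function(n) mp$forward(n))
    },
    upsample = list(dims = c(3, 4, 2),
                    fwd = function(n) wbcseg:::tn_upsample(n, c(7, 9))),
    gap = list(dims = c(3, 5, 4), fwd = wbcseg:::tn_gap),
    gmp = list(dims = c(3, 5, 4), fwd = wbcseg:::tn_gmp),
    channel_mean = list(dims = c(4, 3, 5), fwd = wbcseg:::tn_channel_mean),
    channel_max = list(dims = c(4, 3, 5), fwd = wbcseg:::tn_channel_max),
    sigmoid = list(dims = c(3, 3, 2), fwd = wbcseg:::tn_sigmoid),
    tanh = list(dims = c(3, 3, 2), fwd = wbcseg:::tn_tanh),
    head_reshape = list(dims = c(2, 3, 6),
                        fwd = function(n) wbcseg:::tn_head_reshape(n, 2L, 3L)),
    gather = list(dims = c(3, 3, 4),
                  fwd = function(n) wbcseg:::tn_channel_gather(n, c(1L, 2L, 1L, 4L, 2L)))
  )
  # random-weighted linear loss: well-conditioned for every op (including
  # normalization, whose sum-of-squares gradient vanishes by scale invariance)
  for (nm in names(checks)) {
    ck <- checks[[nm]]
    x <- array(rnorm(prod(ck$dims)), ck$dims)
    probe <- ck$fwd(wbcseg:::tn_const(x))
    pd <- if (is.null(dim(probe$value))) length(probe$value) else dim(probe$value)
    w <- array(rnorm(length(probe$value)), pd)
    wl_loss <- function(node) wbcseg:::new_node(sum(node$value * w), list(node),
                                                function(g) list(g * w))
    xn <- wbcseg:::tn_const(x)
    wbcseg:::tape_backward(wl_loss(ck$fwd(xn)))
    f <- function(v) sum(ck$fwd(wbcseg:::tn_const(array(v, ck$dims)))$value * w)
    expect_equal(xn$grad, array(num_grad(f, as.vector(x)), ck$dims),
                 tolerance = 1e-5, label = nm)
  }
})

test_that("terminal loss nodes carry analytic gradients matching finite differences", {
  set.seed(43)
  # softmax CE
  logits <- matrix(rnorm(12), 6, 2)
  rows <- c(1L, 3L, 5L); labels <- c(1L, 0L, 1L)
  ln <- wbcseg:::tn_const(logits)
  node <- wbcseg:::softmax_ce_node(ln, rows, labels, 3)
  # hand value: mean over rows of log-sum-exp minus picked logit
  hand <- mean(sapply(seq_along(rows), function(i) {
    r <- logits[rows[i], ]
    log(sum(exp(r))) - r[labels[i] + 1]
  }))
  expect_equal(node$value, hand, tolerance = 1e-12)
  wbcseg:::tape_backward(node)
  f <- function(v) {
    m <- matrix(v, 6, 2)
    mean(sapply(seq_along(rows), function(i) {
      r <- m[rows[i], ]
      log(sum(exp(r))) - r[labels[i] + 1]
    }))
  }
  expect_equal(ln$grad, matrix(num_grad(f, as.vector(logits)), 6, 2),
               tolerance = 1e-6)

  # smooth L1
  pred <- matrix(rnorm(8, sd = 2), 2, 4)
  tgt <- matrix(rnorm(4), 1, 4)
  pn <- wbcseg:::tn_const(pred)
  node <- wbcseg:::smooth_l1_node(pn, 2L, tgt, 1)
  wbcseg:::tape_backward(node)
  f <- function(v) {
    d <- matrix(v, 2, 4)[2, ] - tgt
    sum(ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5))
  }
  expect_equal(pn$grad, matrix(num_grad(f, as.vector(pred)), 2, 4),
               tolerance = 1e-6)

  # BCE with logits
  lg <- matrix(rnorm(10), 5, 2)
  tg <- matrix(rbinom(10, 1, 0.5), 5, 2)
  wt <- matrix(runif(10), 5, 2)
  lgn <- wbcseg:::tn_const(lg)
  node <- wbcseg:::bce_logits_node(lgn, tg, wt, 2)
  wbcseg:::tape_backward(node)
  f <- function(v) {
    p <- 1 / (1 + exp(-matrix(v, 5, 2)))
    -sum(wt * (tg * log(p + 1e-7) + (1 - tg) * log(1 - p + 1e-7))) / 2
  }
  expect_equal(lgn$grad, matrix(num_grad(f, as.vector(lg)), 5, 2),
               tolerance = 1e-5)
})

test_that("gradients accumulate across repeated backward passes", {
  set.seed(44)
  fc <- wbcseg:::layer_linear(3L, 2L)
  x <- matrix(rnorm(3), 1, 3)
  wbcseg:::zero_grads(fc$params)
  wbcseg:::tape_backward(sum_sq_loss(fc$forward(wbcseg:::tn_const(x))))
  g1 <- fc$params$w$grad
  wbcseg:::tape_backward(sum_sq_loss(fc$forward(wbcseg:::tn_const(x))))
  expect_equal(fc$params$w$grad, 2 * g1, tolerance = 1e-12)
})
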
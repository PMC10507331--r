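# Frequency-domain channel attention and spatial attention.

test_that("DCT components match the brute-force double sum and the GAP identity", {
  set.seed(30)
  # brute-force oracle over all (h, w) on random 5x7 channels
  f <- array(rnorm(5 * 7 * 3), c(5, 7, 3))
  for (h in 0:4) for (w in 0:6) {
    got <- dct_component(f, h, w)
    want <- vapply(1:3, function(c) brute_dct(f[, , c], h, w), numeric(1))
    expect_equal(got, want, tolerance = 1e-6)
  }

  # constant channel: Y00 = H*W*c, all other components vanish
  const <- array(rep(c(2, -1.5), each = 16), c(4, 4, 2))
  expect_equal(dct_component(const, 0L, 0L), c(32, -24), tolerance = 1e-10)
  for (h in 0:3) for (w in 0:3) {
    if (h == 0 && w == 0) next
    expect_equal(dct_component(const, h, w), c(0, 0), tolerance = 1e-9)
  }

  # GAP identity on 100 random maps
  for (i in 1:100) {
    H <- sample(2:8, 1); W <- sample(2:8, 1); C <- sample(1:4, 1)
    fm <- array(rnorm(H * W * C), c(H, W, C))
    gap <- apply(fm, 3, mean)
    expect_equal(dct_component(fm, 0L, 0L), H * W * gap, tolerance = 1e-5)
  }

  expect_error(dct_component(f, 5L, 0L), "out of range")
  expect_error(dct_component(f, 0L, -1L), "out of range")
})

test_that("channel weights follow the shared-MLP formula and stay inside (0,1)", {
  set.seed(31)
  # zero MLP -> sigmoid(0) = 0.5 for every channel
  fc0 <- wbcseg:::with_zero_init(build_fcam(8L, r = 4L))
  f <- wbcseg:::tn_const(array(rnorm(6 * 6 * 8), c(6, 6, 8)))
  w0 <- fcam_weights(fc0, f)
  expect_equal(as.numeric(w0$value), rep(0.5, 8))

  # C=2, H=W=1 toy with hand-set weights: evaluate the formula by hand
  fc <- build_fcam(2L, r = 1L, components = list(c(0L, 0L)))
  fc$layers$fc1$params$w$value <- matrix(c(1, 0, 0.5, -1), 2, 2)   # C -> C
  fc$layers$fc2$params$w$value <- matrix(c(0.3, -0.2, 1, 0.4), 2, 2)
  x <- array(c(1.2, -0.7), c(1, 1, 2))
  y00 <- c(1.2, -0.7)                       # H=W=1: component = value
  hidden <- pmax(0, y00 %*% fc$layers$fc1$params$w$value)
  hand <- 1 / (1 + exp(-(hidden %*% fc$layers$fc2$params$w$value)))
  got <- fcam_weights(fc, wbcseg:::tn_const(x))
  expect_equal(as.numeric(got$value), as.numeric(hand), tolerance = 1e-12)

  # random weights: strictly inside (0,1)
  set.seed(32)
  fcr <- build_fcam(16L, r = 4L)
  wr <- fcam_weights(fcr, wbcseg:::tn_const(array(rnorm(5 * 5 * 16), c(5, 5, 16))))
  expect_true(all(wr$value > 0 & wr$value < 1))
})

test_that("spatial attention matches a hand-rolled pooling + convolution oracle", {
  set.seed(33)
  sam <- build_spatial_attention(7L)
  f <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  got <- spatial_attention(sam, wbcseg:::tn_const(f))
  # oracle: explicit mean/max pooling, loop convolution, sigmoid
  mean_m <- apply(f, c(1, 2), mean)
  max_m <- apply(f, c(1, 2), max)
  w <- sam$layers$conv$params$w$value  # (7*7*2) x 1, rows (dy, dx, channel)
  b <- sam$layers$conv$params$b$value
  oracle <- matrix(0, 5, 5)
  for (oy in 1:5) for (ox in 1:5) {
    acc <- b
    for (dy in 0:6) for (dx in 0:6) {
      iy <- oy - 3 + dy; ix <- ox - 3 + dx
      if (iy >= 1 && iy <= 5 && ix >= 1 && ix <= 5) {
        row <- (dy * 7 + dx) * 2
        acc <- acc + mean_m[iy, ix] * w[row + 1, 1] + max_m[iy, ix] * w[row + 2, 1]
      }
    }
    oracle[oy, ox] <- 1 / (1 + exp(-acc))
  }
  expect_equal(got$value[, , 1], oracle, tolerance = 1e-10)

  # zero conv weights -> 0.5 everywhere
  sam0 <- wbcseg:::with_zero_init(build_spatial_attention(7L))
  g0 <- spatial_attention(sam0, wbcseg:::tn_const(f))
  expect_equal(as.vector(g0$value), rep(0.5, 25))

  # spatially constant input -> constant attention on interior pixels
  fc <- array(rep(rnorm(3), each = 81), c(9, 9, 3))
  gi <- spatial_attention(sam, wbcseg:::tn_const(fc))$value[4:6, 4:6, 1]
  expect_lt(diff(range(gi)), 1e-12)
})

test_that("dual-domain attention preserves shape and applies channel before spatial masking", {
  set.seed(34)
  dd <- build_ddam(8L, r = 4L)
  f <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  fn <- wbcseg:::tn_const(f)
  out <- ddam_forward(dd, fn)
  expect_equal(dim(out$value), dim(f))

  # channel-then-spatial differs from spatial-then-channel (regression lock)
  mf <- fcam_weights(dd$layers$fcam, fn)
  f1 <- wbcseg:::tn_mul_channel(fn, wbcseg:::new_node(as.numeric(mf$value)))
  ms <- spatial_attention(dd$layers$sam, f1)
  expected <- f1$value * array(ms$value, dim = dim(f))
  expect_equal(out$value, expected, tolerance = 1e-12)

  ms_first <- spatial_attention(dd$layers$sam, fn)
  swapped <- (f * array(ms_first$value, dim = dim(f)))
  swapped <- swapped * aperm(array(as.numeric(mf$value), c(8, 6, 6)), c(2, 3, 1))
  expect_gt(max(abs(out$value - swapped)), 1e-6)
})

test_that("attention config reaches all five ablation variants", {
  set.seed(35)
  f <- wbcseg:::tn_const(array(rnorm(6 * 6 * 8), c(6, 6, 8)))
  variants <- list(
    cbam = build_attention("cbam", 8L, r = 4L),
    y00 = build_attention("fcam_sam", 8L, r = 4L, components = list(c(0L, 0L))),
    y00_y01 = build_attention("fcam_sam", 8L, r = 4L,
                              components = list(c(0L, 0L), c(0L, 1L))),
    default3 = build_attention("fcam_sam", 8L, r = 4L),
    plus_y11 = build_attention("fcam_sam", 8L, r = 4L,
                               components = list(c(0L, 0L), c(0L, 1L),
                                                 c(1L, 0L), c(1L, 1L))))
  outs <- lapply(variants, function(v) ddam_forward(v, f)$value)
  # all distinct as functions (pairwise different outputs on a random input)
  for (i in 1:(length(outs) - 1)) for (j in (i + 1):length(outs))
    expect_gt(max(abs(outs[[i]] - outs[[j]])), 1e-8)
  expect_null(build_attention("none", 8L))
  expect_error(build_attention("nope", 8L), "unknown")
})
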
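# Core layer stack: forward correctness against naive oracles and reverse
# mode against finite differences.

test_that("conv2d matches a triple-loop convolution oracle", {
  set.seed(7)
  for (case in list(list(k = 3, s = 1, p = 1), list(k = 3, s = 2, p = 1),
                    list(k = 1, s = 1, p = 0), list(k = 5, s = 2, p = 2))) {
    x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
    mod <- nn_conv2d(3, 4, case$k, stride = case$s, pad = case$p)
    y <- nn_forward(mod, x)
    yo <- naive_conv2d(x, mod$params$w, mod$params$b, case$s, case$p)
    expect_equal(y, yo, tolerance = 1e-12)
  }
})

test_that("depthwise convolution equals per-channel dense convolution", {
  set.seed(8)
  x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  mod <- nn_conv2d(4, 4, 3, stride = 1, pad = 1, groups = 4)
  y <- nn_forward(mod, x)
  for (c in 1:4) {
    w1 <- array(mod$params$w[, , c], c(3, 3, 1, 1))
    yo <- naive_conv2d(x[, , c, , drop = FALSE], w1, mod$params$b[c], 1, 1)
    expect_equal(y[, , c, , drop = FALSE], yo, tolerance = 1e-12)
  }
})

test_that("max pooling picks window maxima and routes gradients to argmax", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(1:16, 4, 4)
  mod <- nn_maxpool2d(2, 2)
  y <- nn_forward(mod, x)
  expect_equal(as.vector(y), c(6, 8, 14, 16))
  g <- nn_backward(mod, array(1, c(2, 2, 1, 1)))
  expect_equal(sum(g), 4)
  expect_equal(which(g != 0), c(6L, 8L, 14L, 16L))
})

test_that("reverse mode matches finite differences across the layer stack", {
  set.seed(11)
  expect_gradcheck(nn_conv2d(3, 4, 3, stride = 2, pad = 1), c(7, 7, 3, 2))
  expect_gradcheck(nn_conv2d(4, 4, 3, pad = 1, groups = 4), c(6, 6, 4, 2))
  expect_gradcheck(nn_batchnorm2d(3), c(4, 4, 3, 3))
  expect_gradcheck(nn_maxpool2d(3, 2, ceil = TRUE), c(7, 7, 2, 2))
  expect_gradcheck(nn_linear(6, 4), c(3, 6))
  expect_gradcheck(nn_se(4, 2), c(5, 5, 4, 2))
  expect_gradcheck(nn_gelu(), c(3, 8))
  expect_gradcheck(thanet:::resnet_basic_block(4, 8, 2), c(8, 8, 4, 2))
})

test_that("batch norm normalises batch statistics and tracks running stats", {
  set.seed(12)
  x <- array(rnorm(6 * 6 * 3 * 4, mean = 2, sd = 3), c(6, 6, 3, 4))
  mod <- nn_batchnorm2d(3)
  y <- nn_forward(mod, x)
  m <- aperm(y, c(1, 2, 4, 3)); dim(m) <- c(6 * 6 * 4, 3)
  expect_equal(colMeans(m), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(m, 2, sd), rep(1, 3), tolerance = 1e-2)
  # eval mode uses running statistics, not batch statistics
  thanet:::nn_train_mode(mod, FALSE)
  y2 <- nn_forward(mod, x[, , , 1, drop = FALSE])
  expect_true(is.finite(sum(y2)))
})

test_that("sequential/residual containers compose forward and backward", {
  set.seed(13)
  mod <- nn_sequential(nn_conv2d(2, 3, 3, pad = 1), nn_batchnorm2d(3),
                       nn_relu())
  expect_gradcheck(mod, c(5, 5, 2, 2))
  res <- nn_residual(nn_sequential(nn_conv2d(3, 3, 3, pad = 1),
                                   nn_batchnorm2d(3)))
  expect_gradcheck(res, c(5, 5, 3, 2))
})

test_that("checkpoint state round-trips bit-exactly", {
  set.seed(14)
  mod <- nn_sequential(nn_conv2d(3, 4, 3, pad = 1), nn_batchnorm2d(4),
                       nn_relu(), nn_gap(), nn_linear(4, 2))
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  thanet:::nn_train_mode(mod, FALSE)
  y1 <- nn_forward(mod, x)
  st <- thanet:::nn_state(mod)
  set.seed(99)
  mod2 <- nn_sequential(nn_conv2d(3, 4, 3, pad = 1), nn_batchnorm2d(4),
                        nn_relu(), nn_gap(), nn_linear(4, 2))
  thanet:::nn_load_state(mod2, st)
  thanet:::nn_train_mode(mod2, FALSE)
  expect_identical(nn_forward(mod2, x), y1)
})
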
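# Global feature stream: patch partition, attention core, window machinery,
# block composition.

test_that("patch partition produces the expected token grids with padding", {
  set.seed(20)
  pe <- nn_patch_embed(4, 3, 8)
  x <- array(rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  y <- nn_forward(pe, x)
  expect_equal(attr(y, "grid"), c(56, 56))
  expect_equal(dim(y), c(56 * 56, 8, 1))
  x2 <- array(rnorm(225 * 225 * 3), c(225, 225, 3, 1))
  y2 <- nn_forward(pe, x2)
  expect_equal(attr(y2, "grid"), c(57, 57))
  expect_error(nn_patch_embed(0, 3, 8), "positive")
})

test_that("post-partition tokens are layer-normalised per token", {
  set.seed(21)
  pe <- nn_patch_embed(4, 3, 16)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 2))
  y <- nn_forward(pe, x)
  mu <- apply(y, c(1, 3), mean)
  v <- apply(y, c(1, 3), function(t) mean((t - mean(t))^2))
  expect_lt(max(abs(mu)), 1e-10)
  expect_equal(v, array(1, dim(v)), tolerance = 1e-4)
})

test_that("attention core: single token returns V, rows sum to one", {
  r <- msa(matrix(0.3), matrix(1.2), matrix(5), d_k = 1)
  expect_equal(r$out, matrix(5))
  expect_equal(r$attn, matrix(1))
  set.seed(22)
  for (n in c(2, 5, 9)) {
    Q <- matrix(rnorm(n * 4), n); K <- matrix(rnorm(n * 4), n)
    V <- matrix(rnorm(n * 3), n)
    r <- msa(Q, K, V)
    expect_equal(rowSums(r$attn), rep(1, n), tolerance = 1e-6)
  }
  expect_error(msa(matrix(1, 2, 3), matrix(1, 2, 2), matrix(1, 2, 2)),
               "disagree")
})

test_that("attention core reproduces scalar arithmetic on two tokens", {
  # Q = K = (1, 0)', V = (1, 2)', d_k = 1
  Q <- matrix(c(1, 0)); K <- Q; V <- matrix(c(1, 2))
  r <- msa(Q, K, V, d_k = 1)
  w11 <- exp(1) / (exp(1) + exp(0))
  expect_equal(r$out[1, 1], w11 * 1 + (1 - w11) * 2, tolerance = 1e-12)
  expect_equal(r$out[2, 1], 0.5 * 1 + 0.5 * 2, tolerance = 1e-12)
})

test_that("window partition is a bijection, shifted and unshifted", {
  idx <- window_index(8, 8, 4)
  expect_equal(dim(idx), c(16, 4))
  expect_equal(sort(as.vector(idx)), 1:64)       # each token exactly once
  expect_equal(dim(window_index(7, 7, 7)), c(49, 1))
  set.seed(23)
  for (case in list(c(8, 8, 4), c(6, 9, 3), c(4, 4, 2))) {
    x <- array(rnorm(case[1] * case[2] * 5 * 2), c(case[1] * case[2], 5, 2))
    attr(x, "grid") <- case[1:2]
    xw <- window_partition(x, case[3])
    xb <- window_unpartition(xw)
    expect_equal(xb, x, ignore_attr = TRUE)
    # shifted: cyclic shift then partition then inverse recovers original
    s <- case[3] %/% 2
    xs <- thanet:::shift_tokens(x, s)
    back <- thanet:::shift_tokens(window_unpartition(window_partition(xs, case[3])), -s)
    expect_equal(back, x, ignore_attr = TRUE)
    # index-enumeration oracle: token (i,j) lands in window (ceil(i/ws), ceil(j/ws))
    idx <- window_index(case[1], case[2], case[3])
    for (t in sample(case[1] * case[2], 5)) {
      i <- (t - 1) %% case[1] + 1
      j <- (t - 1) %/% case[1] + 1
      win <- which(apply(idx, 2, function(col) t %in% col))
      expected <- (ceiling(j / case[3]) - 1) * (case[1] / case[3]) +
        ceiling(i / case[3])
      expect_equal(win, expected)
    }
  }
})

test_that("windowed attention is equivariant under whole-window permutation", {
  set.seed(24)
  att <- nn_window_attention(8, 2, 2, shifted = FALSE)
  x <- array(rnorm(16 * 8 * 1), c(16, 8, 1))
  attr(x, "grid") <- c(4, 4)
  y <- nn_forward(att, x)
  idx <- window_index(4, 4, 2)
  perm <- c(3, 1, 4, 2)                           # permute the 4 windows
  xp <- x
  for (w in 1:4) xp[idx[, w], , ] <- x[idx[, perm[w]], , ]
  attr(xp, "grid") <- c(4, 4)
  yp <- nn_forward(att, xp)
  for (w in 1:4) {
    expect_equal(yp[idx[, w], , , drop = FALSE],
                 y[idx[, perm[w]], , , drop = FALSE], tolerance = 1e-12)
  }
})

test_that("shifted attention masks wrap-around pairs", {
  mask <- thanet:::shift_attn_mask(8, 8, 4, 2)
  expect_equal(dim(mask), c(16, 16, 4))
  expect_true(all(mask[, , 1] == 0))              # interior window: no mask
  expect_true(any(mask[, , 4] < 0))               # wrapped corner window
  expect_gradcheck(nn_window_attention(8, 2, 2, shifted = TRUE),
                   c(16, 8, 2), grid = c(4, 4))
})

test_that("global feature blocks halve the grid and double the embedding", {
  set.seed(25)
  blk <- global_feature_block(4, 2, 4)
  x <- array(rnorm(64 * 4 * 2), c(64, 4, 2))
  attr(x, "grid") <- c(8, 8)
  y <- nn_forward(blk, x)
  expect_equal(attr(y, "grid"), c(4, 4))
  expect_equal(dim(y), c(16, 8, 2))
  expect_true(all(is.finite(y)))
  expect_error(nn_forward(nn_patch_merge(4), {
    z <- array(rnorm(3 * 4 * 1), c(3, 4, 1)); attr(z, "grid") <- c(3, 1); z
  }), "merged")
})

test_that("zeroed attention and MLP reduce a block to patch merging", {
  set.seed(26)
  blk <- global_feature_block(4, 2, 4)
  # zero the attention projection and the second MLP linear + biases
  att <- blk$children$m02$children$main$children$m02
  att$params$wproj[] <- 0; att$params$bproj[] <- 0
  mlp2 <- blk$children$m03$children$main$children$m02$children$m03
  mlp2$params$w[] <- 0; mlp2$params$b[] <- 0
  x <- array(rnorm(64 * 4 * 2), c(64, 4, 2))
  attr(x, "grid") <- c(8, 8)
  y <- nn_forward(blk, x)
  ym <- nn_forward(blk$children$m01, x)           # the merge sub-module alone
  expect_equal(y, ym, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("three stacked blocks map 56x56x96-style grids to 7x7x8C maps", {
  set.seed(27)
  gfs <- build_gfs(patch = 4, embed = 8, window = 7, heads = c(2, 2, 2))
  x <- array(rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  y <- nn_forward(gfs, x)
  expect_equal(dim(y), c(7, 7, 64, 1))
  # tiny scale: 64 px with window 4 lands on 2x2
  gfs2 <- build_gfs(patch = 4, embed = 8, window = 4, heads = c(2, 2, 2))
  y2 <- nn_forward(gfs2, array(rnorm(64 * 64 * 3), c(64, 64, 3, 1)))
  expect_equal(dim(y2), c(2, 2, 64, 1))
})
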
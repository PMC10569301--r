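# Low-level tensor primitives.
#
# Feature maps are dense double arrays with dim c(H, W, C, N): column-major,
# so H varies fastest. Convolutions are lowered to a single BLAS matrix
# product via im2col; backward passes reuse the cached im2col matrix
# (gradient wrt weights) and scatter-add the column gradient back to the
# input (gradient wrt input).

pad_hw <- function(x, pad, value = 0) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

conv_out_dim <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1

# Dense 2-D convolution, groups == 1.
# x: (H, W, Cin, N); w: (kh, kw, Cin, Cout); b: NULL or length Cout.
conv2d_fwd <- function(x, w, b, stride, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  stopifnot(dim(w)[3] == Cin)
  xp <- pad_hw(x, pad)
  Ho <- conv_out_dim(H, kh, stride, pad)
  Wo <- conv_out_dim(W, kw, stride, pad)
  hs <- seq.int(1L, by = stride, length.out = Ho)
  ws <- seq.int(1L, by = stride, length.out = Wo)
  K <- kh * kw * Cin
  cols <- array(0, c(Ho * Wo, N, K))
  off <- 0L
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      sl <- xp[hs + (ki - 1L), ws + (kj - 1L), , , drop = FALSE]
      sl <- aperm(sl, c(1L, 2L, 4L, 3L))          # Ho, Wo, N, Cin
      cols[, , off + seq_len(Cin)] <- sl
      off <- off + Cin
    }
  }
  dim(cols) <- c(Ho * Wo * N, K)
  # K-order is (channel fastest, then ki, then kj): match with aperm of w.
  wm <- matrix(aperm(w, c(3L, 1L, 2L, 4L)), K, Cout)
  y <- cols %*% wm
  if (!is.null(b)) y <- y + rep(b, each = Ho * Wo * N)
  dim(y) <- c(Ho, Wo, N, Cout)
  list(y = aperm(y, c(1L, 2L, 4L, 3L)), cols = cols,
       geom = list(H = H, W = W, Cin = Cin, N = N, Ho = Ho, Wo = Wo,
                   kh = kh, kw = kw, stride = stride, pad = pad))
}

conv2d_bwd <- function(gy, w, cache) {
  g <- cache$geom
  Cout <- dim(w)[4]
  gym <- aperm(gy, c(1L, 2L, 4L, 3L))             # Ho, Wo, N, Cout
  dim(gym) <- c(g$Ho * g$Wo * g$N, Cout)
  K <- g$kh * g$kw * g$Cin
  wm <- matrix(aperm(w, c(3L, 1L, 2L, 4L)), K, Cout)
  gw <- crossprod(cache$cols, gym)                # K x Cout
  gw <- array(gw, c(g$Cin, g$kh, g$kw, Cout))
  gw <- aperm(gw, c(2L, 3L, 1L, 4L))
  gb <- colSums(gym)
  gcols <- gym %*% t(wm)
  dim(gcols) <- c(g$Ho * g$Wo, g$N, K)
  Hp <- g$H + 2 * g$pad; Wp <- g$W + 2 * g$pad
  gxp <- array(0, c(Hp, Wp, g$Cin, g$N))
  hs <- seq.int(1L, by = g$stride, length.out = g$Ho)
  ws <- seq.int(1L, by = g$stride, length.out = g$Wo)
  off <- 0L
  for (kj in seq_len(g$kw)) {
    for (ki in seq_len(g$kh)) {
      blk <- gcols[, , off + seq_len(g$Cin), drop = FALSE]
      dim(blk) <- c(g$Ho, g$Wo, g$N, g$Cin)
      blk <- aperm(blk, c(1L, 2L, 4L, 3L))
      hi <- hs + (ki - 1L); wi <- ws + (kj - 1L)
      gxp[hi, wi, , ] <- gxp[hi, wi, , , drop = FALSE] + blk
      off <- off + g$Cin
    }
  }
  gx <- if (g$pad > 0) {
    gxp[g$pad + seq_len(g$H), g$pad + seq_len(g$W), , , drop = FALSE]
  } else gxp
  list(gx = gx, gw = gw, gb = gb)
}

# Depthwise convolution (groups == Cin == Cout); w: (kh, kw, C).
dwconv_fwd <- function(x, w, b, stride, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]
  xp <- pad_hw(x, pad)
  Ho <- conv_out_dim(H, kh, stride, pad)
  Wo <- conv_out_dim(W, kw, stride, pad)
  hs <- seq.int(1L, by = stride, length.out = Ho)
  ws <- seq.int(1L, by = stride, length.out = Wo)
  y <- array(0, c(Ho, Wo, C, N))
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      sl <- xp[hs + (ki - 1L), ws + (kj - 1L), , , drop = FALSE]
      wv <- rep(w[ki, kj, ], each = Ho * Wo)       # recycles over N
      y <- y + sl * wv
    }
  }
  if (!is.null(b)) y <- y + rep(b, each = Ho * Wo)
  list(y = y, xp = xp,
       geom = list(H = H, W = W, C = C, N = N, Ho = Ho, Wo = Wo,
                   kh = kh, kw = kw, stride = stride, pad = pad))
}

dwconv_bwd <- function(gy, w, cache) {
  g <- cache$geom
  hs <- seq.int(1L, by = g$stride, length.out = g$Ho)
  ws <- seq.int(1L, by = g$stride, length.out = g$Wo)
  gw <- array(0, dim(w))
  gxp <- array(0, dim(cache$xp))
  for (kj in seq_len(g$kw)) {
    for (ki in seq_len(g$kh)) {
      hi <- hs + (ki - 1L); wi <- ws + (kj - 1L)
      sl <- cache$xp[hi, wi, , , drop = FALSE]
      prod <- sl * gy
      dim(prod) <- c(g$Ho * g$Wo, g$C, g$N)
      gw[ki, kj, ] <- rowSums(colSums(prod))
      wv <- rep(w[ki, kj, ], each = g$Ho * g$Wo)
      gxp[hi, wi, , ] <- gxp[hi, wi, , , drop = FALSE] + gy * wv
    }
  }
  gb <- {
    gm <- gy; dim(gm) <- c(g$Ho * g$Wo, g$C, g$N); rowSums(colSums(gm))
  }
  gx <- if (g$pad > 0) {
    gxp[g$pad + seq_len(g$H), g$pad + seq_len(g$W), , , drop = FALSE]
  } else gxp
  list(gx = gx, gw = gw, gb = gb)
}

maxpool_fwd <- function(x, k, stride, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- pad_hw(x, pad, value = -Inf)
  Ho <- conv_out_dim(H, k, stride, pad)
  Wo <- conv_out_dim(W, k, stride, pad)
  hs <- seq.int(1L, by = stride, length.out = Ho)
  ws <- seq.int(1L, by = stride, length.out = Wo)
  best <- array(-Inf, c(Ho, Wo, C, N))
  argk <- array(0L, c(Ho, Wo, C, N))
  o <- 0L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      o <- o + 1L
      sl <- xp[hs + (ki - 1L), ws + (kj - 1L), , , drop = FALSE]
      upd <- sl > best
      best[upd] <- sl[upd]
      argk[upd] <- o
    }
  }
  list(y = best, argk = argk,
       geom = list(H = H, W = W, C = C, N = N, Ho = Ho, Wo = Wo, k = k,
                   stride = stride, pad = pad))
}

maxpool_bwd <- function(gy, cache) {
  g <- cache$geom
  Hp <- g$H + 2 * g$pad; Wp <- g$W + 2 * g$pad
  gxp <- array(0, c(Hp, Wp, g$C, g$N))
  hs <- seq.int(1L, by = g$stride, length.out = g$Ho)
  ws <- seq.int(1L, by = g$stride, length.out = g$Wo)
  o <- 0L
  for (kj in seq_len(g$k)) {
    for (ki in seq_len(g$k)) {
      o <- o + 1L
      mask <- (cache$argk == o) * gy
      hi <- hs + (ki - 1L); wi <- ws + (kj - 1L)
      gxp[hi, wi, , ] <- gxp[hi, wi, , , drop = FALSE] + mask
    }
  }
  if (g$pad > 0) {
    gxp[g$pad + seq_len(g$H), g$pad + seq_len(g$W), , , drop = FALSE]
  } else gxp
}

avgpool_fwd <- function(x, k, stride, pad = 0) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- pad_hw(x, pad)
  Ho <- conv_out_dim(H, k, stride, pad)
  Wo <- conv_out_dim(W, k, stride, pad)
  hs <- seq.int(1L, by = stride, length.out = Ho)
  ws <- seq.int(1L, by = stride, length.out = Wo)
  y <- array(0, c(Ho, Wo, C, N))
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      y <- y + xp[hs + (ki - 1L), ws + (kj - 1L), , , drop = FALSE]
    }
  }
  list(y = y / (k * k),
       geom = list(H = H, W = W, C = C, N = N, Ho = Ho, Wo = Wo, k = k,
                   stride = stride, pad = pad))
}

avgpool_bwd <- function(gy, cache) {
  g <- cache$geom
  Hp <- g$H + 2 * g$pad; Wp <- g$W + 2 * g$pad
  gxp <- array(0, c(Hp, Wp, g$C, g$N))
  hs <- seq.int(1L, by = g$stride, length.out = g$Ho)
  ws <- seq.int(1L, by = g$stride, length.out = g$Wo)
  gk <- gy / (g$k * g$k)
  for (kj in seq_len(g$k)) {
    for (ki in seq_len(g$k)) {
      hi <- hs + (ki - 1L); wi <- ws + (kj - 1L)
      gxp[hi, wi, , ] <- gxp[hi, wi, , , drop = FALSE] + gk
    }
  }
  if (g$pad > 0) {
    gxp[g$pad + seq_len(g$H), g$pad + seq_len(g$W), , , drop = FALSE]
  } else gxp
}

# Global average pool: (H, W, C, N) -> (N, C) matrix.
gap_fwd <- function(x) {
  d <- dim(x)
  m <- x; dim(m) <- c(d[1] * d[2], d[3] * d[4])
  y <- matrix(colMeans(m), d[3], d[4])
  list(y = t(y), geom = d)
}

gap_bwd <- function(gy, geom) {
  HW <- geom[1] * geom[2]
  gx <- rep(t(gy) / HW, each = HW)                 # (C, N) spread over H*W
  dim(gx) <- geom
  gx
}
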
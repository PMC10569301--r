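# Global feature stream (GFS).
#
# The image is cut into non-overlapping patches by a strided convolution,
# flattened to a token grid and layer-normalised; three successive global
# feature blocks then each apply patch merging (2x2 concat + linear, halving
# the grid and doubling the embedding) followed by two residual sublayers:
# layer-norm + windowed multi-head self-attention (plain or shifted windows,
# alternating across blocks) and layer-norm + linear/GELU/linear.
#
# Token arrays have dim c(L, C, N) with a `grid = c(Hg, Wg)` attribute;
# token index is column-major over the grid (row fastest).

token_grid <- function(x) {
  g <- attr(x, "grid", exact = TRUE)
  if (is.null(g)) stop_thanet("token array lacks a grid attribute")
  g
}

set_grid <- function(x, g) { attr(x, "grid") <- g; x }

#' Scaled dot-product multi-head attention core
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` for a single attention group.
#'
#' @param Q,K,V Matrices with one row per token; `Q` and `K` share column
#'   count `d_k`, `K` and `V` share row count.
#' @param d_k Key dimension used in the temperature (defaults to `ncol(K)`).
#' @param mask Optional additive logit mask (`nrow(Q) x nrow(K)`).
#' @return List with `out` (attended values) and `attn` (row-stochastic
#'   attention weights).
#' @export
msa <- function(Q, K, V, d_k = ncol(K), mask = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop_thanet("Q and K disagree in key dimension")
  if (nrow(K) != nrow(V)) stop_thanet("K and V disagree in token count")
  if (d_k <= 0) stop_thanet("d_k must be positive")
  logits <- tcrossprod(Q, K) / sqrt(d_k)
  if (!is.null(mask)) logits <- logits + mask
  A <- softmax_rows(logits)
  list(out = A %*% V, attn = A)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Window partition of a token grid
#'
#' Splits an `Hg x Wg` token grid into non-overlapping `ws x ws` windows.
#' `window_index()` returns the token-index matrix (one column per window);
#' `window_partition()` gathers a token array into windows and
#' `window_unpartition()` is its exact inverse.
#'
#' @param Hg,Wg Grid dimensions (must be divisible by `ws`).
#' @param ws Window side length in tokens.
#' @return `window_index()`: integer matrix `ws^2 x n_windows`.
#' @export
window_index <- function(Hg, Wg, ws) {
  if (Hg %% ws != 0 || Wg %% ws != 0) {
    stop_thanet("grid ", Hg, "x", Wg, " not divisible by window ", ws)
  }
  nwh <- Hg %/% ws; nww <- Wg %/% ws
  idx <- matrix(0L, ws * ws, nwh * nww)
  w <- 0L
  for (b in seq_len(nww)) {
    for (a in seq_len(nwh)) {
      w <- w + 1L
      rows <- (a - 1L) * ws + seq_len(ws)
      cols <- (b - 1L) * ws + seq_len(ws)
      idx[, w] <- as.vector(outer(rows, (cols - 1L) * Hg, `+`))
    }
  }
  idx
}

#' @rdname window_index
#' @param x Token array `L x C x N` with a `grid` attribute.
#' @return `window_partition()`: array `ws^2 x C x (n_windows * N)`.
#' @export
window_partition <- function(x, ws) {
  g <- token_grid(x)
  d <- dim(x)
  idx <- window_index(g[1], g[2], ws)
  nW <- ncol(idx)
  xw <- x[as.vector(idx), , , drop = FALSE]       # (ws2*nW, C, N)
  dim(xw) <- c(ws * ws, nW, d[2], d[3])
  xw <- aperm(xw, c(1L, 3L, 2L, 4L))
  dim(xw) <- c(ws * ws, d[2], nW * d[3])
  attr(xw, "wgeom") <- list(grid = g, ws = ws, nW = nW, N = d[3], C = d[2])
  xw
}

#' @rdname window_index
#' @param xw Window array produced by `window_partition()`.
#' @param geom Window geometry (taken from the `wgeom` attribute by default).
#' @return `window_unpartition()`: the original token array.
#' @export
window_unpartition <- function(xw, geom = attr(xw, "wgeom", exact = TRUE)) {
  ws <- geom$ws; nW <- geom$nW; N <- geom$N; C <- geom$C
  idx <- window_index(geom$grid[1], geom$grid[2], ws)
  y <- xw
  dim(y) <- c(ws * ws, C, nW, N)
  y <- aperm(y, c(1L, 3L, 2L, 4L))
  dim(y) <- c(ws * ws * nW, C, N)
  out <- array(0, c(geom$grid[1] * geom$grid[2], C, N))
  out[as.vector(idx), , ] <- y
  set_grid(out, geom$grid)
}

# Cyclic shift of a token grid by s rows and columns (s may be negative).
shift_tokens <- function(x, s) {
  if (s == 0) return(x)
  g <- token_grid(x)
  d <- dim(x)
  m <- x
  dim(m) <- c(g[1], g[2], d[2], d[3])
  ri <- ((seq_len(g[1]) - 1L + s) %% g[1]) + 1L
  ci <- ((seq_len(g[2]) - 1L + s) %% g[2]) + 1L
  m <- m[ri, ci, , , drop = FALSE]
  dim(m) <- d
  set_grid(m, g)
}

# Additive attention mask for shifted windows (Swin-style region bookkeeping):
# tokens whose pre-shift neighbourhoods wrap across the grid boundary must not
# attend to each other. Returns ws^2 x ws^2 x nW with 0 / -1e9 entries.
shift_attn_mask <- function(Hg, Wg, ws, s) {
  slice_ids <- function(n) {
    ids <- integer(n)
    ids[seq_len(n - ws)] <- 0L
    ids[(n - ws + 1L):(n - s)] <- 1L
    ids[(n - s + 1L):n] <- 2L
    ids
  }
  hid <- slice_ids(Hg); wid <- slice_ids(Wg)
  region <- outer(hid, wid, function(a, b) a * 3L + b)
  idx <- window_index(Hg, Wg, ws)
  nW <- ncol(idx)
  mask <- array(0, c(ws * ws, ws * ws, nW))
  for (w in seq_len(nW)) {
    r <- region[idx[, w]]
    mask[, , w] <- ifelse(outer(r, r, `!=`), -1e9, 0)
  }
  mask
}

## ---- token layers ---------------------------------------------------------

#' Layer normalisation over the embedding axis of a token array
#' @param ch Embedding width.
#' @param eps Variance floor.
#' @return A module.
#' @export
nn_layernorm_tokens <- function(ch, eps = 1e-5) {
  new_module("nn_layernorm_tokens",
             params = list(gamma = rep(1, ch), beta = numeric(ch)),
             ch = ch, eps = eps)
}

#' @export
nn_forward.nn_layernorm_tokens <- function(mod, x) {
  g <- token_grid(x)
  d <- dim(x)
  m <- aperm(x, c(2L, 1L, 3L))                    # C x (L*N)
  dim(m) <- c(d[2], d[1] * d[3])
  mu <- colMeans(m)
  xc <- m - rep(mu, each = d[2])
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + mod$eps)
  xhat <- xc * rep(invstd, each = d[2])
  y <- xhat * mod$params$gamma + mod$params$beta
  mod$cache <- list(xhat = xhat, invstd = invstd, d = d, g = g)
  dim(y) <- c(d[2], d[1], d[3])
  set_grid(aperm(y, c(2L, 1L, 3L)), g)
}

#' @export
nn_backward.nn_layernorm_tokens <- function(mod, gy) {
  cc <- mod$cache
  d <- cc$d; C <- d[2]
  gm <- aperm(gy, c(2L, 1L, 3L))
  dim(gm) <- c(C, d[1] * d[3])
  mod$grads$gamma <- mod$grads$gamma + rowSums(gm * cc$xhat)
  mod$grads$beta <- mod$grads$beta + rowSums(gm)
  gxh <- gm * mod$params$gamma
  s1 <- colMeans(gxh)
  s2 <- colMeans(gxh * cc$xhat)
  gr <- (gxh - rep(s1, each = C) - cc$xhat * rep(s2, each = C)) *
    rep(cc$invstd, each = C)
  dim(gr) <- c(C, d[1], d[3])
  set_grid(aperm(gr, c(2L, 1L, 3L)), cc$g)
}

#' @export
nn_trace.nn_layernorm_tokens <- function(mod, shape) {
  list(shape = shape, macs = prod(shape))
}

#' Linear layer over the embedding axis of a token array
#' @param in_f,out_f Embedding widths.
#' @param bias Include bias?
#' @return A module.
#' @export
nn_token_linear <- function(in_f, out_f, bias = TRUE) {
  bound <- 1 / sqrt(in_f)
  params <- list(w = matrix(stats::runif(in_f * out_f, -bound, bound), in_f, out_f))
  if (bias) params$b <- stats::runif(out_f, -bound, bound)
  new_module("nn_token_linear", params = params, in_f = in_f, out_f = out_f)
}

#' @export
nn_forward.nn_token_linear <- function(mod, x) {
  g <- token_grid(x)
  d <- dim(x)
  m <- aperm(x, c(1L, 3L, 2L))                    # L x N x C
  dim(m) <- c(d[1] * d[3], d[2])
  y <- m %*% mod$params$w
  if (!is.null(mod$params$b)) y <- y + rep(mod$params$b, each = nrow(y))
  mod$cache <- list(m = m, d = d, g = g)
  dim(y) <- c(d[1], d[3], mod$out_f)
  set_grid(aperm(y, c(1L, 3L, 2L)), g)
}

#' @export
nn_backward.nn_token_linear <- function(mod, gy) {
  cc <- mod$cache
  gm <- aperm(gy, c(1L, 3L, 2L))
  dim(gm) <- c(cc$d[1] * cc$d[3], mod$out_f)
  mod$grads$w <- mod$grads$w + crossprod(cc$m, gm)
  if (!is.null(mod$params$b)) mod$grads$b <- mod$grads$b + colSums(gm)
  gx <- gm %*% t(mod$params$w)
  dim(gx) <- c(cc$d[1], cc$d[3], mod$in_f)
  set_grid(aperm(gx, c(1L, 3L, 2L)), cc$g)
}

#' @export
nn_trace.nn_token_linear <- function(mod, shape) {
  list(shape = c(shape[1], shape[2], mod$out_f),
       macs = shape[1] * shape[2] * mod$in_f * mod$out_f)
}

#' Patch embedding: image to normalised token grid
#'
#' A `patch x patch` strided convolution cuts the (zero-padded) image into
#' non-overlapping patches, the result is flattened to tokens and
#' layer-normalised per token.
#'
#' @param patch Patch side in pixels.
#' @param in_ch Image channels.
#' @param embed Embedding width.
#' @return A module.
#' @export
nn_patch_embed <- function(patch, in_ch, embed) {
  if (patch <= 0) stop_thanet("patch size must be positive")
  new_module("nn_patch_embed",
             children = list(
               proj = nn_conv2d(in_ch, embed, patch, stride = patch),
               ln = nn_layernorm_tokens(embed)
             ),
             patch = patch, embed = embed)
}

#' @export
nn_forward.nn_patch_embed <- function(mod, x) {
  d <- dim(x)
  p <- mod$patch
  ph <- (p - d[1] %% p) %% p
  pw <- (p - d[2] %% p) %% p
  if (ph > 0 || pw > 0) {
    xp <- array(0, c(d[1] + ph, d[2] + pw, d[3], d[4]))
    xp[seq_len(d[1]), seq_len(d[2]), , ] <- x
    x <- xp
  }
  mod$cache <- list(d = d, ph = ph, pw = pw)
  y <- nn_forward(mod$children$proj, x)
  dy <- dim(y)
  g <- c(dy[1], dy[2])
  dim(y) <- c(dy[1] * dy[2], dy[3], dy[4])
  nn_forward(mod$children$ln, set_grid(y, g))
}

#' @export
nn_backward.nn_patch_embed <- function(mod, gy) {
  cc <- mod$cache
  g <- nn_backward(mod$children$ln, gy)
  gr <- token_grid(g)
  d <- dim(g)
  dim(g) <- c(gr[1], gr[2], d[2], d[3])
  gx <- nn_backward(mod$children$proj, g)
  if (cc$ph > 0 || cc$pw > 0) {
    gx <- gx[seq_len(cc$d[1]), seq_len(cc$d[2]), , , drop = FALSE]
  }
  gx
}

#' @export
nn_trace.nn_patch_embed <- function(mod, shape) {
  hg <- ceiling(shape[1] / mod$patch)
  wg <- ceiling(shape[2] / mod$patch)
  macs <- hg * wg * mod$patch^2 * shape[3] * mod$embed + hg * wg * mod$embed
  list(shape = c(hg, wg, mod$embed), macs = macs)
}

#' Patch merging: downsample a token grid 2x and double its width
#'
#' Concatenates each 2x2 token neighbourhood, layer-normalises, and projects
#' `4C -> 2C` with a bias-free linear map.
#'
#' @param in_ch Incoming embedding width `C`.
#' @return A module.
#' @export
nn_patch_merge <- function(in_ch) {
  new_module("nn_patch_merge",
             children = list(
               ln = nn_layernorm_tokens(4 * in_ch),
               proj = nn_token_linear(4 * in_ch, 2 * in_ch, bias = FALSE)
             ),
             in_ch = in_ch)
}

merge_index <- function(Hg, Wg) {
  Hh <- Hg %/% 2L; Wh <- Wg %/% 2L
  i <- rep(seq_len(Hh), Wh)
  j <- rep(seq_len(Wh), each = Hh)
  lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(o) {
    (2L * j - 2L + o[2]) * Hg + (2L * i - 1L + o[1])
  })
}

#' @export
nn_forward.nn_patch_merge <- function(mod, x) {
  g <- token_grid(x)
  if (g[1] < 2 || g[2] < 2 || g[1] %% 2 != 0 || g[2] %% 2 != 0) {
    stop_thanet("grid ", g[1], "x", g[2], " cannot be 2x2-merged")
  }
  d <- dim(x)
  C <- d[2]
  idx <- merge_index(g[1], g[2])
  Lh <- length(idx[[1]])
  xm <- array(0, c(Lh, 4L * C, d[3]))
  for (k in 1:4) xm[, (k - 1L) * C + seq_len(C), ] <- x[idx[[k]], , , drop = FALSE]
  mod$cache <- list(g = g, d = d, idx = idx)
  y <- set_grid(xm, c(g[1] %/% 2L, g[2] %/% 2L))
  nn_forward(mod$children$proj, nn_forward(mod$children$ln, y))
}

#' @export
nn_backward.nn_patch_merge <- function(mod, gy) {
  cc <- mod$cache
  gm <- nn_backward(mod$children$ln, nn_backward(mod$children$proj, gy))
  C <- cc$d[2]
  gx <- array(0, cc$d)
  for (k in 1:4) {
    gx[cc$idx[[k]], , ] <- gm[, (k - 1L) * C + seq_len(C), , drop = FALSE]
  }
  set_grid(gx, cc$g)
}

#' @export
nn_trace.nn_patch_merge <- function(mod, shape) {
  hg <- shape[1] %/% 2; wg <- shape[2] %/% 2
  C <- mod$in_ch
  macs <- hg * wg * 4 * C +                # layer norm
    hg * wg * (4 * C) * (2 * C)            # projection
  list(shape = c(hg, wg, 2 * C), macs = macs)
}

#' Windowed multi-head self-attention layer
#'
#' Splits the token grid into `window x window` blocks and applies multi-head
#' self-attention inside each block ([msa()]); in shifted mode the grid is
#' cyclically shifted by half a window first and wrap-around attention is
#' masked out, so adjacent windows exchange information across layers. When
#' the window does not fit the grid it shrinks to the grid size (single
#' window, no shift).
#'
#' @param ch Embedding width (divisible by `heads`).
#' @param heads Attention head count.
#' @param window Window side in tokens.
#' @param shifted Use shifted windows?
#' @return A module.
#' @export
nn_window_attention <- function(ch, heads, window, shifted = FALSE) {
  if (ch %% heads != 0) stop_thanet("embedding not divisible by heads")
  bound <- 1 / sqrt(ch)
  new_module("nn_window_attention",
             params = list(
               wqkv = matrix(stats::runif(ch * 3 * ch, -bound, bound), ch, 3 * ch),
               bqkv = numeric(3 * ch),
               wproj = matrix(stats::runif(ch * ch, -bound, bound), ch, ch),
               bproj = numeric(ch)
             ),
             ch = ch, heads = heads, window = window, shifted = shifted)
}

#' @export
nn_forward.nn_window_attention <- function(mod, x) {
  g <- token_grid(x)
  d <- dim(x)
  C <- mod$ch; nh <- mod$heads; dh <- C %/% nh
  ws <- min(mod$window, g[1], g[2])
  if (g[1] %% ws != 0 || g[2] %% ws != 0) {
    stop_thanet("grid ", g[1], "x", g[2], " not divisible by window ", ws)
  }
  nW <- (g[1] %/% ws) * (g[2] %/% ws)
  s <- if (mod$shifted && nW > 1L) ws %/% 2L else 0L
  xs <- if (s > 0) shift_tokens(x, s) else x
  xw <- window_partition(set_grid(xs, g), ws)
  wgeom <- attr(xw, "wgeom", exact = TRUE)
  ws2 <- ws * ws
  nB <- nW * d[3]
  m <- aperm(xw, c(1L, 3L, 2L))
  dim(m) <- c(ws2 * nB, C)
  qkv <- m %*% mod$params$wqkv + rep(mod$params$bqkv, each = ws2 * nB)
  mask <- if (s > 0) shift_attn_mask(g[1], g[2], ws, s) else NULL
  O <- matrix(0, ws2 * nB, C)
  Aarr <- array(0, c(ws2, ws2, nh, nB))
  for (b in seq_len(nB)) {
    rows <- (b - 1L) * ws2 + seq_len(ws2)
    mw <- if (is.null(mask)) NULL else mask[, , ((b - 1L) %% nW) + 1L]
    for (h in seq_len(nh)) {
      cs <- (h - 1L) * dh + seq_len(dh)
      q <- qkv[rows, cs, drop = FALSE]
      k <- qkv[rows, C + cs, drop = FALSE]
      v <- qkv[rows, 2L * C + cs, drop = FALSE]
      logits <- tcrossprod(q, k) / sqrt(dh)
      if (!is.null(mw)) logits <- logits + mw
      A <- softmax_rows(logits)
      O[rows, cs] <- A %*% v
      Aarr[, , h, b] <- A
    }
  }
  y <- O %*% mod$params$wproj + rep(mod$params$bproj, each = ws2 * nB)
  dim(y) <- c(ws2, nB, C)
  y <- aperm(y, c(1L, 3L, 2L))
  out <- window_unpartition(y, wgeom)
  if (s > 0) out <- shift_tokens(out, -s)
  mod$cache <- list(m = m, qkv = qkv, O = O, A = Aarr, wgeom = wgeom,
                    ws = ws, ws2 = ws2, nB = nB, nW = nW, s = s, g = g, d = d)
  set_grid(out, g)
}

#' @export
nn_backward.nn_window_attention <- function(mod, gy) {
  cc <- mod$cache
  C <- mod$ch; nh <- mod$heads; dh <- C %/% nh
  ws2 <- cc$ws2; nB <- cc$nB
  if (cc$s > 0) gy <- shift_tokens(set_grid(gy, cc$g), cc$s)
  gw <- window_partition(set_grid(gy, cc$g), cc$ws)
  gm <- aperm(gw, c(1L, 3L, 2L))
  dim(gm) <- c(ws2 * nB, C)
  mod$grads$wproj <- mod$grads$wproj + crossprod(cc$O, gm)
  mod$grads$bproj <- mod$grads$bproj + colSums(gm)
  gO <- gm %*% t(mod$params$wproj)
  gqkv <- matrix(0, ws2 * nB, 3L * C)
  for (b in seq_len(nB)) {
    rows <- (b - 1L) * ws2 + seq_len(ws2)
    for (h in seq_len(nh)) {
      cs <- (h - 1L) * dh + seq_len(dh)
      q <- cc$qkv[rows, cs, drop = FALSE]
      k <- cc$qkv[rows, C + cs, drop = FALSE]
      v <- cc$qkv[rows, 2L * C + cs, drop = FALSE]
      A <- cc$A[, , h, b]
      go <- gO[rows, cs, drop = FALSE]
      gA <- tcrossprod(go, v)                     # go %*% t(v)
      gv <- crossprod(A, go)
      dl <- A * (gA - rowSums(gA * A))
      gqkv[rows, cs] <- (dl %*% k) / sqrt(dh)
      gqkv[rows, C + cs] <- crossprod(dl, q) / sqrt(dh)
      gqkv[rows, 2L * C + cs] <- gv
    }
  }
  mod$grads$wqkv <- mod$grads$wqkv + crossprod(cc$m, gqkv)
  mod$grads$bqkv <- mod$grads$bqkv + colSums(gqkv)
  gxm <- gqkv %*% t(mod$params$wqkv)
  dim(gxm) <- c(ws2, nB, C)
  gxm <- aperm(gxm, c(1L, 3L, 2L))
  gx <- window_unpartition(gxm, cc$wgeom)
  if (cc$s > 0) gx <- shift_tokens(gx, -cc$s)
  set_grid(gx, cc$g)
}

#' @export
nn_trace.nn_window_attention <- function(mod, shape) {
  L <- shape[1] * shape[2]
  ws <- min(mod$window, shape[1], shape[2])
  C <- mod$ch
  macs <- 3 * L * C^2 + 2 * L * ws^2 * C + L * C^2
  list(shape = shape, macs = macs)
}

#' Token MLP sublayer (linear, GELU, linear)
#' @param ch Embedding width.
#' @param hidden Hidden width (default `4 * ch`).
#' @return A module.
#' @export
nn_token_mlp <- function(ch, hidden = 4 * ch) {
  nn_sequential(nn_token_linear(ch, hidden), nn_gelu(),
                nn_token_linear(hidden, ch))
}

#' One global feature block
#'
#' Patch merging followed by the two residual sublayers
#' (`LN -> (S)W-MSA -> +x` and `LN -> MLP -> +x`). The grid halves and the
#' embedding doubles: input `Hg x Wg x C`, output `Hg/2 x Wg/2 x 2C`.
#'
#' @param in_ch Incoming embedding width.
#' @param heads Head count for the attention sublayer (divides `2 * in_ch`).
#' @param window Window side in tokens.
#' @param shifted Use shifted windows in this block?
#' @return A module.
#' @export
global_feature_block <- function(in_ch, heads, window, shifted = FALSE) {
  ch <- 2L * in_ch
  nn_sequential(
    nn_patch_merge(in_ch),
    nn_residual(nn_sequential(
      nn_layernorm_tokens(ch),
      nn_window_attention(ch, heads, window, shifted)
    )),
    nn_residual(nn_sequential(
      nn_layernorm_tokens(ch),
      nn_token_mlp(ch)
    ))
  )
}

#' Reshape a token grid into a feature map
#' @return A module.
#' @export
nn_tokens_to_map <- function() new_module("nn_tokens_to_map")

#' @export
nn_forward.nn_tokens_to_map <- function(mod, x) {
  g <- token_grid(x)
  d <- dim(x)
  mod$cache <- list(g = g, d = d)
  y <- x
  attr(y, "grid") <- NULL
  dim(y) <- c(g[1], g[2], d[2], d[3])
  y
}

#' @export
nn_backward.nn_tokens_to_map <- function(mod, gy) {
  cc <- mod$cache
  dim(gy) <- cc$d
  set_grid(gy, cc$g)
}

#' @export
nn_trace.nn_tokens_to_map <- function(mod, shape) list(shape = shape, macs = 0)

#' Build the global feature stream
#'
#' Patch partition plus three successive global feature blocks with
#' alternating plain / shifted windows, ending in a feature map at 1/32 of
#' the input resolution with `8 x embed` channels (e.g. `patch = 4`,
#' `embed = 96` maps a 224-pixel image to a `7 x 7 x 768` block).
#'
#' @param patch Patch side in pixels.
#' @param embed Embedding width after patch partition.
#' @param window Window side in tokens.
#' @param heads Integer vector of three head counts, one per block.
#' @param in_ch Image channels.
#' @return A module emitting a feature map.
#' @export
build_gfs <- function(patch = 4, embed = 96, window = 7, heads = c(3, 6, 12),
                      in_ch = 3) {
  stopifnot(length(heads) == 3)
  nn_sequential(
    nn_patch_embed(patch, in_ch, embed),
    global_feature_block(embed, heads[1], window, shifted = FALSE),
    global_feature_block(2 * embed, heads[2], window, shifted = TRUE),
    global_feature_block(4 * embed, heads[3], window, shifted = FALSE),
    nn_tokens_to_map()
  )
}
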
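# Standard layers. Weight initialisation follows the usual He/uniform fan-in
# schemes; draws come from the current RNG stream so model construction is
# reproducible under set.seed()/with_seed().

#' 2-D convolution layer
#'
#' @param in_ch,out_ch Channel counts.
#' @param kernel Kernel size (square).
#' @param stride,pad Stride and zero padding.
#' @param bias Include a bias vector?
#' @param groups Channel groups; `groups == in_ch == out_ch` selects the
#'   depthwise path, other grouped cases loop over dense groups.
#' @return A module.
#' @export
nn_conv2d <- function(in_ch, out_ch, kernel, stride = 1, pad = 0,
                      bias = TRUE, groups = 1) {
  if (kernel <= 0) stop_thanet("kernel size must be positive")
  if (in_ch %% groups != 0 || out_ch %% groups != 0) {
    stop_thanet("channels not divisible by groups")
  }
  fan_in <- kernel * kernel * in_ch / groups
  sd <- sqrt(2 / fan_in)
  dw <- groups > 1 && groups == in_ch && groups == out_ch
  w <- if (dw) {
    array(stats::rnorm(kernel * kernel * in_ch, sd = sd),
          c(kernel, kernel, in_ch))
  } else {
    array(stats::rnorm(kernel * kernel * (in_ch / groups) * out_ch, sd = sd),
          c(kernel, kernel, in_ch / groups, out_ch))
  }
  params <- list(w = w)
  if (bias) params$b <- numeric(out_ch)
  new_module("nn_conv2d", params = params,
             in_ch = in_ch, out_ch = out_ch, kernel = kernel, stride = stride,
             pad = pad, groups = groups, depthwise = dw)
}

#' @export
nn_forward.nn_conv2d <- function(mod, x) {
  b <- mod$params$b
  if (mod$depthwise) {
    r <- dwconv_fwd(x, mod$params$w, b, mod$stride, mod$pad)
    mod$cache <- r[c("xp", "geom")]
    return(r$y)
  }
  if (mod$groups == 1) {
    r <- conv2d_fwd(x, mod$params$w, b, mod$stride, mod$pad)
    mod$cache <- r[c("cols", "geom")]
    return(r$y)
  }
  # general grouped case: loop dense groups
  gs_in <- mod$in_ch / mod$groups; gs_out <- mod$out_ch / mod$groups
  caches <- vector("list", mod$groups)
  ys <- vector("list", mod$groups)
  for (g in seq_len(mod$groups)) {
    xi <- x[, , (g - 1) * gs_in + seq_len(gs_in), , drop = FALSE]
    wi <- mod$params$w[, , , (g - 1) * gs_out + seq_len(gs_out), drop = FALSE]
    bi <- if (is.null(b)) NULL else b[(g - 1) * gs_out + seq_len(gs_out)]
    r <- conv2d_fwd(xi, wi, bi, mod$stride, mod$pad)
    caches[[g]] <- r[c("cols", "geom")]
    ys[[g]] <- r$y
  }
  d <- dim(ys[[1]])
  out <- array(0, c(d[1], d[2], mod$out_ch, d[4]))
  for (g in seq_len(mod$groups)) {
    out[, , (g - 1) * gs_out + seq_len(gs_out), ] <- ys[[g]]
  }
  mod$cache <- list(groups = caches)
  out
}

#' @export
nn_backward.nn_conv2d <- function(mod, gy) {
  if (mod$depthwise) {
    r <- dwconv_bwd(gy, mod$params$w, mod$cache)
  } else if (mod$groups == 1) {
    r <- conv2d_bwd(gy, mod$params$w, mod$cache)
  } else {
    gs_in <- mod$in_ch / mod$groups; gs_out <- mod$out_ch / mod$groups
    gw <- array(0, dim(mod$params$w)); gb <- numeric(mod$out_ch); gx <- NULL
    for (g in seq_len(mod$groups)) {
      wi <- mod$params$w[, , , (g - 1) * gs_out + seq_len(gs_out), drop = FALSE]
      ri <- conv2d_bwd(gy[, , (g - 1) * gs_out + seq_len(gs_out), , drop = FALSE],
                       wi, mod$cache$groups[[g]])
      gw[, , , (g - 1) * gs_out + seq_len(gs_out)] <- ri$gw
      gb[(g - 1) * gs_out + seq_len(gs_out)] <- ri$gb
      if (is.null(gx)) {
        d <- mod$cache$groups[[1]]$geom
        gx <- array(0, c(d$H, d$W, mod$in_ch, d$N))
      }
      gx[, , (g - 1) * gs_in + seq_len(gs_in), ] <- ri$gx
    }
    r <- list(gx = gx, gw = gw, gb = gb)
  }
  mod$grads$w <- mod$grads$w + r$gw
  if (!is.null(mod$params$b)) mod$grads$b <- mod$grads$b + r$gb
  r$gx
}

#' @export
nn_trace.nn_conv2d <- function(mod, shape) {
  ho <- conv_out_dim(shape[1], mod$kernel, mod$stride, mod$pad)
  wo <- conv_out_dim(shape[2], mod$kernel, mod$stride, mod$pad)
  macs <- ho * wo * mod$kernel^2 * (mod$in_ch / mod$groups) * mod$out_ch
  list(shape = c(ho, wo, mod$out_ch), macs = macs)
}

#' Batch normalisation over channels of a feature map
#' @param ch Channel count.
#' @param eps Variance floor.
#' @param momentum Running-statistics update rate.
#' @return A module.
#' @export
nn_batchnorm2d <- function(ch, eps = 1e-5, momentum = 0.1) {
  new_module("nn_batchnorm2d",
             params = list(gamma = rep(1, ch), beta = numeric(ch)),
             state = list(run_mean = numeric(ch), run_var = rep(1, ch)),
             ch = ch, eps = eps, momentum = momentum)
}

#' @export
nn_forward.nn_batchnorm2d <- function(mod, x) {
  d <- dim(x)
  r <- aperm(x, c(1L, 2L, 4L, 3L))
  M <- d[1] * d[2] * d[4]
  dim(r) <- c(M, d[3])
  if (mod$training) {
    mu <- colMeans(r)
    v <- colMeans(r * r) - mu * mu
    mod$state$run_mean <- (1 - mod$momentum) * mod$state$run_mean + mod$momentum * mu
    mod$state$run_var <- (1 - mod$momentum) * mod$state$run_var +
      mod$momentum * v * M / max(1, M - 1)
  } else {
    mu <- mod$state$run_mean
    v <- mod$state$run_var
  }
  invstd <- 1 / sqrt(v + mod$eps)
  xhat <- (r - rep(mu, each = M)) * rep(invstd, each = M)
  y <- xhat * rep(mod$params$gamma, each = M) + rep(mod$params$beta, each = M)
  mod$cache <- list(xhat = xhat, invstd = invstd, d = d, M = M,
                    batch_stats = mod$training)
  dim(y) <- c(d[1], d[2], d[4], d[3])
  aperm(y, c(1L, 2L, 4L, 3L))
}

#' @export
nn_backward.nn_batchnorm2d <- function(mod, gy) {
  cc <- mod$cache
  d <- cc$d; M <- cc$M
  g <- aperm(gy, c(1L, 2L, 4L, 3L))
  dim(g) <- c(M, d[3])
  mod$grads$gamma <- mod$grads$gamma + colSums(g * cc$xhat)
  mod$grads$beta <- mod$grads$beta + colSums(g)
  gxh <- g * rep(mod$params$gamma, each = M)
  if (cc$batch_stats) {
    s1 <- colMeans(gxh)
    s2 <- colMeans(gxh * cc$xhat)
    gr <- (gxh - rep(s1, each = M) - cc$xhat * rep(s2, each = M)) *
      rep(cc$invstd, each = M)
  } else {
    gr <- gxh * rep(cc$invstd, each = M)
  }
  dim(gr) <- c(d[1], d[2], d[4], d[3])
  aperm(gr, c(1L, 2L, 4L, 3L))
}

#' @export
nn_trace.nn_batchnorm2d <- function(mod, shape) {
  list(shape = shape, macs = prod(shape))
}

#' Fully-connected layer on `N x in` matrices
#' @param in_f,out_f Feature counts.
#' @param bias Include bias?
#' @return A module.
#' @export
nn_linear <- function(in_f, out_f, bias = TRUE) {
  bound <- 1 / sqrt(in_f)
  params <- list(w = matrix(stats::runif(in_f * out_f, -bound, bound), in_f, out_f))
  if (bias) params$b <- stats::runif(out_f, -bound, bound)
  new_module("nn_linear", params = params, in_f = in_f, out_f = out_f)
}

#' @export
nn_forward.nn_linear <- function(mod, x) {
  mod$cache <- list(x = x)
  y <- x %*% mod$params$w
  if (!is.null(mod$params$b)) y <- y + rep(mod$params$b, each = nrow(x))
  y
}

#' @export
nn_backward.nn_linear <- function(mod, gy) {
  mod$grads$w <- mod$grads$w + crossprod(mod$cache$x, gy)
  if (!is.null(mod$params$b)) mod$grads$b <- mod$grads$b + colSums(gy)
  gy %*% t(mod$params$w)
}

#' @export
nn_trace.nn_linear <- function(mod, shape) {
  list(shape = mod$out_f, macs = mod$in_f * mod$out_f)
}

## ---- activations ----------------------------------------------------------

act_module <- function(class) new_module(class)

#' Activation layers
#' @return A module.
#' @name activations
NULL

#' @rdname activations
#' @export
nn_relu <- function() act_module("nn_relu")
#' @export
nn_forward.nn_relu <- function(mod, x) {
  mod$cache <- list(mask = x > 0)
  y <- x * mod$cache$mask
  attr(y, "grid") <- attr(x, "grid", exact = TRUE)
  y
}
#' @export
nn_backward.nn_relu <- function(mod, gy) gy * mod$cache$mask

#' @rdname activations
#' @export
nn_sigmoid <- function() act_module("nn_sigmoid")
#' @export
nn_forward.nn_sigmoid <- function(mod, x) {
  y <- 1 / (1 + exp(-x))
  mod$cache <- list(y = y)
  y
}
#' @export
nn_backward.nn_sigmoid <- function(mod, gy) gy * mod$cache$y * (1 - mod$cache$y)

#' @rdname activations
#' @export
nn_gelu <- function() act_module("nn_gelu")
#' @export
nn_forward.nn_gelu <- function(mod, x) {
  p <- stats::pnorm(x)
  mod$cache <- list(x = x, p = p)
  y <- x * p
  attr(y, "grid") <- attr(x, "grid", exact = TRUE)
  y
}
#' @export
nn_backward.nn_gelu <- function(mod, gy) {
  gy * (mod$cache$p + mod$cache$x * stats::dnorm(mod$cache$x))
}

#' @rdname activations
#' @export
nn_silu <- function() act_module("nn_silu")
#' @export
nn_forward.nn_silu <- function(mod, x) {
  s <- 1 / (1 + exp(-x))
  mod$cache <- list(x = x, s = s)
  x * s
}
#' @export
nn_backward.nn_silu <- function(mod, gy) {
  s <- mod$cache$s
  gy * (s + mod$cache$x * s * (1 - s))
}

#' @rdname activations
#' @export
nn_hardswish <- function() act_module("nn_hardswish")
#' @export
nn_forward.nn_hardswish <- function(mod, x) {
  r <- pmin(pmax(x + 3, 0), 6)
  mod$cache <- list(x = x)
  x * r / 6
}
#' @export
nn_backward.nn_hardswish <- function(mod, gy) {
  x <- mod$cache$x
  d <- ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6))
  gy * d
}

#' @rdname activations
#' @export
nn_hardsigmoid <- function() act_module("nn_hardsigmoid")
#' @export
nn_forward.nn_hardsigmoid <- function(mod, x) {
  mod$cache <- list(x = x)
  pmin(pmax(x / 6 + 0.5, 0), 1)
}
#' @export
nn_backward.nn_hardsigmoid <- function(mod, gy) {
  x <- mod$cache$x
  gy * ifelse(x > -3 & x < 3, 1 / 6, 0)
}

#' @export
nn_trace.nn_relu <- function(mod, shape) list(shape = shape, macs = 0)
#' @export
nn_trace.nn_sigmoid <- nn_trace.nn_relu
#' @export
nn_trace.nn_gelu <- nn_trace.nn_relu
#' @export
nn_trace.nn_silu <- nn_trace.nn_relu
#' @export
nn_trace.nn_hardswish <- nn_trace.nn_relu
#' @export
nn_trace.nn_hardsigmoid <- nn_trace.nn_relu

## ---- pooling and reshaping ------------------------------------------------

#' Max pooling
#' @param kernel,stride,pad Pooling geometry.
#' @param ceil Use ceiling-mode output sizing (pads bottom/right as needed).
#' @return A module.
#' @export
nn_maxpool2d <- function(kernel, stride = kernel, pad = 0, ceil = FALSE) {
  new_module("nn_maxpool2d", kernel = kernel, stride = stride, pad = pad,
             ceil = ceil)
}

pool_out_dim <- function(n, k, stride, pad, ceil) {
  if (ceil) as.integer(ceiling((n + 2 * pad - k) / stride)) + 1L
  else conv_out_dim(n, k, stride, pad)
}

#' @export
nn_forward.nn_maxpool2d <- function(mod, x) {
  d <- dim(x)
  mod$cache_trim <- NULL
  if (mod$ceil) {
    ho <- pool_out_dim(d[1], mod$kernel, mod$stride, mod$pad, TRUE)
    wo <- pool_out_dim(d[2], mod$kernel, mod$stride, mod$pad, TRUE)
    need_h <- (ho - 1L) * mod$stride + mod$kernel - 2L * mod$pad
    need_w <- (wo - 1L) * mod$stride + mod$kernel - 2L * mod$pad
    if (need_h > d[1] || need_w > d[2]) {
      xp <- array(-Inf, c(max(need_h, d[1]), max(need_w, d[2]), d[3], d[4]))
      xp[seq_len(d[1]), seq_len(d[2]), , ] <- x
      mod$cache_trim <- d
      x <- xp
    }
  }
  r <- maxpool_fwd(x, mod$kernel, mod$stride, mod$pad)
  mod$cache <- r[c("argk", "geom")]
  r$y
}
#' @export
nn_backward.nn_maxpool2d <- function(mod, gy) {
  gx <- maxpool_bwd(gy, mod$cache)
  if (!is.null(mod$cache_trim)) {
    d <- mod$cache_trim
    gx <- gx[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]
  }
  gx
}
#' @export
nn_trace.nn_maxpool2d <- function(mod, shape) {
  list(shape = c(pool_out_dim(shape[1], mod$kernel, mod$stride, mod$pad, mod$ceil),
                 pool_out_dim(shape[2], mod$kernel, mod$stride, mod$pad, mod$ceil),
                 shape[3]), macs = 0)
}

#' Identity module
#' @return A module.
#' @export
nn_identity <- function() new_module("nn_identity")
#' @export
nn_forward.nn_identity <- function(mod, x) x
#' @export
nn_backward.nn_identity <- function(mod, gy) gy
#' @export
nn_trace.nn_identity <- function(mod, shape) list(shape = shape, macs = 0)

#' Average pooling
#' @param kernel,stride Pooling geometry.
#' @return A module.
#' @export
nn_avgpool2d <- function(kernel, stride = kernel) {
  new_module("nn_avgpool2d", kernel = kernel, stride = stride)
}
#' @export
nn_forward.nn_avgpool2d <- function(mod, x) {
  r <- avgpool_fwd(x, mod$kernel, mod$stride)
  mod$cache <- r["geom"]
  r$y
}
#' @export
nn_backward.nn_avgpool2d <- function(mod, gy) avgpool_bwd(gy, mod$cache)
#' @export
nn_trace.nn_avgpool2d <- function(mod, shape) {
  list(shape = c(conv_out_dim(shape[1], mod$kernel, mod$stride, 0),
                 conv_out_dim(shape[2], mod$kernel, mod$stride, 0),
                 shape[3]), macs = 0)
}

#' Global average pooling: feature map to `N x C` matrix
#' @return A module.
#' @export
nn_gap <- function() new_module("nn_gap")
#' @export
nn_forward.nn_gap <- function(mod, x) {
  r <- gap_fwd(x)
  mod$cache <- list(geom = r$geom)
  r$y
}
#' @export
nn_backward.nn_gap <- function(mod, gy) gap_bwd(gy, mod$cache$geom)
#' @export
nn_trace.nn_gap <- function(mod, shape) list(shape = shape[3], macs = 0)

#' Flatten feature map to `N x (H*W*C)`
#' @return A module.
#' @export
nn_flatten <- function() new_module("nn_flatten")
#' @export
nn_forward.nn_flatten <- function(mod, x) {
  d <- dim(x)
  mod$cache <- list(d = d)
  m <- x
  dim(m) <- c(d[1] * d[2] * d[3], d[4])
  t(m)
}
#' @export
nn_backward.nn_flatten <- function(mod, gy) {
  d <- mod$cache$d
  g <- t(gy)
  dim(g) <- d
  g
}
#' @export
nn_trace.nn_flatten <- function(mod, shape) list(shape = prod(shape), macs = 0)
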
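# Channel feature stream (CFS).
#
# A convolutional stem (7x7 stride-2 conv + 3x3 stride-2 max-pool) followed
# by three stages, each a stride-2 3x3 convolution whose output is re-scaled
# per channel by dual-pool channel attention: global average and global max
# descriptors pass through one shared bottleneck MLP, the two maps are added
# and squashed by a sigmoid. For a 224-pixel input the stream ends at a
# 64 x 7 x 7 feature map (224 -> 112 -> 56 -> 28 -> 14 -> 7).

#' Dual-pool channel attention layer
#'
#' Computes per-channel gates `a = sigmoid(MLP(avgpool(X)) + MLP(maxpool(X)))`
#' with a shared bias-free two-layer MLP (`C -> C/r -> C`, ReLU inside), and
#' multiplies the input feature map by `a` channel-wise. Gates are strictly
#' inside (0, 1).
#'
#' @param ch Channel count.
#' @param reduction Bottleneck reduction ratio `r` (hidden width is
#'   `max(1, ch / r)`; `ch` must be divisible by `r` when `ch >= r`).
#' @return A module.
#' @export
nn_channel_attention <- function(ch, reduction = 16) {
  if (ch >= reduction && ch %% reduction != 0) {
    stop_thanet("channels (", ch, ") not divisible by reduction (", reduction, ")")
  }
  hidden <- max(1L, ch %/% reduction)
  sd1 <- sqrt(2 / ch)
  sd2 <- sqrt(2 / hidden)
  new_module("nn_channel_attention",
             params = list(
               w1 = matrix(stats::rnorm(ch * hidden, sd = sd1), ch, hidden),
               w2 = matrix(stats::rnorm(hidden * ch, sd = sd2), hidden, ch)
             ),
             ch = ch, hidden = hidden)
}

#' Channel attention gates for a feature map
#'
#' Functional access to the gates of [nn_channel_attention()] without
#' applying them to the input.
#'
#' @param mod An `nn_channel_attention` module.
#' @param x Feature map `H x W x C x N`.
#' @return Gate matrix `N x C`, entries in (0, 1).
#' @export
channel_attention_weights <- function(mod, x) {
  d <- dim(x)
  m <- x; dim(m) <- c(d[1] * d[2], d[3] * d[4])
  ap <- t(matrix(colMeans(m), d[3], d[4]))        # N x C
  mx <- t(matrix(apply(m, 2, max), d[3], d[4]))
  mlp <- function(v) pmax(v %*% mod$params$w1, 0) %*% mod$params$w2
  1 / (1 + exp(-(mlp(ap) + mlp(mx))))
}

#' @export
nn_forward.nn_channel_attention <- function(mod, x) {
  d <- dim(x)
  HW <- d[1] * d[2]
  m <- x; dim(m) <- c(HW, d[3] * d[4])
  ap <- t(matrix(colMeans(m), d[3], d[4]))        # N x C
  amax <- apply(m, 2, which.max)
  mx <- t(matrix(m[cbind(amax, seq_len(d[3] * d[4]))], d[3], d[4]))
  h_a <- ap %*% mod$params$w1
  h_m <- mx %*% mod$params$w1
  z <- pmax(h_a, 0) %*% mod$params$w2 + pmax(h_m, 0) %*% mod$params$w2
  a <- 1 / (1 + exp(-z))                          # N x C
  arep <- rep(t(a), each = HW)
  y <- x * arep
  mod$cache <- list(x = x, a = a, arep = arep, ap = ap, mx = mx,
                    h_a = h_a, h_m = h_m, amax = amax, d = d)
  y
}

#' @export
nn_backward.nn_channel_attention <- function(mod, gy) {
  cc <- mod$cache
  d <- cc$d; HW <- d[1] * d[2]
  gx <- gy * cc$arep
  # gradient wrt the gate, per (channel, sample)
  prod <- gy * cc$x
  dim(prod) <- c(HW, d[3], d[4])
  ga <- t(colSums(prod))                          # N x C
  gz <- ga * cc$a * (1 - cc$a)
  gh_a <- (gz %*% t(mod$params$w2)) * (cc$h_a > 0)
  gh_m <- (gz %*% t(mod$params$w2)) * (cc$h_m > 0)
  mod$grads$w2 <- mod$grads$w2 +
    crossprod(pmax(cc$h_a, 0), gz) + crossprod(pmax(cc$h_m, 0), gz)
  mod$grads$w1 <- mod$grads$w1 + crossprod(cc$ap, gh_a) + crossprod(cc$mx, gh_m)
  gap_in <- gh_a %*% t(mod$params$w1)             # N x C, through avg pool
  gmx_in <- gh_m %*% t(mod$params$w1)             # N x C, through max pool
  gx <- gx + rep(t(gap_in) / HW, each = HW)
  # scatter max-pool gradient to argmax positions
  gmx_flat <- as.vector(t(gmx_in))                # length C*N, matches amax
  gadd <- numeric(HW * d[3] * d[4])
  pos <- cc$amax + (seq_along(cc$amax) - 1L) * HW
  gadd[pos] <- gmx_flat
  dim(gadd) <- d
  gx + gadd
}

#' @export
nn_trace.nn_channel_attention <- function(mod, shape) {
  list(shape = shape, macs = 2 * (mod$ch * mod$hidden * 2))
}

#' One channel feature block
#'
#' Stride-2 3x3 convolution (+ batch norm and ReLU) followed by dual-pool
#' channel attention re-scaling its output.
#'
#' @param in_ch,out_ch Channel counts.
#' @param reduction Attention bottleneck ratio.
#' @return A module.
#' @export
channel_feature_block <- function(in_ch, out_ch, reduction = 16) {
  nn_sequential(
    nn_conv2d(in_ch, out_ch, 3, stride = 2, pad = 1, bias = FALSE),
    nn_batchnorm2d(out_ch),
    nn_relu(),
    nn_channel_attention(out_ch, reduction)
  )
}

#' Build the channel feature stream
#'
#' Stem (7x7 stride-2 convolution to `width` channels, batch norm, ReLU,
#' 3x3 stride-2 max-pool) followed by three channel feature blocks, ending at
#' 1/32 of the input resolution.
#'
#' @param width Constant stage width in channels.
#' @param reduction Attention bottleneck ratio.
#' @param in_ch Image channels.
#' @return A module emitting a feature map.
#' @export
build_cfs <- function(width = 64, reduction = 16, in_ch = 3) {
  nn_sequential(
    nn_conv2d(in_ch, width, 7, stride = 2, pad = 3, bias = FALSE),
    nn_batchnorm2d(width),
    nn_relu(),
    nn_maxpool2d(3, stride = 2, pad = 1),
    channel_feature_block(width, width, reduction),
    channel_feature_block(width, width, reduction),
    channel_feature_block(width, width, reduction)
  )
}
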
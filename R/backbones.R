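# Backbone zoo: the standard classification architectures used as
# comparators, built from the package's layer primitives so that one
# declarative definition yields the forward pass, the trainable-parameter
# count and the analytic MAC count. All final fully-connected layers are
# replaced by a `num_outputs`-way head; everything upstream is the canonical
# published architecture.

conv_bn_act <- function(in_ch, out_ch, kernel, stride = 1, pad = 0,
                        act = nn_relu, groups = 1) {
  nn_sequential(
    nn_conv2d(in_ch, out_ch, kernel, stride = stride, pad = pad,
              bias = FALSE, groups = groups),
    nn_batchnorm2d(out_ch),
    act()
  )
}

## ---- ResNet ---------------------------------------------------------------

resnet_basic_block <- function(in_ch, out_ch, stride) {
  main <- nn_sequential(
    nn_conv2d(in_ch, out_ch, 3, stride = stride, pad = 1, bias = FALSE),
    nn_batchnorm2d(out_ch),
    nn_relu(),
    nn_conv2d(out_ch, out_ch, 3, stride = 1, pad = 1, bias = FALSE),
    nn_batchnorm2d(out_ch)
  )
  shortcut <- if (stride != 1 || in_ch != out_ch) {
    nn_sequential(
      nn_conv2d(in_ch, out_ch, 1, stride = stride, bias = FALSE),
      nn_batchnorm2d(out_ch)
    )
  } else NULL
  nn_sequential(nn_residual(main, shortcut), nn_relu())
}

resnet_bottleneck <- function(in_ch, mid, stride) {
  out_ch <- mid * 4L
  main <- nn_sequential(
    nn_conv2d(in_ch, mid, 1, bias = FALSE), nn_batchnorm2d(mid), nn_relu(),
    nn_conv2d(mid, mid, 3, stride = stride, pad = 1, bias = FALSE),
    nn_batchnorm2d(mid), nn_relu(),
    nn_conv2d(mid, out_ch, 1, bias = FALSE), nn_batchnorm2d(out_ch)
  )
  shortcut <- if (stride != 1 || in_ch != out_ch) {
    nn_sequential(
      nn_conv2d(in_ch, out_ch, 1, stride = stride, bias = FALSE),
      nn_batchnorm2d(out_ch)
    )
  } else NULL
  nn_sequential(nn_residual(main, shortcut), nn_relu())
}

build_resnet_features <- function(blocks, bottleneck = FALSE, base_width = 64L) {
  w <- as.integer(base_width)
  stem <- list(
    nn_conv2d(3, w, 7, stride = 2, pad = 3, bias = FALSE),
    nn_batchnorm2d(w), nn_relu(),
    nn_maxpool2d(3, stride = 2, pad = 1)
  )
  stages <- list()
  in_ch <- w
  for (s in 1:4) {
    width <- w * 2L^(s - 1L)
    stride <- if (s == 1) 1L else 2L
    for (b in seq_len(blocks[s])) {
      st <- if (b == 1) stride else 1L
      blk <- if (bottleneck) resnet_bottleneck(in_ch, width, st)
             else resnet_basic_block(in_ch, width, st)
      stages[[length(stages) + 1L]] <- blk
      in_ch <- if (bottleneck) width * 4L else width
    }
  }
  list(mod = nn_sequential(c(stem, stages)), out_ch = in_ch)
}

## ---- DenseNet -------------------------------------------------------------

dense_layer <- function(in_ch, growth, bn_size = 4L) {
  f <- nn_sequential(
    nn_batchnorm2d(in_ch), nn_relu(),
    nn_conv2d(in_ch, bn_size * growth, 1, bias = FALSE),
    nn_batchnorm2d(bn_size * growth), nn_relu(),
    nn_conv2d(bn_size * growth, growth, 3, pad = 1, bias = FALSE)
  )
  nn_parallel_concat(list(keep = nn_identity(), new = f))
}

build_densenet_features <- function(blocks, growth, init_ch) {
  mods <- list(
    nn_conv2d(3, init_ch, 7, stride = 2, pad = 3, bias = FALSE),
    nn_batchnorm2d(init_ch), nn_relu(),
    nn_maxpool2d(3, stride = 2, pad = 1)
  )
  ch <- init_ch
  for (s in seq_along(blocks)) {
    for (l in seq_len(blocks[s])) {
      mods[[length(mods) + 1L]] <- dense_layer(ch, growth)
      ch <- ch + growth
    }
    if (s < length(blocks)) {
      out <- ch %/% 2L
      mods[[length(mods) + 1L]] <- nn_sequential(
        nn_batchnorm2d(ch), nn_relu(),
        nn_conv2d(ch, out, 1, bias = FALSE),
        nn_avgpool2d(2, stride = 2)
      )
      ch <- out
    }
  }
  mods[[length(mods) + 1L]] <- nn_batchnorm2d(ch)
  mods[[length(mods) + 1L]] <- nn_relu()
  list(mod = nn_sequential(mods), out_ch = ch)
}

## ---- GoogLeNet ------------------------------------------------------------

inception <- function(in_ch, c1, c2a, c2b, c3a, c3b, c4) {
  nn_parallel_concat(list(
    b1 = conv_bn_act(in_ch, c1, 1),
    b2 = nn_sequential(conv_bn_act(in_ch, c2a, 1),
                       conv_bn_act(c2a, c2b, 3, pad = 1)),
    b3 = nn_sequential(conv_bn_act(in_ch, c3a, 1),
                       conv_bn_act(c3a, c3b, 3, pad = 1)),
    b4 = nn_sequential(nn_maxpool2d(3, stride = 1, pad = 1, ceil = TRUE),
                       conv_bn_act(in_ch, c4, 1))
  ))
}

build_googlenet_features <- function() {
  mod <- nn_sequential(
    conv_bn_act(3, 64, 7, stride = 2, pad = 3),
    nn_maxpool2d(3, stride = 2, ceil = TRUE),
    conv_bn_act(64, 64, 1),
    conv_bn_act(64, 192, 3, pad = 1),
    nn_maxpool2d(3, stride = 2, ceil = TRUE),
    inception(192, 64, 96, 128, 16, 32, 32),
    inception(256, 128, 128, 192, 32, 96, 64),
    nn_maxpool2d(3, stride = 2, ceil = TRUE),
    inception(480, 192, 96, 208, 16, 48, 64),
    inception(512, 160, 112, 224, 24, 64, 64),
    inception(512, 128, 128, 256, 24, 64, 64),
    inception(512, 112, 144, 288, 32, 64, 64),
    inception(528, 256, 160, 320, 32, 128, 128),
    nn_maxpool2d(2, stride = 2, ceil = TRUE),
    inception(832, 256, 160, 320, 32, 128, 128),
    inception(832, 384, 192, 384, 48, 128, 128)
  )
  list(mod = mod, out_ch = 1024L)
}

## ---- squeeze-and-excitation -----------------------------------------------

#' Squeeze-and-excitation gate
#'
#' Global-average channel descriptor through a two-layer bottleneck MLP
#' (with biases), gating the feature map per channel.
#'
#' @param ch Channel count.
#' @param squeeze Bottleneck width.
#' @param act Inner activation constructor (ReLU or SiLU).
#' @param gate Gate constructor (sigmoid or hard sigmoid).
#' @return A module.
#' @export
nn_se <- function(ch, squeeze, act = nn_relu, gate = nn_sigmoid) {
  new_module("nn_se",
             children = list(fc1 = nn_linear(ch, squeeze),
                             act = act(),
                             fc2 = nn_linear(squeeze, ch),
                             gate = gate()),
             ch = ch, squeeze = squeeze)
}

#' @export
nn_forward.nn_se <- function(mod, x) {
  d <- dim(x)
  HW <- d[1] * d[2]
  p <- gap_fwd(x)                                  # N x C
  g1 <- nn_forward(mod$children$fc1, p$y)
  g2 <- nn_forward(mod$children$act, g1)
  g3 <- nn_forward(mod$children$fc2, g2)
  a <- nn_forward(mod$children$gate, g3)           # N x C
  arep <- rep(t(a), each = HW)
  mod$cache <- list(x = x, arep = arep, d = d)
  x * arep
}

#' @export
nn_backward.nn_se <- function(mod, gy) {
  cc <- mod$cache
  d <- cc$d; HW <- d[1] * d[2]
  gx <- gy * cc$arep
  prod <- gy * cc$x
  dim(prod) <- c(HW, d[3], d[4])
  ga <- t(colSums(prod))
  g <- nn_backward(mod$children$gate, ga)
  g <- nn_backward(mod$children$fc2, g)
  g <- nn_backward(mod$children$act, g)
  g <- nn_backward(mod$children$fc1, g)            # N x C at pooled input
  gx + gap_bwd(g, d)
}

#' @export
nn_trace.nn_se <- function(mod, shape) {
  list(shape = shape, macs = 2 * mod$ch * mod$squeeze)
}

## ---- MobileNetV3 (small) --------------------------------------------------

make_divisible <- function(v, divisor = 8L) {
  nv <- max(divisor, (as.integer(v + divisor / 2) %/% divisor) * divisor)
  if (nv < 0.9 * v) nv <- nv + divisor
  as.integer(nv)
}

mbv3_block <- function(in_ch, exp_ch, out_ch, kernel, stride, use_se, act) {
  mods <- list()
  if (exp_ch != in_ch) {
    mods[[length(mods) + 1L]] <- conv_bn_act(in_ch, exp_ch, 1, act = act)
  }
  mods[[length(mods) + 1L]] <- conv_bn_act(exp_ch, exp_ch, kernel,
                                           stride = stride,
                                           pad = (kernel - 1L) %/% 2L,
                                           act = act, groups = exp_ch)
  if (use_se) {
    mods[[length(mods) + 1L]] <- nn_se(exp_ch, make_divisible(exp_ch / 4),
                                       act = nn_relu, gate = nn_hardsigmoid)
  }
  mods[[length(mods) + 1L]] <- nn_sequential(
    nn_conv2d(exp_ch, out_ch, 1, bias = FALSE), nn_batchnorm2d(out_ch))
  main <- nn_sequential(mods)
  if (stride == 1 && in_ch == out_ch) nn_residual(main) else main
}

build_mobilenet_v3_small_features <- function() {
  cfg <- list(
    # kernel, expanded, out, SE, activation, stride
    list(3, 16, 16, TRUE, nn_relu, 2),
    list(3, 72, 24, FALSE, nn_relu, 2),
    list(3, 88, 24, FALSE, nn_relu, 1),
    list(5, 96, 40, TRUE, nn_hardswish, 2),
    list(5, 240, 40, TRUE, nn_hardswish, 1),
    list(5, 240, 40, TRUE, nn_hardswish, 1),
    list(5, 120, 48, TRUE, nn_hardswish, 1),
    list(5, 144, 48, TRUE, nn_hardswish, 1),
    list(5, 288, 96, TRUE, nn_hardswish, 2),
    list(5, 576, 96, TRUE, nn_hardswish, 1),
    list(5, 576, 96, TRUE, nn_hardswish, 1)
  )
  mods <- list(conv_bn_act(3, 16, 3, stride = 2, pad = 1, act = nn_hardswish))
  in_ch <- 16L
  for (c in cfg) {
    mods[[length(mods) + 1L]] <- mbv3_block(in_ch, c[[2]], c[[3]], c[[1]],
                                            c[[6]], c[[4]], c[[5]])
    in_ch <- c[[3]]
  }
  mods[[length(mods) + 1L]] <- conv_bn_act(96, 576, 1, act = nn_hardswish)
  list(mod = nn_sequential(mods), out_ch = 576L)
}

mobilenet_v3_small_head <- function(num_outputs) {
  nn_sequential(nn_gap(), nn_linear(576, 1024), nn_hardswish(),
                nn_linear(1024, num_outputs))
}

## ---- EfficientNet-B0 ------------------------------------------------------

effnet_mbconv <- function(in_ch, out_ch, expand, kernel, stride) {
  exp_ch <- in_ch * expand
  mods <- list()
  if (expand != 1) {
    mods[[length(mods) + 1L]] <- conv_bn_act(in_ch, exp_ch, 1, act = nn_silu)
  }
  mods[[length(mods) + 1L]] <- conv_bn_act(exp_ch, exp_ch, kernel,
                                           stride = stride,
                                           pad = (kernel - 1L) %/% 2L,
                                           act = nn_silu, groups = exp_ch)
  mods[[length(mods) + 1L]] <- nn_se(exp_ch, max(1L, in_ch %/% 4L),
                                     act = nn_silu, gate = nn_sigmoid)
  mods[[length(mods) + 1L]] <- nn_sequential(
    nn_conv2d(exp_ch, out_ch, 1, bias = FALSE), nn_batchnorm2d(out_ch))
  main <- nn_sequential(mods)
  if (stride == 1 && in_ch == out_ch) nn_residual(main) else main
}

build_efficientnet_b0_features <- function() {
  cfg <- list(
    # expand, kernel, stride, in, out, repeats
    list(1, 3, 1, 32, 16, 1),
    list(6, 3, 2, 16, 24, 2),
    list(6, 5, 2, 24, 40, 2),
    list(6, 3, 2, 40, 80, 3),
    list(6, 5, 1, 80, 112, 3),
    list(6, 5, 2, 112, 192, 4),
    list(6, 3, 1, 192, 320, 1)
  )
  mods <- list(conv_bn_act(3, 32, 3, stride = 2, pad = 1, act = nn_silu))
  for (c in cfg) {
    for (r in seq_len(c[[6]])) {
      in_ch <- if (r == 1) c[[4]] else c[[5]]
      st <- if (r == 1) c[[3]] else 1
      mods[[length(mods) + 1L]] <- effnet_mbconv(in_ch, c[[5]], c[[1]],
                                                 c[[2]], st)
    }
  }
  mods[[length(mods) + 1L]] <- conv_bn_act(320, 1280, 1, act = nn_silu)
  list(mod = nn_sequential(mods), out_ch = 1280L)
}

## ---- public surface -------------------------------------------------------

backbone_names <- c("resnet18", "resnet50", "resnet101", "densenet121",
                    "densenet161", "googlenet", "mobilenet_v3", "efficientnet")

# Truncated feature extractor of a named backbone (no classification head,
# so no head weights are drawn from the RNG stream).
backbone_features <- function(name, base_width = 64) {
  if (!name %in% backbone_names) {
    stop_thanet("unknown backbone '", name, "'; supported: ",
                paste(backbone_names, collapse = ", "))
  }
  switch(name,
    resnet18 = build_resnet_features(c(2, 2, 2, 2), FALSE, base_width),
    resnet50 = build_resnet_features(c(3, 4, 6, 3), TRUE, base_width),
    resnet101 = build_resnet_features(c(3, 4, 23, 3), TRUE, base_width),
    densenet121 = build_densenet_features(c(6, 12, 24, 16), 32L, 64L),
    densenet161 = build_densenet_features(c(6, 12, 36, 24), 48L, 96L),
    googlenet = build_googlenet_features(),
    mobilenet_v3 = build_mobilenet_v3_small_features(),
    efficientnet = build_efficientnet_b0_features()
  )
}

#' Construct a classification backbone with a replaced head
#'
#' Builds one of the standard architectures with its final fully-connected
#' layer replaced by a `num_outputs`-way linear head. `mobilenet_v3` is the
#' small variant; `efficientnet` is B0. Initialisation draws from the current
#' RNG stream (seed with [set.seed()] for reproducible weights).
#'
#' @param name One of `"resnet18"`, `"resnet50"`, `"resnet101"`,
#'   `"densenet121"`, `"densenet161"`, `"googlenet"`, `"mobilenet_v3"`,
#'   `"efficientnet"`.
#' @param num_outputs Output score count (7 for the complication panel, 1 for
#'   a binary task).
#' @param pretrained `FALSE` for random initialisation (the offline default),
#'   or a path to an `.rds` state snapshot previously written by
#'   [save_checkpoint()].
#' @param base_width Stem width for the ResNet family (default 64; smaller
#'   values give proportionally scaled-down models for quick experiments).
#' @return A `backbone_handle`: list with `model` (full classifier),
#'   `features` (truncated extractor), `head`, `name`, `feature_channels`,
#'   `feature_stride` and `num_outputs`.
#' @export
build_backbone <- function(name, num_outputs = 7, pretrained = FALSE,
                           base_width = 64) {
  f <- backbone_features(name, base_width)
  head <- if (name == "mobilenet_v3") {
    mobilenet_v3_small_head(num_outputs)
  } else {
    nn_gap_linear_head(f$out_ch, num_outputs)
  }
  model <- nn_sequential(features = f$mod, head = head)
  names(model$children) <- c("features", "head")
  handle <- list(name = name, model = model, features = f$mod, head = head,
                 feature_channels = f$out_ch, feature_stride = 32L,
                 num_outputs = num_outputs)
  class(handle) <- "backbone_handle"
  if (!isFALSE(pretrained)) {
    if (!is.character(pretrained) || !file.exists(pretrained)) {
      stop_thanet("pretrained must be FALSE or a path to an .rds state file")
    }
    nn_load_state(model, readRDS(pretrained))
  }
  handle
}

#' @export
print.backbone_handle <- function(x, ...) {
  cat("backbone:", x$name, "| outputs:", x$num_outputs,
      "| feature channels:", x$feature_channels,
      "| params:", fmt_num(count_parameters(x$model)), "\n")
  invisible(x)
}
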
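# Independent oracles used across the suite. These deliberately use naive
# scalar loops so they share no code path with the package implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Triple-loop dense 2-D convolution on H x W x C x N arrays.
naive_conv2d <- function(x, w, b, stride, pad) {
  d <- dim(x)
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  ho <- (d[1] + 2 * pad - kh) %/% stride + 1
  wo <- (d[2] + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(ho, wo, cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(cout)) {
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(d[3])) for (a in seq_len(kh)) for (bb in seq_len(kw)) {
        acc <- acc + xp[(i - 1) * stride + a, (j - 1) * stride + bb, ci, n] *
          w[a, bb, ci, co]
      }
      y[i, j, co, n] <- acc
    }
  }
  y
}

# Explicit rank-loop average precision.
brute_ap <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  s <- labels[ord]
  total <- 0
  hits <- 0
  for (r in seq_along(s)) {
    if (s[r] == 1) {
      hits <- hits + 1
      total <- total + hits / r
    }
  }
  total / sum(labels)
}

# Explicit support-weighted precision/recall/F1 from thresholded scores.
brute_weighted_prf1 <- function(scores, labels, threshold = 0.5) {
  pred <- (1 / (1 + exp(-scores)) >= threshold) * 1
  C <- ncol(labels)
  sup <- colSums(labels)
  ps <- rs <- fs <- numeric(C)
  for (k in seq_len(C)) {
    tp <- sum(pred[, k] == 1 & labels[, k] == 1)
    fp <- sum(pred[, k] == 1 & labels[, k] == 0)
    fn <- sum(pred[, k] == 0 & labels[, k] == 1)
    ps[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rs[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    fs[k] <- if (ps[k] + rs[k] > 0) 2 * ps[k] * rs[k] / (ps[k] + rs[k]) else 0
  }
  w <- sup / sum(sup)
  c(precision = sum(w * ps), recall = sum(w * rs), f1 = sum(w * fs))
}

# Central-difference gradient of a scalar function of an array.
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Relative max-abs error, guarded for small scales.
rel_err <- function(a, b) max(abs(a - b)) / max(1, max(abs(b)))

# Gradient-check a module against finite differences under a random linear
# functional of its output; checks input gradient and a parameter sample.
expect_gradcheck <- function(mod, xdim, grid = NULL, tol = 1e-6, seed = 42,
                             n_param = 4) {
  ns <- asNamespace("thanet")
  set.seed(seed)
  x <- array(rnorm(prod(xdim)), xdim)
  if (!is.null(grid)) attr(x, "grid") <- grid
  thanet:::nn_train_mode(mod, TRUE)
  y0 <- nn_forward(mod, x)
  w <- array(rnorm(length(y0)), dim(y0) %||% length(y0))
  loss <- function(xx) {
    if (!is.null(grid)) attr(xx, "grid") <- grid
    sum(w * nn_forward(mod, xx))
  }
  thanet:::nn_zero_grads(mod)
  nn_forward(mod, x)
  gin <- nn_backward(mod, w)
  expect_lt(rel_err(gin, num_grad(loss, x)), tol)
  refs <- thanet:::nn_param_refs(mod)
  for (r in refs) {
    p <- r$mod$params[[r$name]]
    for (i in sample(length(p), min(n_param, length(p)))) {
      orig <- p[i]
      e <- 1e-5
      r$mod$params[[r$name]][i] <- orig + e; lp <- loss(x)
      r$mod$params[[r$name]][i] <- orig - e; lm <- loss(x)
      r$mod$params[[r$name]][i] <- orig
      ng <- (lp - lm) / (2 * e)
      expect_lt(abs(r$mod$grads[[r$name]][i] - ng) / max(1, abs(ng)), tol)
    }
  }
  invisible(TRUE)
}

# Small deterministic manifest data frame.
toy_records <- function(n = 3, seed = 1) {
  labs <- thanet::complication_labels()
  set.seed(seed)
  df <- data.frame(image = sprintf("img_%03d.png", seq_len(n)))
  for (l in labs) df[[l]] <- rbinom(n, 1, 0.4)
  df
}

tiny_model_cfg <- function(..., seed = 1) {
  model_config(input_size = 64, base_width = 8,
               gfs = list(patch = 4, embed = 8, window = 4, heads = c(2, 2, 2)),
               cfs = list(width = 16, reduction = 8), seed = seed, ...)
}
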
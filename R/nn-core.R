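# Module protocol.
#
# A module is an environment carrying:
#   params   named list of numeric arrays (trainable)
#   grads    list of matching shapes, accumulated by nn_backward()
#   state    non-trainable buffers (e.g. batch-norm running stats)
#   children named list of sub-modules
#   training logical flag toggled by nn_train_mode()
#   cache    forward-pass intermediates consumed by the next backward pass
#
# Three S3 generics define behaviour: nn_forward(), nn_backward() and
# nn_trace() (analytic shape/MAC propagation, no data required). Shapes are
# c(H, W, C) for feature maps (token grids use the same triple, read as
# grid-height, grid-width, embedding) and a single integer for flat feature
# vectors.

new_module <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  if (is.null(e$params)) e$params <- list()
  if (is.null(e$children)) e$children <- list()
  e$grads <- lapply(e$params, function(p) p * 0)
  e$training <- TRUE
  e$cache <- NULL
  class(e) <- c(class, "nn_module")
  e
}

#' Run a module forward
#'
#' @param mod A module built by one of the `nn_*` constructors.
#' @param x Input array; feature maps are `H x W x C x N` arrays, flat
#'   features are `N x F` matrices, token grids are `L x C x N` arrays with a
#'   `grid` attribute.
#' @return The module output (same conventions).
#' @export
nn_forward <- function(mod, x) UseMethod("nn_forward")

#' Backpropagate through a module
#'
#' Must follow a call to [nn_forward()] on the same module; accumulates
#' parameter gradients into the module and returns the input gradient.
#'
#' @param mod A module.
#' @param gy Gradient of the loss with respect to the module output.
#' @return Gradient with respect to the module input.
#' @export
nn_backward <- function(mod, gy) UseMethod("nn_backward")

#' Analytic shape and multiply-accumulate propagation
#'
#' Propagates an input shape through a module without running any data,
#' returning the output shape and the MAC count. Convolutions count
#' `out-positions x kernel-volume x in-channels/groups x out-channels`,
#' linear layers `in x out`, and normalisation layers one MAC per output
#' element (a fused scale-shift); activations and pooling count zero.
#'
#' @param mod A module.
#' @param shape Input shape: `c(H, W, C)` or a single feature count.
#' @return A list with `shape` (output shape) and `macs`.
#' @export
nn_trace <- function(mod, shape) UseMethod("nn_trace")

#' @export
print.nn_module <- function(x, ...) {
  cat("<", class(x)[1], "> params: ", fmt_num(nn_count_params(x)), "\n",
      sep = "")
  invisible(x)
}

# Depth-first list of (module, param-name) references.
nn_param_refs <- function(mod) {
  refs <- list()
  for (nm in names(mod$params)) {
    refs[[length(refs) + 1L]] <- list(mod = mod, name = nm)
  }
  for (ch in mod$children) refs <- c(refs, nn_param_refs(ch))
  refs
}

#' Count trainable parameters of a model
#'
#' Sums the element counts of every trainable array in the module tree.
#' Non-trainable buffers (batch-norm running statistics) are excluded, as are
#' parameters of frozen sub-modules (`mod$frozen <- TRUE`).
#'
#' @param model A module.
#' @return Integer-valued double: total trainable parameter count.
#' @export
count_parameters <- function(model) nn_count_params(model)

nn_count_params <- function(mod) {
  if (isTRUE(mod$frozen)) return(0)
  n <- sum(vapply(mod$params, length, numeric(1)))
  for (ch in mod$children) n <- n + nn_count_params(ch)
  n
}

nn_zero_grads <- function(mod) {
  for (nm in names(mod$grads)) mod$grads[[nm]][] <- 0
  for (ch in mod$children) nn_zero_grads(ch)
  invisible(mod)
}

nn_train_mode <- function(mod, training = TRUE) {
  mod$training <- training
  for (ch in mod$children) nn_train_mode(ch, training)
  invisible(mod)
}

# Flat named snapshot of all parameters and buffers (checkpointing).
nn_state <- function(mod, prefix = "") {
  out <- list()
  for (nm in names(mod$params)) out[[paste0(prefix, "p:", nm)]] <- mod$params[[nm]]
  for (nm in names(mod$state)) out[[paste0(prefix, "s:", nm)]] <- mod$state[[nm]]
  chn <- names(mod$children)
  for (i in seq_along(mod$children)) {
    out <- c(out, nn_state(mod$children[[i]], paste0(prefix, chn[i], "/")))
  }
  out
}

nn_load_state <- function(mod, state, prefix = "") {
  for (nm in names(mod$params)) {
    key <- paste0(prefix, "p:", nm)
    if (!key %in% names(state)) stop_thanet("missing parameter in state: ", key)
    mod$params[[nm]] <- state[[key]]
  }
  for (nm in names(mod$state)) {
    key <- paste0(prefix, "s:", nm)
    if (key %in% names(state)) mod$state[[nm]] <- state[[key]]
  }
  chn <- names(mod$children)
  for (i in seq_along(mod$children)) {
    nn_load_state(mod$children[[i]], state, paste0(prefix, chn[i], "/"))
  }
  invisible(mod)
}

## ---- containers -----------------------------------------------------------

#' Sequential container
#' @param ... Modules, applied in order.
#' @return A module.
#' @export
nn_sequential <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1]]) && !inherits(ch[[1]], "nn_module")) {
    ch <- ch[[1]]
  }
  names(ch) <- sprintf("m%02d", seq_along(ch))
  new_module("nn_sequential", children = ch)
}

#' @export
nn_forward.nn_sequential <- function(mod, x) {
  for (ch in mod$children) x <- nn_forward(ch, x)
  x
}

#' @export
nn_backward.nn_sequential <- function(mod, gy) {
  for (ch in rev(mod$children)) gy <- nn_backward(ch, gy)
  gy
}

#' @export
nn_trace.nn_sequential <- function(mod, shape) {
  macs <- 0
  for (ch in mod$children) {
    tr <- nn_trace(ch, shape)
    shape <- tr$shape
    macs <- macs + tr$macs
  }
  list(shape = shape, macs = macs)
}

#' Residual wrapper: `y = main(x) + shortcut(x)`
#'
#' The shortcut defaults to the identity. Works for feature maps and token
#' arrays alike (token `grid` attribute is taken from the main branch).
#'
#' @param main Main-branch module.
#' @param shortcut Optional shortcut module (identity when `NULL`).
#' @return A module.
#' @export
nn_residual <- function(main, shortcut = NULL) {
  ch <- list(main = main)
  if (!is.null(shortcut)) ch$shortcut <- shortcut
  new_module("nn_residual", children = ch)
}

#' @export
nn_forward.nn_residual <- function(mod, x) {
  y <- nn_forward(mod$children$main, x)
  s <- if (!is.null(mod$children$shortcut)) {
    nn_forward(mod$children$shortcut, x)
  } else x
  out <- y + s
  attr(out, "grid") <- attr(y, "grid", exact = TRUE)
  out
}

#' @export
nn_backward.nn_residual <- function(mod, gy) {
  gx <- nn_backward(mod$children$main, gy)
  gs <- if (!is.null(mod$children$shortcut)) {
    nn_backward(mod$children$shortcut, gy)
  } else gy
  gx + gs
}

#' @export
nn_trace.nn_residual <- function(mod, shape) {
  tr <- nn_trace(mod$children$main, shape)
  if (!is.null(mod$children$shortcut)) {
    tr$macs <- tr$macs + nn_trace(mod$children$shortcut, shape)$macs
  }
  tr
}

#' Parallel branches concatenated along the channel axis
#'
#' Every branch receives the same input; outputs must agree in spatial size
#' and are concatenated channel-wise.
#'
#' @param branches Named list of modules.
#' @return A module.
#' @export
nn_parallel_concat <- function(branches) {
  new_module("nn_parallel_concat", children = branches)
}

#' @export
nn_forward.nn_parallel_concat <- function(mod, x) {
  ys <- lapply(mod$children, nn_forward, x = x)
  dims <- lapply(ys, dim)
  ref <- dims[[1]]
  for (d in dims) {
    if (d[1] != ref[1] || d[2] != ref[2] || d[4] != ref[4]) {
      stop_thanet("branch outputs disagree in spatial/batch dims")
    }
  }
  chs <- vapply(dims, function(d) d[3], numeric(1))
  out <- array(0, c(ref[1], ref[2], sum(chs), ref[4]))
  at <- 0L
  for (i in seq_along(ys)) {
    out[, , at + seq_len(chs[i]), ] <- ys[[i]]
    at <- at + chs[i]
  }
  mod$cache <- list(chs = chs)
  out
}

#' @export
nn_backward.nn_parallel_concat <- function(mod, gy) {
  chs <- mod$cache$chs
  gx <- NULL
  at <- 0L
  for (i in seq_along(mod$children)) {
    g <- nn_backward(mod$children[[i]], gy[, , at + seq_len(chs[i]), , drop = FALSE])
    gx <- if (is.null(gx)) g else gx + g
    at <- at + chs[i]
  }
  gx
}

#' @export
nn_trace.nn_parallel_concat <- function(mod, shape) {
  trs <- lapply(mod$children, nn_trace, shape = shape)
  sh <- trs[[1]]$shape
  sh[3] <- sum(vapply(trs, function(t) t$shape[3], numeric(1)))
  list(shape = sh, macs = sum(vapply(trs, function(t) t$macs, numeric(1))))
}

## ---- optimiser ------------------------------------------------------------

# Adam with in-place updates through module references.
adam_new <- function(model, lr = 2e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  refs <- Filter(function(r) !isTRUE(r$mod$frozen), nn_param_refs(model))
  opt <- new.env(parent = emptyenv())
  opt$refs <- refs
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(refs, function(r) 0 * r$mod$params[[r$name]])
  opt$v <- lapply(refs, function(r) 0 * r$mod$params[[r$name]])
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$refs)) {
    r <- opt$refs[[i]]
    g <- r$mod$grads[[r$name]]
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    mh <- opt$m[[i]] / bc1
    vh <- opt$v[[i]] / bc2
    r$mod$params[[r$name]] <- r$mod$params[[r$name]] - opt$lr * mh / (sqrt(vh) + opt$eps)
  }
  invisible(opt)
}
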
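# Multi-branch assembly: backbone + optional global feature stream (GFS) +
# optional channel feature stream (CFS), fused by channel concatenation at
# the shared 1/32-resolution feature map, then scored by either the plain
# GAP+linear head or the MC-CSRA head. Any ablation subset is expressible.

#' Model configuration
#'
#' Declarative description of a multi-branch model: which streams and head
#' are enabled plus every architectural hyperparameter left open by the
#' design. The defaults describe the full-scale proposed model (224-pixel
#' input); `base_width`, `gfs` and `cfs` can be scaled down together for
#' quick CPU experiments.
#'
#' @param backbone Backbone name, see [build_backbone()].
#' @param use_gfs,use_cfs,use_mc_csra Stream/head toggles.
#' @param n_classes Output count (7-label panel by default).
#' @param input_size Input side in pixels; must be a multiple of 32 so all
#'   branches land on the same grid.
#' @param seed Optional seed for weight initialisation.
#' @param base_width ResNet stem width (64 = canonical).
#' @param gfs List of GFS hyperparameters: `patch`, `embed`, `window`,
#'   `heads` (three head counts).
#' @param cfs List of CFS hyperparameters: `width`, `reduction`.
#' @param coef_init,coef_noise_sd MC-CSRA coefficient initialisation, see
#'   [nn_coef()].
#' @return A `model_config` list.
#' @export
model_config <- function(backbone = "resnet18", use_gfs = FALSE,
                         use_cfs = FALSE, use_mc_csra = FALSE, n_classes = 7,
                         input_size = 224, seed = NULL, base_width = 64,
                         gfs = list(), cfs = list(),
                         coef_init = "identity_noise", coef_noise_sd = 0.01) {
  gfs_def <- list(patch = 4, embed = 96, window = 7, heads = c(3, 6, 12))
  cfs_def <- list(width = 64, reduction = 16)
  gfs <- utils::modifyList(gfs_def, gfs)
  cfs <- utils::modifyList(cfs_def, cfs)
  if (input_size %% 32 != 0) {
    stop_thanet("input_size must be a multiple of 32 (all branches emit ",
                "1/32-resolution maps)")
  }
  if (n_classes < 1) stop_thanet("n_classes must be at least 1")
  structure(list(backbone = backbone, use_gfs = use_gfs, use_cfs = use_cfs,
                 use_mc_csra = use_mc_csra, n_classes = n_classes,
                 input_size = input_size, seed = seed,
                 base_width = base_width, gfs = gfs, cfs = cfs,
                 coef_init = coef_init, coef_noise_sd = coef_noise_sd),
            class = "model_config")
}

#' Assemble a multi-branch model from a configuration
#'
#' Enabled streams each map the input image to a feature block at 1/32 of
#' the input resolution; blocks are concatenated channel-wise and scored by
#' the configured head. With every extra stream disabled and the plain head,
#' the model is exactly the backbone classifier of [build_backbone()]
#' (identical weights under the same seed).
#'
#' @param cfg A [model_config()].
#' @return A `tha_model`: list with `module` (the network), `cfg`,
#'   `feature_channels` (per branch) and `branches`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  builder <- function() {
    bf <- backbone_features(cfg$backbone, cfg$base_width)
    branches <- list(backbone = bf$mod)
    chans <- c(backbone = bf$out_ch)
    if (cfg$use_gfs) {
      branches$gfs <- build_gfs(cfg$gfs$patch, cfg$gfs$embed, cfg$gfs$window,
                                cfg$gfs$heads)
      chans["gfs"] <- 8 * cfg$gfs$embed
    }
    if (cfg$use_cfs) {
      branches$cfs <- build_cfs(cfg$cfs$width, cfg$cfs$reduction)
      chans["cfs"] <- cfg$cfs$width
    }
    total <- sum(chans)
    trunk <- if (length(branches) == 1) branches[[1]] else
      nn_parallel_concat(branches)
    head <- if (cfg$use_mc_csra) {
      nn_mc_csra(total, cfg$n_classes, cfg$coef_init, cfg$coef_noise_sd)
    } else {
      nn_gap_linear_head(total, cfg$n_classes)
    }
    module <- nn_sequential(trunk, head)
    names(module$children) <- c("trunk", "head")
    structure(list(module = module, cfg = cfg, feature_channels = chans,
                   branches = names(branches)),
              class = "tha_model")
  }
  if (!is.null(cfg$seed)) with_seed(cfg$seed, builder()) else builder()
}

#' @export
print.tha_model <- function(x, ...) {
  cat("multi-branch model:", paste(x$branches, collapse = " + "),
      if (x$cfg$use_mc_csra) "+ MC-CSRA head" else "+ GAP/linear head", "\n")
  cat("  classes:", x$cfg$n_classes,
      "| params:", fmt_num(count_parameters(x$module)), "\n")
  invisible(x)
}

model_module <- function(model) {
  if (inherits(model, "tha_model")) model$module
  else if (inherits(model, "backbone_handle")) model$model
  else if (inherits(model, "nn_module")) model
  else stop_thanet("not a model")
}

#' Forward pass producing logits
#' @param model A `tha_model`, `backbone_handle` or raw module.
#' @param x Image batch `H x W x 3 x N`.
#' @param training Run layers in training mode (batch statistics)?
#' @return `N x n_classes` logit matrix.
#' @export
model_forward <- function(model, x, training = FALSE) {
  m <- model_module(model)
  nn_train_mode(m, training)
  nn_forward(m, x)
}

#' Model complexity report
#'
#' Parameters by exact summation over the module tree, multiply-accumulate
#' count by analytic per-layer accounting at the stated input size (see
#' [nn_trace()] for the conventions), and mean wall-clock seconds for a
#' single-image forward pass after one warm-up.
#'
#' @param model A model (any form accepted by [model_forward()]).
#' @param input_size Input side in pixels.
#' @param time_reps Timed repetitions (0 skips timing).
#' @return A `complexity_report`: list with `params`, `macs`,
#'   `inference_seconds`, `input_size`.
#' @export
complexity <- function(model, input_size = 224, time_reps = 3) {
  m <- model_module(model)
  tr <- nn_trace(m, c(input_size, input_size, 3))
  secs <- NA_real_
  if (time_reps > 0) {
    nn_train_mode(m, FALSE)
    x <- array(stats::runif(input_size * input_size * 3),
               c(input_size, input_size, 3, 1))
    nn_forward(m, x)                               # warm-up
    t0 <- proc.time()[["elapsed"]]
    for (i in seq_len(time_reps)) nn_forward(m, x)
    secs <- (proc.time()[["elapsed"]] - t0) / time_reps
  }
  structure(list(params = count_parameters(m), macs = tr$macs,
                 inference_seconds = secs, input_size = input_size),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("params: %.2f x10^6 | MACs @%d px: %.2f x10^9 | inference: %s s\n",
              x$params / 1e6, x$input_size, x$macs / 1e9,
              ifelse(is.na(x$inference_seconds), "-",
                     format(x$inference_seconds, digits = 3))))
  invisible(x)
}
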
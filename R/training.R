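# Optimisation loop and experiment protocols.
#
# Multi-label models are trained with per-label binary cross-entropy on
# sigmoid logits under Adam. The learning rate starts at 2e-4 and is
# multiplied by 0.9 whenever the validation loss has failed to improve
# (beyond a small tolerance) for 5 consecutive epochs; training stops early
# after `early_stop_patience` epochs without improvement. Batch order is
# reshuffled per epoch from the configured seed, so runs are fully
# deterministic.

#' Training configuration
#'
#' @param lr0 Initial learning rate.
#' @param lr_decay_factor Multiplier applied on a validation-loss plateau
#'   (0.9 = "reduced by 10 percent").
#' @param plateau_patience Epochs without improvement before each decay.
#' @param plateau_tol Minimum decrease in validation loss that counts as an
#'   improvement.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch budget.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param loss `"bce_multilabel"` or `"bce_binary"`.
#' @param seed Integer seed driving batch order and any split derived from
#'   this configuration.
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 2e-4, lr_decay_factor = 0.9,
                         plateau_patience = 5, plateau_tol = 1e-4,
                         batch_size = 32, max_epochs = 50,
                         early_stop_patience = 10,
                         loss = c("bce_multilabel", "bce_binary"), seed = 1) {
  loss <- match.arg(loss)
  stopifnot(lr0 > 0, lr_decay_factor > 0, lr_decay_factor < 1,
            plateau_patience >= 1, batch_size >= 1, max_epochs >= 1)
  structure(list(lr0 = lr0, lr_decay_factor = lr_decay_factor,
                 plateau_patience = plateau_patience,
                 plateau_tol = plateau_tol, batch_size = batch_size,
                 max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience, loss = loss,
                 seed = seed), class = "train_config")
}

# Numerically stable binary cross-entropy with logits; returns mean loss and
# the logit gradient of the mean.
bce_with_logits <- function(z, y) {
  l <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  g <- (stats::plogis(z) - y) / length(z)
  list(loss = l, grad = g)
}

#' Predict logits in evaluation mode
#' @param model Model (any form accepted by [model_forward()]).
#' @param x Image tensor `H x W x 3 x N`.
#' @param batch_size Forward batch size.
#' @return `N x C` logit matrix.
#' @export
predict_scores <- function(model, x, batch_size = 32) {
  m <- model_module(model)
  nn_train_mode(m, FALSE)
  n <- dim(x)[4]
  out <- NULL
  for (at in seq(1, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1, n)
    z <- nn_forward(m, x[, , , idx, drop = FALSE])
    out <- rbind(out, z)
  }
  out
}

#' Train one model on fixed train/validation tensors
#'
#' Adam optimisation of the configured loss with reduce-on-plateau learning
#' rate decay and early stopping on the validation loss.
#'
#' @param model A `tha_model` (or raw module).
#' @param data_train,data_val Lists with `x` (`H x W x 3 x N` tensor) and
#'   `y` (`N x C` binary matrix).
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress?
#' @return List with `model`, `curves` (data frame: epoch, lr, train_loss,
#'   val_loss), `stopped_epoch`, `best_val`.
#' @export
train_one <- function(model, data_train, data_val, cfg = train_config(),
                      verbose = FALSE) {
  m <- model_module(model)
  n_tr <- dim(data_train$x)[4]
  if (n_tr == 0 || dim(data_val$x)[4] == 0) stop_thanet("empty split")
  if (is.vector(data_train$y)) data_train$y <- matrix(data_train$y)
  if (is.vector(data_val$y)) data_val$y <- matrix(data_val$y)
  opt <- adam_new(m, lr = cfg$lr0)
  curves <- NULL
  best_val <- Inf
  best_state <- NULL
  bad <- 0L
  stopped <- cfg$max_epochs
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, epoch), sample.int(n_tr))
    nn_train_mode(m, TRUE)
    tr_loss <- 0
    nb <- 0L
    for (at in seq(1, n_tr, by = cfg$batch_size)) {
      idx <- ord[at:min(at + cfg$batch_size - 1, n_tr)]
      xb <- data_train$x[, , , idx, drop = FALSE]
      yb <- data_train$y[idx, , drop = FALSE]
      nn_zero_grads(m)
      z <- nn_forward(m, xb)
      l <- bce_with_logits(z, yb)
      if (!is.finite(l$loss)) {
        stop_thanet("non-finite training loss at epoch ", epoch,
                    " (lr = ", format(opt$lr), ")")
      }
      nn_backward(m, l$grad)
      adam_step(opt)
      tr_loss <- tr_loss + l$loss
      nb <- nb + 1L
    }
    tr_loss <- tr_loss / nb
    zv <- predict_scores(m, data_val$x, cfg$batch_size)
    val_loss <- bce_with_logits(zv, data_val$y)$loss
    curves <- rbind(curves, data.frame(epoch = epoch, lr = opt$lr,
                                       train_loss = tr_loss,
                                       val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %2d lr %.2e train %.4f val %.4f", epoch,
                      opt$lr, tr_loss, val_loss))
    }
    if (val_loss < best_val - cfg$plateau_tol) {
      best_val <- val_loss
      best_state <- nn_state(m)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad %% cfg$plateau_patience == 0L) {
        opt$lr <- opt$lr * cfg$lr_decay_factor
      }
      if (bad >= cfg$early_stop_patience) {
        stopped <- epoch
        break
      }
    }
  }
  if (!is.null(best_state)) nn_load_state(m, best_state)
  list(model = model, curves = curves, stopped_epoch = stopped,
       best_val = best_val)
}

#' Five-fold cross-validation experiment
#'
#' Builds the fold plan once (so paired ablation arms trained with the same
#' `train_cfg$seed` share identical folds and batch orders), trains a fresh
#' model per fold on the remaining folds, and evaluates the held-out fold.
#' The aggregate report is the arithmetic mean of the per-fold values.
#'
#' @param data List with `x` (image tensor) and `y` (label matrix), e.g.
#'   from [phantom_tensors()] or [load_image_batch()] + [label_matrix()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param n_folds Fold count.
#' @param val_fraction Fraction of each training split held out as the
#'   validation set steering the plateau/early-stop rules.
#' @param verbose Print progress?
#' @return An `experiment_result`: list with `folds` (per-fold
#'   `metrics_report`s), `aggregate` (mean mAP / weighted P,R,F1 / per-class
#'   accuracy and F1), `fold_plan`, `model_cfg`, `train_cfg`.
#' @export
run_crossval <- function(data, model_cfg, train_cfg = train_config(),
                         n_folds = 5, val_fraction = 0.15, verbose = FALSE) {
  n <- dim(data$x)[4]
  plan <- make_folds(n, n_folds, train_cfg$seed)
  reports <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_idx <- which(plan$assignments == f)
    pool <- which(plan$assignments != f)
    n_val <- max(1L, floor(val_fraction * length(pool)))
    vsel <- with_seed(derive_seed(train_cfg$seed, 1000 + f),
                      sample(pool, n_val))
    tr <- setdiff(pool, vsel)
    mc <- model_cfg
    mc$seed <- derive_seed(train_cfg$seed, 2000 + f)
    model <- build_model(mc)
    fit <- train_one(model,
                     list(x = data$x[, , , tr, drop = FALSE],
                          y = data$y[tr, , drop = FALSE]),
                     list(x = data$x[, , , vsel, drop = FALSE],
                          y = data$y[vsel, , drop = FALSE]),
                     train_cfg, verbose = verbose)
    z <- predict_scores(fit$model, data$x[, , , test_idx, drop = FALSE],
                        train_cfg$batch_size)
    reports[[f]] <- suppressWarnings(
      evaluate_predictions(z, data$y[test_idx, , drop = FALSE]))
    if (verbose) message("fold ", f, ": mAP ", round(reports[[f]]$map, 3))
  }
  agg <- list(
    map = mean(vapply(reports, function(r) r$map, numeric(1))),
    weighted = colMeans(do.call(rbind, lapply(reports, `[[`, "weighted"))),
    per_class_accuracy = colMeans(do.call(rbind, lapply(reports, function(r) {
      stats::setNames(r$per_class$accuracy, r$per_class$label)
    }))),
    per_class_f1 = colMeans(do.call(rbind, lapply(reports, function(r) {
      stats::setNames(r$per_class$f1, r$per_class$label)
    })))
  )
  structure(list(folds = reports, aggregate = agg, fold_plan = plan,
                 model_cfg = model_cfg, train_cfg = train_cfg),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("%d-fold CV | mean mAP %.3f | weighted P %.3f R %.3f F1 %.3f\n",
              x$fold_plan$n_folds, x$aggregate$map,
              x$aggregate$weighted[["precision"]],
              x$aggregate$weighted[["recall"]],
              x$aggregate$weighted[["f1"]]))
  invisible(x)
}

#' Single-complication binary task under a 6:2:2 protocol
#'
#' Splits the records 60/20/20 into train/validation/test, trains a
#' single-logit model and reports accuracy, precision, recall and F1 on the
#' test set.
#'
#' @param data List with `x` (image tensor) and `y` (binary vector, e.g. the
#'   loosening column).
#' @param model_cfg A [model_config()] with `n_classes = 1`.
#' @param train_cfg A [train_config()] (use `loss = "bce_binary"`).
#' @param verbose Print progress?
#' @return List with `metrics` (accuracy, precision, recall, f1), `split`,
#'   `curves`, `model`.
#' @export
run_binary_task <- function(data, model_cfg, train_cfg = train_config(),
                            verbose = FALSE) {
  y <- as.vector(data$y)
  if (length(unique(y)) < 2) {
    stop_thanet("binary task needs both classes present")
  }
  if (model_cfg$n_classes != 1) stop_thanet("model_cfg$n_classes must be 1")
  sp <- split_622(length(y), train_cfg$seed)
  mc <- model_cfg
  if (is.null(mc$seed)) mc$seed <- derive_seed(train_cfg$seed, 77)
  model <- build_model(mc)
  fit <- train_one(model,
                   list(x = data$x[, , , sp$train, drop = FALSE],
                        y = matrix(y[sp$train])),
                   list(x = data$x[, , , sp$val, drop = FALSE],
                        y = matrix(y[sp$val])),
                   train_cfg, verbose = verbose)
  z <- predict_scores(fit$model, data$x[, , , sp$test, drop = FALSE],
                      train_cfg$batch_size)
  pred <- (stats::plogis(z[, 1]) >= 0.5) * 1
  cnt <- confusion_counts(pred, y[sp$test])
  pr <- suppressWarnings(prf1(cnt))
  list(metrics = c(accuracy = accuracy(cnt), precision = pr[["precision"]],
                   recall = pr[["recall"]], f1 = pr[["f1"]]),
       split = sp, curves = fit$curves, model = fit$model)
}

#' Save / restore a model checkpoint
#'
#' The checkpoint stores the full parameter and buffer state plus the model
#' configuration fingerprint; reloading reproduces predictions bit-exactly.
#'
#' @param model A `tha_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly / the restored `tha_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tha_model"))
  saveRDS(list(state = nn_state(model$module), cfg = model$cfg), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg)
  nn_load_state(model$module, ck$state)
  model
}
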
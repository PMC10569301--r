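# Training engine: optimisation loop, LR schedule, protocols, checkpoints.

make_toy_data <- function(n, size = 32, seed = 1, p = 0.4) {
  set.seed(seed)
  list(x = array(runif(size * size * 3 * n), c(size, size, 3, n)),
       y = matrix(rbinom(n * 7, 1, p), n, 7))
}

micro_cfg <- function(..., seed = 1) {
  model_config(input_size = 32, base_width = 4, seed = seed, ...)
}

test_that("one plateau event reduces the learning rate from 2e-4 to 1.8e-4", {
  data <- make_toy_data(12)
  # epoch 1 establishes the baseline; the plateau-tolerance is set so that
  # no later epoch can count as an improvement, so with patience 1 the decay
  # fires after epoch 2 and epoch 3 trains at 2e-4 * 0.9 = 1.8e-4
  cfg <- train_config(lr0 = 2e-4, plateau_patience = 1, plateau_tol = 1e9,
                      max_epochs = 3, early_stop_patience = 10,
                      batch_size = 6, seed = 2)
  fit <- train_one(build_model(micro_cfg(seed = 3)),
                   list(x = data$x[, , , 1:8, drop = FALSE], y = data$y[1:8, ]),
                   list(x = data$x[, , , 9:12, drop = FALSE], y = data$y[9:12, ]),
                   cfg)
  expect_equal(fit$curves$lr, c(2e-4, 2e-4, 2e-4 * 0.9), tolerance = 1e-12)
})

test_that("early stopping halts before the epoch budget on flat validation", {
  data <- make_toy_data(12, seed = 4)
  cfg <- train_config(plateau_tol = 1e9, early_stop_patience = 3,
                      max_epochs = 20, batch_size = 6, seed = 5)
  fit <- train_one(build_model(micro_cfg(seed = 6)),
                   list(x = data$x[, , , 1:8, drop = FALSE], y = data$y[1:8, ]),
                   list(x = data$x[, , , 9:12, drop = FALSE], y = data$y[9:12, ]),
                   cfg)
  expect_equal(fit$stopped_epoch, 4)               # baseline + 3 flat epochs
  expect_equal(nrow(fit$curves), 4)
  expect_error(train_one(build_model(micro_cfg(seed = 6)),
                         list(x = data$x[, , , integer(0), drop = FALSE],
                              y = data$y[integer(0), ]),
                         list(x = data$x, y = data$y), cfg), "empty split")
})

test_that("training reduces the loss on easy phantoms", {
  spec <- phantom_spec(n_samples = 60, image_size = 64, noise_sigma = 0.02,
                       seed = 7)
  data <- phantom_tensors(spec)
  cfg <- train_config(lr0 = 1e-3, batch_size = 12, max_epochs = 3,
                      early_stop_patience = 5, seed = 8)
  fit <- train_one(build_model(model_config(input_size = 64, base_width = 8,
                                            seed = 9)),
                   list(x = data$x[, , , 1:48, drop = FALSE], y = data$y[1:48, ]),
                   list(x = data$x[, , , 49:60, drop = FALSE], y = data$y[49:60, ]),
                   cfg)
  expect_lt(tail(fit$curves$train_loss, 1), fit$curves$train_loss[1])
  expect_true(all(is.finite(fit$curves$val_loss)))
})

test_that("cross-validation aggregates are exact fold means with shared plans", {
  data <- make_toy_data(20, seed = 10)
  tcfg <- train_config(max_epochs = 1, batch_size = 8, seed = 11)
  res <- run_crossval(data, micro_cfg(), tcfg, n_folds = 3)
  expect_length(res$folds, 3)
  expect_equal(res$aggregate$map,
               mean(vapply(res$folds, `[[`, numeric(1), "map")),
               tolerance = 1e-12)
  expect_equal(res$aggregate$weighted,
               colMeans(do.call(rbind, lapply(res$folds, `[[`, "weighted"))),
               tolerance = 1e-12)
  # paired-ablation contract: same train seed means identical fold plans
  res2 <- run_crossval(data, micro_cfg(use_mc_csra = TRUE), tcfg, n_folds = 3)
  expect_identical(res$fold_plan$assignments, res2$fold_plan$assignments)
})

test_that("the binary protocol reports the four test metrics on a 6:2:2 split", {
  spec <- phantom_spec(n_samples = 40, image_size = 32,
                       marginals = c(0.5, rep(0, 6)), noise_sigma = 0.02,
                       seed = 12)
  data <- phantom_tensors(spec)
  tcfg <- train_config(lr0 = 1e-3, batch_size = 8, max_epochs = 1,
                       loss = "bce_binary", seed = 13)
  res <- run_binary_task(list(x = data$x, y = data$y[, 1]),
                         micro_cfg(n_classes = 1), tcfg)
  expect_named(res$metrics, c("accuracy", "precision", "recall", "f1"))
  expect_equal(lengths(res$split), c(train = 24, val = 8, test = 8))
  # split determinism under the config seed
  res_split <- split_622(40, tcfg$seed)
  expect_identical(res$split, res_split)
  expect_error(run_binary_task(list(x = data$x, y = rep(1, 40)),
                               micro_cfg(n_classes = 1), tcfg),
               "both classes")
})

test_that("checkpoints reproduce predictions bit-exactly", {
  data <- make_toy_data(8, seed = 14)
  model <- build_model(micro_cfg(use_cfs = TRUE, use_mc_csra = TRUE, seed = 15))
  cfg <- train_config(max_epochs = 1, batch_size = 4, seed = 16)
  fit <- train_one(model,
                   list(x = data$x[, , , 1:6, drop = FALSE], y = data$y[1:6, ]),
                   list(x = data$x[, , , 7:8, drop = FALSE], y = data$y[7:8, ]),
                   cfg)
  z1 <- predict_scores(fit$model, data$x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  restored <- load_checkpoint(path)
  expect_identical(predict_scores(restored, data$x), z1)
})
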
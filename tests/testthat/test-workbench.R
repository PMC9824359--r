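# training runs here are deliberately miniature (two IMUs, sub-second
# repetitions, few epochs) to keep the default suite fast

test_that("the network overfits a small separable training set", {
  ds <- generate_dataset(separable_config(seed = 11))
  fold <- stratified_shuffle_split(dataset_labels(ds), split_spec(seed = 3))
  prep <- prepare_fold(ds, fold, n_windows = 10L)
  arch <- architecture_config(
    n_blocks = 2, n_lstm_layers = 1, batch_size = 8, seed = 4
  )
  model <- build_model(arch, c(10L, 12L, prep$windowing$window_length), ds$layout)
  fit <- train_network(model, prep$train, prep$val,
    training_config(max_epochs = 40, patience = 40, seed = 5)
  )
  expect_gte(max(fit$history$train_macro_f1), 0.95)
})

test_that("early stopping with patience 0 stops after the first non-improving epoch", {
  ds <- generate_dataset(separable_config(seed = 21, n_subjects = 4L, reps_per_subject = 12L))
  fold <- stratified_shuffle_split(dataset_labels(ds), split_spec(seed = 1))
  prep <- prepare_fold(ds, fold, n_windows = 10L)
  arch <- tiny_arch(n_blocks = 1, n_lstm_layers = 1, batch_size = 8, seed = 2)
  model <- build_model(arch, c(10L, 12L, prep$windowing$window_length), ds$layout)
  # a large learning rate makes the validation loss fluctuate within a few
  # epochs, exercising the stopping rule
  fit <- train_network(model, prep$train, prep$val,
    training_config(max_epochs = 50, patience = 0, learning_rate = 0.01, seed = 3)
  )
  h <- fit$history
  n <- nrow(h)
  expect_lt(n, 50)
  # every epoch before the last improved on the best-so-far validation loss,
  # the final epoch did not, and the best weights are the previous epoch's
  expect_true(all(diff(h$val_loss[-n]) < 0))
  expect_gte(h$val_loss[n], min(h$val_loss[-n]))
  expect_identical(fit$best_epoch, n - 1L)
})

test_that("training is reproducible for fixed seeds and warns on missing classes", {
  ds <- generate_dataset(separable_config(seed = 8, n_subjects = 3L, reps_per_subject = 8L))
  fold <- stratified_shuffle_split(dataset_labels(ds), split_spec(seed = 2))
  prep <- prepare_fold(ds, fold, n_windows = 10L)
  arch <- tiny_arch(n_blocks = 1, n_lstm_layers = 1, batch_size = 8, seed = 7)
  shape <- c(10L, 12L, prep$windowing$window_length)
  cfg <- training_config(max_epochs = 3, patience = 3, seed = 9)
  fit1 <- train_network(build_model(arch, shape, ds$layout), prep$train, prep$val, cfg)
  fit2 <- train_network(build_model(arch, shape, ds$layout), prep$train, prep$val, cfg)
  expect_identical(fit1$history, fit2$history)

  # drop class 3 from training: warn, proceed
  keep <- prep$train$labels != 3L
  sub <- list(
    x = prep$train$x[keep, , , , drop = FALSE],
    mask = prep$train$mask[keep, , drop = FALSE],
    labels = prep$train$labels[keep]
  )
  expect_warning(
    train_network(build_model(arch, shape, ds$layout), sub, prep$val,
      training_config(max_epochs = 1, patience = 1, seed = 1)
    ),
    "missing from the training set"
  )
})

test_that("run_cv trains per fold without leakage and aggregates by arithmetic mean", {
  ds <- generate_dataset(separable_config(seed = 13, n_subjects = 4L, reps_per_subject = 9L))
  arch <- tiny_arch(n_blocks = 1, n_lstm_layers = 1, batch_size = 8, seed = 1)
  res <- run_cv(ds, arch,
    n_folds = 2L, split = split_spec(seed = 6),
    training = training_config(max_epochs = 2, patience = 2, seed = 3)
  )
  expect_s3_class(res, "run_result")
  expect_length(res$folds, 2L)
  for (s in c("train", "val", "test")) {
    macro <- vapply(res$folds, function(f) f$metrics[[s]]$macro_f1, numeric(1))
    row <- res$aggregate[res$aggregate$split == s, ]
    expect_equal(row$macro_f1_mean, mean(macro))
    expect_equal(row$macro_f1_sd, sd(macro))
  }
  # same seeds -> identical fold memberships
  res2 <- run_cv(ds, arch,
    n_folds = 2L, split = split_spec(seed = 6),
    training = training_config(max_epochs = 1, patience = 1, seed = 3)
  )
  for (i in 1:2) {
    expect_identical(res2$folds[[i]]$fold$test, res$folds[[i]]$fold$test)
  }
})

test_that("fold preprocessing depends only on the training split", {
  ds <- generate_dataset(separable_config(seed = 17, n_subjects = 3L, reps_per_subject = 8L))
  fold <- stratified_shuffle_split(dataset_labels(ds), split_spec(seed = 4))
  prep <- prepare_fold(ds, fold)
  # removing a test repetition and refitting leaves the parameters unchanged
  ds2 <- ds
  ds2$repetitions <- ds$repetitions[-fold$test[1]]
  shift <- function(idx, removed) ifelse(idx > removed, idx - 1L, idx)
  fold2 <- fold
  fold2$train <- shift(fold$train, fold$test[1])
  fold2$val <- shift(fold$val, fold$test[1])
  fold2$test <- shift(fold$test[-1], fold$test[1])
  prep2 <- prepare_fold(ds2, fold2)
  expect_identical(prep2$standardization, prep$standardization)
  expect_identical(prep2$windowing$pad_length, prep$windowing$pad_length)
})

test_that("run_losocv excludes the held-out subject from every training batch", {
  ds <- generate_dataset(separable_config(seed = 19, n_subjects = 4L, reps_per_subject = 9L))
  arch <- tiny_arch(n_blocks = 1, n_lstm_layers = 1, batch_size = 8, seed = 5)
  res <- run_losocv(ds, arch,
    n_folds = 3L,
    training = training_config(max_epochs = 2, patience = 2, seed = 7), seed = 8
  )
  expect_length(res$folds, 3L)
  expect_identical(res$headline_metric, "weighted_f1")
  subjects <- dataset_subjects(ds)
  held <- vapply(res$folds, function(f) f$fold$held_out_subject, character(1))
  expect_identical(anyDuplicated(held), 0L)
  for (f in res$folds) {
    expect_false(f$fold$held_out_subject %in% subjects[c(f$fold$train, f$fold$val)])
    expect_true(all(subjects[f$fold$test] == f$fold$held_out_subject))
  }
})

test_that("random search sampling is reproducible, in-domain and rank-stable", {
  grid <- hyperparameter_grid()
  configs <- sample_search_configs(grid, n_runs = 90L, base_seed = 42L)
  expect_length(configs, 90L)
  configs2 <- sample_search_configs(grid, n_runs = 90L, base_seed = 42L)
  key <- function(cf) {
    paste(cf$activation, cf$n_blocks, cf$scheme, cf$regularizer,
      cf$n_lstm_layers, cf$batch_size,
      sep = "|"
    )
  }
  expect_identical(vapply(configs2, key, character(1)), vapply(configs, key, character(1)))
  for (cf in configs) {
    expect_true(cf$activation %in% grid$activation)
    expect_true(cf$n_blocks %in% grid$n_blocks)
    expect_true(cf$scheme %in% grid$scheme)
    expect_true(cf$regularizer %in% grid$regularizer)
    expect_true(cf$n_lstm_layers %in% grid$n_lstm_layers)
    expect_true(cf$batch_size %in% grid$batch_size)
  }
  # independent draws cover a substantial part of the 288-cell grid
  expect_gt(length(unique(vapply(configs, key, character(1)))), 40L)

  # stub evaluator: a deterministic function of the configuration
  stub <- function(dataset, cf) cf$n_blocks + 0.1 * (cf$activation == "ELU")
  res <- random_search(NULL, grid, n_runs = 20L, base_seed = 7L, evaluator = stub)
  expect_identical(sort(res$ranking), 1:20)
  expect_identical(res$val_scores[res$ranking], sort(res$val_scores, decreasing = TRUE))
  # ties broken by run index
  tied <- which(res$val_scores == max(res$val_scores))
  expect_identical(res$ranking[seq_along(tied)], tied)

  # de-duplication switch
  dd <- sample_search_configs(grid, n_runs = 30L, base_seed = 3L, dedupe = TRUE)
  expect_identical(anyDuplicated(vapply(dd, key, character(1))), 0L)
})

test_that("the command-line interface round-trips generate -> labels -> describe", {
  dir <- withr::local_tempdir()
  out1 <- file.path(dir, "raw")
  imuqc_cli(c(
    "generate", "--out", out1, "--seed", "5", "--n-subjects", "2",
    "--reps-per-subject", "3", "--n-imus", "2", "--min-duration", "0.3",
    "--max-duration", "0.5", "--affected-segments", "2"
  ))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  out2 <- file.path(dir, "labeled")
  suppressMessages(imuqc_cli(c("labels", "--data", out1, "--out", out2)))
  expect_true(file.exists(file.path(out2, "agreement_report.tsv")))
  ds <- read_dataset(out2)
  expect_true(all(!is.na(dataset_labels(ds))))
  inv <- imuqc_cli(c("describe", "--n-imus", "2", "--window-length", "8", "--n-blocks", "1"))
  expect_s3_class(inv, "data.frame")
  cfgs <- imuqc_cli(c("sweep", "--configs-only", "--n-runs", "5", "--seed", "3"))
  expect_length(cfgs, 5L)
})
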
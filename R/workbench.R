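#' Training configuration
#'
#' Adam with the architecture's fixed learning rate (0.0001) and categorical
#' cross-entropy, up to `max_epochs` epochs with early stopping on validation
#' loss (`patience` epochs without improvement; best-validation weights are
#' restored).
#'
#' @param max_epochs epoch budget (default 300).
#' @param patience early-stopping patience on validation loss (default 30).
#'   `patience = 0` stops after the first non-improving epoch.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param seed seed for batch shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return object of class `training_config`.
#' @export
training_config <- function(max_epochs = 300L, patience = 30L,
                            learning_rate = 1e-4, seed = 1L, verbose = FALSE) {
  stop_if_not_count(max_epochs, "max_epochs")
  stop_if_not_count(patience, "patience", min = 0L)
  structure(
    list(
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      learning_rate = as.numeric(learning_rate), seed = as.integer(seed),
      verbose = isTRUE(verbose)
    ),
    class = "training_config"
  )
}

one_hot <- function(labels, n_classes = 3L) {
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), labels)] <- 1
  y
}

eval_split <- function(model, batch) {
  probs <- predict_proba(model, batch$x, batch$mask)
  pred <- as.integer(max.col(probs, ties.method = "first"))
  eps <- 1e-12
  loss <- -mean(log(probs[cbind(seq_along(batch$labels), batch$labels)] + eps))
  list(loss = loss, metrics = f1_metrics(batch$labels, pred), predicted = pred)
}

#' Train a scoring network
#'
#' Minimizes categorical cross-entropy with Adam on minibatches of the
#' architecture's batch size. Training stops at `max_epochs` or when the
#' validation loss has not improved for more than `patience` epochs; the
#' weights of the best validation epoch are restored. The history records
#' per-epoch loss and macro F1 for the training batches and the validation
#' set.
#'
#' @param model a [build_model()] network.
#' @param train,val batches from [preprocess_batch()] with resolved labels.
#' @param config a [training_config()].
#' @return list with `model` (trained), `history` (data.frame of epoch,
#'   train_loss, train_macro_f1, val_loss, val_macro_f1), `best_epoch`.
#' @export
train_network <- function(model, train, val, config = training_config()) {
  stopifnot(inherits(model, "imuqc_model"), inherits(config, "training_config"))
  n <- dim(train$x)[1]
  if (n == 0L) stop("empty training set", call. = FALSE)
  if (anyNA(train$labels) || anyNA(val$labels)) {
    stop("unresolved labels in training or validation data", call. = FALSE)
  }
  missing_classes <- setdiff(1:3, unique(train$labels))
  if (length(missing_classes)) {
    warning(sprintf(
      "class(es) %s missing from the training set; proceeding",
      paste(missing_classes, collapse = ", ")
    ), call. = FALSE)
  }
  batch_size <- model$config$batch_size
  y <- one_hot(train$labels, model$n_classes)
  opt <- adam_init(model$params)
  history <- data.frame(
    epoch = integer(0), train_loss = numeric(0), train_macro_f1 = numeric(0),
    val_loss = numeric(0), val_macro_f1 = numeric(0)
  )
  best <- list(loss = Inf, params = model$params, state = model$state, epoch = 0L)
  wait <- 0L

  with_seed(derive_seed(config$seed, "train-loop"), {
    for (epoch in seq_len(config$max_epochs)) {
      order_ <- sample.int(n)
      batch_losses <- numeric(0)
      pred_all <- integer(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- order_[start:min(start + batch_size - 1L, n)]
        fw <- model_forward(model,
          train$x[idx, , , , drop = FALSE],
          train$mask[idx, , drop = FALSE],
          training = TRUE
        )
        ce <- cross_entropy_softmax(fw$logits, y[idx, , drop = FALSE])
        batch_losses <- c(batch_losses, ce$loss)
        pred_all[idx] <- max.col(ce$probs, ties.method = "first")
        grads <- model_backward(model, fw, ce$dlogits)
        upd <- adam_step(model$params, grads, opt, lr = config$learning_rate)
        model$params <- upd$params
        opt <- upd$state
        if (length(fw$state_updates)) {
          model$state[names(fw$state_updates)] <- fw$state_updates
        }
      }
      train_f1 <- f1_metrics(train$labels, pred_all)$macro_f1
      ev <- eval_split(model, val)
      history[epoch, ] <- list(epoch, mean(batch_losses), train_f1, ev$loss, ev$metrics$macro_f1)
      if (config$verbose) {
        message(sprintf(
          "epoch %3d  train loss %.4f  F1 %.3f | val loss %.4f  F1 %.3f",
          epoch, mean(batch_losses), train_f1, ev$loss, ev$metrics$macro_f1
        ))
      }
      if (ev$loss < best$loss) {
        best <- list(loss = ev$loss, params = model$params, state = model$state, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > config$patience) break
      }
    }
  })
  model$params <- best$params
  model$state <- best$state
  list(model = model, history = history, best_epoch = best$epoch)
}

#' Materialize one fold as network-ready batches
#'
#' Fits the standardization parameters and the pad length on the fold's
#' training split only (no leakage), then preprocesses all three splits.
#'
#' @param dataset an [imu_dataset()] with resolved labels.
#' @param fold a `fold` from [stratified_shuffle_split()] or [loso_folds()].
#' @param n_windows number of input windows X (default 10).
#' @return list with `standardization`, `windowing` and the `train`, `val`,
#'   `test` batches from [preprocess_batch()].
#' @export
prepare_fold <- function(dataset, fold, n_windows = 10L) {
  reps <- dataset$repetitions
  train_reps <- reps[fold$train]
  std <- fit_standardization(train_reps, dataset$layout)
  wcfg <- fit_pad_length(windowing_config(n_windows), train_reps)
  list(
    standardization = std, windowing = wcfg,
    train = preprocess_batch(train_reps, std, wcfg, dataset$layout),
    val = preprocess_batch(reps[fold$val], std, wcfg, dataset$layout),
    test = preprocess_batch(reps[fold$test], std, wcfg, dataset$layout)
  )
}

run_folds <- function(dataset, arch_config, folds, training, n_windows) {
  fold_results <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    fold <- folds[[i]]
    prep <- prepare_fold(dataset, fold, n_windows)
    shape <- c(n_windows, n_channel_rows(dataset$layout), prep$windowing$window_length)
    cfg <- arch_config
    cfg$seed <- derive_seed(arch_config$seed, "fold-init", i)
    model <- build_model(cfg, shape, dataset$layout)
    tr_cfg <- training
    tr_cfg$seed <- derive_seed(training$seed, "fold-train", i)
    fit <- train_network(model, prep$train, prep$val, tr_cfg)
    fold_results[[i]] <- list(
      fold = fold,
      history = fit$history,
      best_epoch = fit$best_epoch,
      metrics = list(
        train = eval_split(fit$model, prep$train)$metrics,
        val = eval_split(fit$model, prep$val)$metrics,
        test = eval_split(fit$model, prep$test)$metrics
      )
    )
  }
  fold_results
}

aggregate_folds <- function(fold_results) {
  splits <- c("train", "val", "test")
  do.call(rbind, lapply(splits, function(s) {
    macro <- vapply(fold_results, function(f) f$metrics[[s]]$macro_f1, numeric(1))
    weighted <- vapply(fold_results, function(f) f$metrics[[s]]$weighted_f1, numeric(1))
    data.frame(
      split = s,
      macro_f1_mean = mean(macro), macro_f1_sd = stats::sd(macro),
      weighted_f1_mean = mean(weighted), weighted_f1_sd = stats::sd(weighted)
    )
  }))
}

#' Within-subject cross-validated training run
#'
#' Trains and evaluates one architecture with `n_folds` independent
#' stratified shuffle splits (20% test / 16% validation / 64% training of the
#' whole set). Standardization parameters and the pad length are fitted per
#' fold on that fold's training split only. The headline metric is the macro
#' F1 score.
#'
#' @param dataset an [imu_dataset()] with resolved labels.
#' @param arch_config an [architecture_config()].
#' @param n_folds number of folds (default 5).
#' @param split a [split_spec()].
#' @param training a [training_config()].
#' @param n_windows number of input windows X (default 10).
#' @return object of class `run_result` with `folds` (per-fold metrics and
#'   histories), `aggregate` (mean and s.d. of macro and weighted F1 per
#'   split) and the configurations used.
#' @export
run_cv <- function(dataset, arch_config, n_folds = 5L, split = split_spec(),
                   training = training_config(), n_windows = 10L) {
  stopifnot(inherits(dataset, "imu_dataset"), inherits(arch_config, "architecture_config"))
  labels <- dataset_labels(dataset)
  if (anyNA(labels)) stop("dataset contains unresolved labels; run resolve_labels() first",
    call. = FALSE
  )
  folds <- monte_carlo_cv(labels, split, n_folds)
  fold_results <- run_folds(dataset, arch_config, folds, training, n_windows)
  structure(
    list(
      kind = "cv", config = arch_config, split = split, training = training,
      folds = fold_results, aggregate = aggregate_folds(fold_results),
      headline_metric = "macro_f1"
    ),
    class = "run_result"
  )
}

#' Leave-one-subject-out cross-validated training run
#'
#' As [run_cv()], but each fold's test set is the complete data of one
#' held-out subject absent from training and validation; the remaining data
#' are split 80% / 20% stratified by label. The headline metric is the
#' weighted F1 score, which is robust to the one-sided label distributions of
#' single subjects.
#'
#' @inheritParams run_cv
#' @param n_folds number of held-out subjects (default 10).
#' @param inner_val_fraction validation share of the remaining data
#'   (default 0.2).
#' @param seed seed for subject selection and inner splits.
#' @return object of class `run_result` (see [run_cv()]).
#' @export
run_losocv <- function(dataset, arch_config, n_folds = 10L, inner_val_fraction = 0.2,
                       training = training_config(), n_windows = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "imu_dataset"), inherits(arch_config, "architecture_config"))
  labels <- dataset_labels(dataset)
  if (anyNA(labels)) stop("dataset contains unresolved labels; run resolve_labels() first",
    call. = FALSE
  )
  folds <- loso_folds(dataset_subjects(dataset), labels, n_folds, inner_val_fraction, seed)
  fold_results <- run_folds(dataset, arch_config, folds, training, n_windows)
  structure(
    list(
      kind = "losocv", config = arch_config, training = training,
      folds = fold_results, aggregate = aggregate_folds(fold_results),
      headline_metric = "weighted_f1"
    ),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %s, %d folds, headline %s\n", x$kind, length(x$folds), x$headline_metric))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' The hyperparameter search grid
#'
#' Domains of the tunable parameters: activation ReLU/ELU/LReLU, 1-3
#' CNN-blocks, fixed- or decreasing-kernel combination scheme, dropout(0.2)
#' or batch normalization, 1-2 LSTM layers, batch size 4/8/16/32.
#'
#' @return named list of parameter domains.
#' @export
hyperparameter_grid <- function() {
  list(
    activation = ACTIVATIONS,
    n_blocks = 1:3,
    scheme = SCHEMES,
    regularizer = REGULARIZERS,
    n_lstm_layers = 1:2,
    batch_size = BATCH_SIZES
  )
}

#' Sample random search configurations from the grid
#'
#' Each run draws every parameter independently and uniformly from its
#' domain. Independent draws may repeat a combination (the full grid has 288
#' cells); set `dedupe = TRUE` to redraw duplicates.
#'
#' @param grid a [hyperparameter_grid()]-shaped list of domains.
#' @param n_runs number of configurations (default 90).
#' @param base_seed seed; the same seed regenerates the identical list.
#' @param variant network variant for all configs (default baseline).
#' @param dedupe redraw duplicated combinations (default `FALSE`).
#' @return list of [architecture_config()] objects.
#' @export
sample_search_configs <- function(grid = hyperparameter_grid(), n_runs = 90L,
                                  base_seed = 1L, variant = "baseline",
                                  dedupe = FALSE) {
  stop_if_not_count(n_runs, "n_runs")
  with_seed(derive_seed(base_seed, "sweep-configs"), {
    draw_one <- function(i) {
      architecture_config(
        variant = variant,
        n_blocks = sample(grid$n_blocks, 1L),
        scheme = sample(grid$scheme, 1L),
        activation = sample(grid$activation, 1L),
        regularizer = sample(grid$regularizer, 1L),
        n_lstm_layers = sample(grid$n_lstm_layers, 1L),
        batch_size = sample(grid$batch_size, 1L),
        seed = derive_seed(base_seed, "sweep-run", i)
      )
    }
    configs <- lapply(seq_len(n_runs), draw_one)
    if (dedupe) {
      key <- function(cf) {
        paste(cf$n_blocks, cf$scheme, cf$activation, cf$regularizer,
          cf$n_lstm_layers, cf$batch_size,
          sep = "|"
        )
      }
      seen <- character(0)
      for (i in seq_along(configs)) {
        tries <- 0L
        while (key(configs[[i]]) %in% seen && tries < 1000L) {
          configs[[i]] <- draw_one(i)
          tries <- tries + 1L
        }
        seen <- c(seen, key(configs[[i]]))
      }
    }
    configs
  })
}

#' Random hyperparameter search
#'
#' Draws `n_runs` configurations from the grid (seeded, reproducible),
#' evaluates each with `evaluator` (by default a [run_cv()] 5-fold
#' cross-validation) and ranks runs by mean validation macro F1, ties broken
#' by run index.
#'
#' @param dataset an [imu_dataset()] with resolved labels.
#' @param grid parameter domains (default [hyperparameter_grid()]).
#' @param n_runs number of runs (default 90).
#' @param base_seed seed for configuration sampling.
#' @param evaluator function `(dataset, config) -> run_result | numeric`;
#'   a numeric return is taken directly as the validation score (used e.g.
#'   to stub out training when only the sampling is exercised).
#' @param ... passed to [run_cv()] when `evaluator` is `NULL`.
#' @return object of class `search_result`: `configs`, `results`,
#'   `val_scores`, `ranking` (run indices, best first).
#' @export
random_search <- function(dataset, grid = hyperparameter_grid(), n_runs = 90L,
                          base_seed = 1L, evaluator = NULL, ...) {
  configs <- sample_search_configs(grid, n_runs, base_seed)
  results <- vector("list", n_runs)
  scores <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    res <- if (is.null(evaluator)) {
      run_cv(dataset, configs[[i]], ...)
    } else {
      evaluator(dataset, configs[[i]])
    }
    results[[i]] <- res
    scores[i] <- if (inherits(res, "run_result")) {
      res$aggregate$macro_f1_mean[res$aggregate$split == "val"]
    } else {
      as.numeric(res)
    }
  }
  structure(
    list(
      configs = configs, results = results, val_scores = scores,
      ranking = order(-scores, seq_len(n_runs))
    ),
    class = "search_result"
  )
}

#' The headline architecture
#'
#' The best combination of the hyperparameter search, used for all
#' per-exercise and leave-one-subject-out evaluations: baseline variant,
#' three CNN-blocks with increasing filters and fixed 5x5 kernels, ELU,
#' dropout 0.2, two 256-unit LSTM layers, batch size 32.
#'
#' @param seed initialization seed.
#' @return an [architecture_config()].
#' @export
headline_config <- function(seed = 1L) {
  architecture_config(
    variant = "baseline", n_blocks = 3L, scheme = "fixed_kernel",
    activation = "ELU", regularizer = "dropout_0.2", n_lstm_layers = 2L,
    batch_size = 32L, seed = seed
  )
}
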
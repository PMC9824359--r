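#' Specification of a stratified train/validation/test split
#'
#' Default fractions: 20% test, 16% validation, 64% training of the whole
#' dataset (the validation set is 20% of the remaining 80%), stratified by
#' label.
#'
#' @param test_fraction,val_fraction,train_fraction fractions summing to 1.
#' @param seed integer seed.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.20, val_fraction = 0.16,
                       train_fraction = 0.64, seed = 1L) {
  if (abs(test_fraction + val_fraction + train_fraction - 1) > 1e-8) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  if (min(test_fraction, val_fraction, train_fraction) <= 0) {
    stop("split fractions must be positive", call. = FALSE)
  }
  structure(
    list(
      test_fraction = test_fraction, val_fraction = val_fraction,
      train_fraction = train_fraction, seed = as.integer(seed)
    ),
    class = "split_spec"
  )
}

#' Stratified shuffle split
#'
#' Randomly partitions indices into train/validation/test sets so that each
#' split's class proportions match the overall proportions up to rounding.
#' Deterministic for a given seed.
#'
#' @param labels vector of class labels (one per item).
#' @param spec a [split_spec()].
#' @return object of class `fold`: list of disjoint index vectors `train`,
#'   `val`, `test` (1-based into `labels`).
#' @export
stratified_shuffle_split <- function(labels, spec) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(labels)
  if (n < 3L) stop("too few items to split", call. = FALSE)
  idx_train <- integer(0)
  idx_val <- integer(0)
  idx_test <- integer(0)
  with_seed(spec$seed, {
    for (cl in sort(unique(labels))) {
      members <- which(labels == cl)
      n_c <- length(members)
      n_test <- round(n_c * spec$test_fraction)
      n_val <- round(n_c * spec$val_fraction)
      n_train <- n_c - n_test - n_val
      if (min(n_test, n_val, n_train) < 1L) {
        stop(sprintf(
          "class '%s' has too few members (%d) to stratify into all splits", cl, n_c
        ), call. = FALSE)
      }
      perm <- sample(members)
      idx_test <- c(idx_test, perm[seq_len(n_test)])
      idx_val <- c(idx_val, perm[n_test + seq_len(n_val)])
      idx_train <- c(idx_train, perm[n_test + n_val + seq_len(n_train)])
    }
  })
  structure(
    list(train = sort(idx_train), val = sort(idx_val), test = sort(idx_test),
         held_out_subject = NULL, seed = spec$seed),
    class = "fold"
  )
}

#' Monte-Carlo cross-validation folds
#'
#' `n_folds` independent stratified shuffle splits, each drawn with a seed
#' derived deterministically from `spec$seed` and the fold index.
#'
#' @param labels class labels.
#' @param spec a [split_spec()].
#' @param n_folds number of independent splits (default 5).
#' @return list of `n_folds` [stratified_shuffle_split()] folds.
#' @export
monte_carlo_cv <- function(labels, spec, n_folds = 5L) {
  stop_if_not_count(n_folds, "n_folds")
  lapply(seq_len(n_folds), function(f) {
    fold_spec <- spec
    fold_spec$seed <- derive_seed(spec$seed, "cv-fold", f)
    stratified_shuffle_split(labels, fold_spec)
  })
}

#' Leave-one-subject-out folds
#'
#' Each fold holds out the complete data of one subject as the test set; the
#' remaining items are split into training (80%) and validation (20%),
#' stratified by label. When `n_folds` is smaller than the number of
#' subjects, held-out subjects are drawn by seeded sampling without
#' replacement.
#'
#' @param subject_ids subject id per item.
#' @param labels class label per item.
#' @param n_folds number of held-out subjects.
#' @param inner_val_fraction validation fraction of the remaining data
#'   (default 0.2).
#' @param seed integer seed.
#' @return list of `fold` objects with `held_out_subject` set.
#' @export
loso_folds <- function(subject_ids, labels, n_folds = 10L,
                       inner_val_fraction = 0.2, seed = 1L) {
  stopifnot(length(subject_ids) == length(labels))
  subjects <- unique(subject_ids)
  stop_if_not_count(n_folds, "n_folds")
  if (n_folds > length(subjects)) {
    stop(sprintf("n_folds = %d exceeds number of subjects (%d)", n_folds, length(subjects)),
      call. = FALSE
    )
  }
  held_out <- with_seed(derive_seed(seed, "loso-subjects"), {
    if (n_folds == length(subjects)) subjects else sample(subjects, n_folds)
  })
  lapply(seq_along(held_out), function(f) {
    subj <- held_out[f]
    test <- which(subject_ids == subj)
    rest <- which(subject_ids != subj)
    inner <- integer(0)
    with_seed(derive_seed(seed, "loso-inner", f), {
      for (cl in sort(unique(labels[rest]))) {
        members <- rest[labels[rest] == cl]
        n_val <- max(1L, round(length(members) * inner_val_fraction))
        inner <- c(inner, sample(members, n_val))
      }
    })
    structure(
      list(
        train = sort(setdiff(rest, inner)), val = sort(inner), test = sort(test),
        held_out_subject = subj, seed = seed
      ),
      class = "fold"
    )
  })
}

#' @export
print.fold <- function(x, ...) {
  cat(sprintf(
    "<fold> train %d / val %d / test %d%s\n",
    length(x$train), length(x$val), length(x$test),
    if (!is.null(x$held_out_subject)) sprintf("  (held out: %s)", x$held_out_subject) else ""
  ))
  invisible(x)
}

#' Classification metrics over the fixed 1/2/3 label set
#'
#' Computes the confusion matrix (rows = truth), per-class F1 with the
#' 0-convention for undefined precision or recall, the macro F1 (unweighted
#' mean over the fixed label set — a class absent from both truth and
#' prediction contributes 0) and the weighted F1 (support-weighted mean).
#'
#' @param true,predicted equal-length label vectors with values in
#'   `label_set`.
#' @param label_set the fixed class set (default 1:3).
#' @return object of class `metric_report`: list with `confusion`,
#'   `per_class_f1`, `macro_f1`, `weighted_f1`, `support`, `n`.
#' @export
f1_metrics <- function(true, predicted, label_set = 1:3) {
  if (length(true) == 0L) stop("empty input", call. = FALSE)
  if (length(true) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (!all(true %in% label_set) || !all(predicted %in% label_set)) {
    stop("labels outside the declared label set", call. = FALSE)
  }
  k <- length(label_set)
  confusion <- table(
    factor(true, levels = label_set),
    factor(predicted, levels = label_set)
  )
  confusion <- matrix(as.integer(confusion), k, k,
    dimnames = list(true = label_set, predicted = label_set)
  )
  tp <- diag(confusion)
  support <- rowSums(confusion)
  pred_n <- colSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  structure(
    list(
      confusion = confusion,
      per_class_f1 = stats::setNames(f1, label_set),
      macro_f1 = mean(f1),
      weighted_f1 = if (sum(support) > 0) sum(f1 * support) / sum(support) else 0,
      support = stats::setNames(support, label_set),
      n = length(true)
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> n=%d  macro F1 = %.4f  weighted F1 = %.4f\n",
    x$n, x$macro_f1, x$weighted_f1
  ))
  print(x$confusion)
  invisible(x)
}
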
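test_that("generator produces the configured number of repetitions, reproducibly", {
  cfg <- separable_config(seed = 3, n_subjects = 5L, reps_per_subject = 10L)
  ds <- generate_dataset(cfg)
  expect_identical(length(ds), 50L)
  expect_identical(length(unique(dataset_subjects(ds))), 5L)
  expect_true(all(dataset_labels(ds) %in% 1:3))

  ds2 <- generate_dataset(cfg)
  for (id in names(ds$repetitions)) {
    expect_identical(ds2$repetitions[[id]]$data, ds$repetitions[[id]]$data)
    expect_identical(ds2$repetitions[[id]]$resolved_label, ds$repetitions[[id]]$resolved_label)
  }

  # different seed changes the data
  ds3 <- generate_dataset(separable_config(seed = 4, n_subjects = 5L, reps_per_subject = 10L))
  expect_false(identical(ds3$repetitions[[1]]$data, ds$repetitions[[1]]$data))
})

test_that("generator leaves the caller's RNG state untouched", {
  set.seed(999)
  before <- .Random.seed
  invisible(generate_dataset(separable_config(seed = 1, n_subjects = 1L, reps_per_subject = 2L)))
  expect_identical(.Random.seed, before)
})

test_that("degenerate config carries no class signal", {
  cfg <- synthetic_config(
    n_subjects = 2L, reps_per_subject = 6L, n_imus = 2L,
    duration_range = c(0.5, 0.5), deviation_amplitude = 0,
    restriction_factor = 0.999999, noise_sd = 0, subject_effect_scale = 0.1,
    affected_segments = 2L, seed = 6
  )
  # restriction_factor must be < 1; 0.999999 approximates the null. Equal
  # durations make all repetitions of one subject identical up to the class
  # effect, which is absent here.
  ds <- generate_dataset(cfg)
  by_subject <- split(ds$repetitions, dataset_subjects(ds))
  for (reps in by_subject) {
    base <- reps[[1]]$data
    for (r in reps[-1]) {
      expect_equal(r$data, base, tolerance = 1e-4)
    }
  }
})

test_that("label proportions converge to class_probabilities", {
  cfg <- synthetic_config(
    n_subjects = 30L, reps_per_subject = 100L, n_imus = 2L,
    duration_range = c(0.1, 0.15), class_probabilities = c(0.2, 0.4, 0.4),
    affected_segments = 1L, seed = 12
  )
  ds <- generate_dataset(cfg)
  n <- length(ds)
  expect_identical(n, 3000L)
  freq <- tabulate(dataset_labels(ds), 3) / n
  # 4 sd multinomial bounds
  for (k in 1:3) {
    p <- cfg$class_probabilities[k]
    expect_lt(abs(freq[k] - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("class separability grows with deviation_amplitude at fixed seed", {
  # separability = distance between class-conditional means of the relative
  # energy of the affected channels (isolates the compensation burst, which
  # is the feature that scales with deviation_amplitude)
  sep <- function(dev) {
    cfg <- synthetic_config(
      n_subjects = 4L, reps_per_subject = 10L, n_imus = 2L,
      duration_range = c(0.3, 0.5), deviation_amplitude = dev,
      restriction_factor = 0.6, subject_effect_scale = 0.02, noise_sd = 0.02,
      affected_segments = 1L, seed = 31
    )
    ds <- generate_dataset(cfg)
    rows_aff <- unlist(lapply(ds$manifest$affected_imus - 1L, imu_rows, layout = ds$layout))
    f <- vapply(ds$repetitions, function(r) {
      mean(r$data[rows_aff, , drop = FALSE]^2) / mean(r$data[-rows_aff, , drop = FALSE]^2)
    }, numeric(1))
    sum(dist(tapply(f, dataset_labels(ds), mean)))
  }
  s <- vapply(c(0, 1, 2, 4), sep, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("simulated raters hit the configured error rates and clip at the scale ends", {
  # noise free: all raters agree with the truth
  ds <- generate_dataset(separable_config(seed = 2, n_subjects = 2L, reps_per_subject = 5L))
  ds0 <- simulate_raters(ds, rater_config(p_off_by_one = 0, p_off_by_two = 0, seed = 4))
  for (r in ds0$repetitions) {
    expect_identical(r$rater_scores, rep(r$resolved_label, 3L))
  }

  # error rate: fraction of discrepant single ratings ~ Binomial(n, 0.2);
  # 99% bounds
  cfg <- synthetic_config(
    n_subjects = 10L, reps_per_subject = 34L, n_imus = 2L,
    duration_range = c(0.1, 0.12), affected_segments = 1L, seed = 44
  )
  big <- generate_dataset(cfg)
  rated <- simulate_raters(big, rater_config(p_off_by_one = 0.2, p_off_by_two = 0, seed = 9))
  truth <- dataset_labels(rated)
  scores <- t(vapply(rated$repetitions, function(r) r$rater_scores, integer(3)))
  n_ratings <- length(scores)
  mismatch <- sum(scores != truth)
  p_hat <- mismatch / n_ratings
  half <- qnorm(0.995) * sqrt(0.2 * 0.8 / n_ratings)
  expect_gt(p_hat, 0.2 - half)
  expect_lt(p_hat, 0.2 + half)

  # off-by-one errors from the extremes can only move inward
  err_idx <- which(scores != truth)
  moved <- scores[err_idx]
  truth_rep <- matrix(truth, nrow(scores), 3)[err_idx]
  expect_true(all(abs(moved - truth_rep) == 1))
  expect_true(all(moved[truth_rep == 3] == 2))
  expect_true(all(moved[truth_rep == 1] == 2))

  # rater noise does not perturb the kinematics (independent streams)
  expect_identical(rated$repetitions[[1]]$data, big$repetitions[[1]]$data)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(class_probabilities = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(synthetic_config(duration_range = c(3, 2)), "ordered")
  expect_error(synthetic_config(restriction_factor = 1), "\\(0, 1\\)")
  expect_error(synthetic_config(affected_segments = 20, n_imus = 4), "exceeds")
  expect_error(rater_config(p_off_by_one = 0.9, p_off_by_two = 0.2), "sum <= 1")
  unlabeled <- make_dataset(2L)
  unlabeled$repetitions[[1]]$resolved_label <- NA_integer_
  expect_error(simulate_raters(unlabeled, rater_config()), "true resolved_label")
})
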
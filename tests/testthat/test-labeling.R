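random_rating_table <- function(n_items, n_raters = 3L, p_missing = 0) {
  tab <- matrix(sample(1:3, n_items * n_raters, replace = TRUE), n_items, n_raters)
  if (p_missing > 0) {
    tab[matrix(runif(length(tab)) < p_missing, nrow(tab))] <- NA
  }
  tab
}

test_that("krippendorff_alpha matches the pair-enumeration oracle", {
  # frozen spec example
  tab <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3), c(1, 1, 2))
  expect_equal(krippendorff_alpha(tab, "ordinal"), oracle_krippendorff(tab, "ordinal"),
    tolerance = 1e-10
  )
  set.seed(101)
  for (i in 1:30) {
    tab <- random_rating_table(sample(4:30, 1), p_missing = sample(c(0, 0.2), 1))
    if (length(unique(stats::na.omit(as.vector(tab)))) < 2) next
    for (metric in c("ordinal", "nominal", "interval")) {
      expect_equal(
        krippendorff_alpha(tab, metric),
        oracle_krippendorff(tab, metric),
        tolerance = 1e-10,
        label = sprintf("iter %d metric %s", i, metric)
      )
    }
  }
})

test_that("alpha is exactly 1 under perfect agreement and errs when undefined", {
  tab <- rbind(c(1, 1, 1), c(3, 3, 3), c(2, 2, 2))
  expect_identical(krippendorff_alpha(tab), 1)
  expect_error(krippendorff_alpha(matrix(2, 5, 3)), "alpha undefined")
  expect_error(krippendorff_alpha(rbind(c(1, 2, NA))), "at least 2 items")
})

test_that("alpha is invariant to item order and rater-column order", {
  set.seed(7)
  tab <- random_rating_table(20, p_missing = 0.1)
  a <- krippendorff_alpha(tab)
  expect_equal(krippendorff_alpha(tab[sample(nrow(tab)), ]), a)
  expect_equal(krippendorff_alpha(tab[, c(3, 1, 2)]), a)
})

test_that("nominal and ordinal alpha coincide on binary tables", {
  set.seed(13)
  for (i in 1:10) {
    tab <- matrix(sample(1:2, 30, replace = TRUE), 10, 3)
    if (length(unique(as.vector(tab))) < 2) next
    expect_equal(
      krippendorff_alpha(tab, "nominal"),
      krippendorff_alpha(tab, "ordinal"),
      tolerance = 1e-12
    )
  }
})

test_that("majority_vote resolves the canonical score triples", {
  r <- majority_vote(c(2, 2, 2))
  expect_identical(r$label, 2L)
  expect_identical(r$agreement, "unanimous")

  r <- majority_vote(c(1, 1, 3))
  expect_identical(r$label, 1L)
  expect_identical(r$agreement, "majority_major")

  r <- majority_vote(c(1, 1, 2))
  expect_identical(r$agreement, "majority_minor")

  r <- majority_vote(c(1, 2, 3))
  expect_true(is.na(r$label))
  expect_identical(r$agreement, "no_majority")

  expect_error(majority_vote(c(1, 2)), "exactly 3")
  expect_error(majority_vote(c(1, 2, 4)), "exactly 3|\\{1,2,3\\}")
})

test_that("majority_vote is permutation symmetric with the expected category census", {
  triples <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
  cats <- character(nrow(triples))
  for (i in seq_len(nrow(triples))) {
    s <- as.integer(triples[i, ])
    res <- majority_vote(s)
    cats[i] <- res$agreement
    for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      rp <- majority_vote(s[p])
      expect_identical(rp$agreement, res$agreement)
      expect_identical(rp$label, res$label)
    }
  }
  census <- table(cats)
  expect_identical(as.integer(census[["unanimous"]]), 3L)
  expect_identical(as.integer(census[["majority_minor"]]), 12L)
  expect_identical(as.integer(census[["majority_major"]]), 6L)
  expect_identical(as.integer(census[["no_majority"]]), 6L)
})

test_that("summarize_agreement returns proportions summing to 1 and usable counts", {
  scores <- rbind(matrix(3, 10, 3))
  s <- summarize_agreement(scores)
  expect_equal(s$proportions[["unanimous"]], 1)
  expect_identical(s$usable, 10L)

  s2 <- summarize_agreement(rbind(c(1, 2, 3), c(2, 2, 2)))
  expect_equal(s2$proportions[["no_majority"]], 0.5)
  expect_equal(s2$proportions[["unanimous"]], 0.5)
  expect_identical(s2$usable, 1L)
  expect_equal(sum(s2$proportions), 1)
})

test_that("resolve_labels applies the vote and drops excluded repetitions", {
  layout <- tiny_layout()
  reps <- list(
    make_rep("a", layout = layout, scores = c(3L, 3L, 3L)),
    make_rep("b", layout = layout, scores = c(1L, 2L, 3L)),
    make_rep("c", layout = layout, scores = c(2L, 2L, 1L))
  )
  ds <- imu_dataset(reps, layout)
  res <- resolve_labels(ds)
  expect_identical(names(res$dataset$repetitions), c("a", "c"))
  expect_identical(res$dataset$repetitions[["a"]]$resolved_label, 3L)
  expect_identical(res$dataset$repetitions[["c"]]$resolved_label, 2L)
  expect_identical(res$summary$usable, 2L)
  kept <- resolve_labels(ds, drop_excluded = FALSE)
  expect_identical(length(kept$dataset), 3L)
  expect_true(is.na(kept$dataset$repetitions[["b"]]$resolved_label))
})

test_that("noise-free simulated raters are unanimous with alpha exactly 1", {
  ds <- generate_dataset(separable_config(seed = 5, n_subjects = 2L, reps_per_subject = 10L))
  ds <- simulate_raters(ds, rater_config(p_off_by_one = 0, p_off_by_two = 0, seed = 1))
  scores <- t(vapply(ds$repetitions, function(r) r$rater_scores, integer(3)))
  expect_identical(summarize_agreement(scores)$proportions[["unanimous"]], 1)
  expect_identical(krippendorff_alpha(scores), 1)
})
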
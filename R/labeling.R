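#' Krippendorff's alpha interrater reliability
#'
#' Chance-corrected agreement for an items-by-raters table of scores with
#' missing values allowed, computed from the coincidence matrix:
#' \deqn{\alpha = 1 - D_o / D_e,}
#' where the observed disagreement \eqn{D_o} sums the coincidence matrix
#' weighted by the squared difference function and the expected disagreement
#' \eqn{D_e} sums the products of the coincidence margins. For the `ordinal`
#' difference function,
#' \deqn{\delta^2(c,k) = \Big(\sum_{g=c}^{k} n_g - \frac{n_c + n_k}{2}\Big)^2,}
#' with \eqn{n_g} the coincidence-matrix margin of category \eqn{g}; `interval`
#' uses \eqn{(c-k)^2} and `nominal` uses the 0/1 indicator. Items with fewer
#' than two ratings contribute nothing (pairwise deletion of missing values).
#'
#' @param values numeric matrix, items in rows and raters in columns; `NA`
#'   marks a missing rating. Scores are treated as ordinal categories.
#' @param metric difference function: `"ordinal"` (default), `"nominal"` or
#'   `"interval"`.
#' @return alpha in (-1, 1]; exactly 1 under perfect agreement.
#' @details Errors when fewer than two items carry two or more ratings, or
#'   when the expected disagreement is zero (all pairable values identical),
#'   in which case alpha is undefined.
#' @seealso [majority_vote()], [summarize_agreement()]
#' @export
krippendorff_alpha <- function(values, metric = c("ordinal", "nominal", "interval")) {
  metric <- match.arg(metric)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  m_u <- rowSums(!is.na(values))
  pairable <- m_u >= 2L
  if (sum(pairable) < 2L) {
    stop("krippendorff_alpha requires at least 2 items with >= 2 ratings each", call. = FALSE)
  }
  vals <- values[pairable, , drop = FALSE]
  m_u <- m_u[pairable]
  cats <- sort(unique(as.vector(vals[!is.na(vals)])))
  ncat <- length(cats)
  if (ncat < 2L) {
    stop("alpha undefined: zero expected disagreement (all pairable values identical)",
      call. = FALSE
    )
  }

  # coincidence matrix: within each item, every ordered pair of ratings
  # contributes 1/(m_u - 1)
  o <- matrix(0, ncat, ncat)
  for (u in seq_len(nrow(vals))) {
    v <- vals[u, ]
    v <- v[!is.na(v)]
    idx <- match(v, cats)
    tab <- tabulate(idx, nbins = ncat)
    pair_counts <- outer(tab, tab) - diag(tab)
    o <- o + pair_counts / (length(v) - 1)
  }
  n_c <- rowSums(o)
  n <- sum(n_c)

  d2 <- switch(metric,
    nominal = 1 - diag(ncat),
    interval = outer(cats, cats, function(a, b) (a - b)^2),
    ordinal = {
      cum <- cumsum(n_c)
      # sum of margins between categories c..k inclusive, minus half the ends
      s <- outer(seq_len(ncat), seq_len(ncat), function(i, j) {
        lo <- pmin(i, j)
        hi <- pmax(i, j)
        (cum[hi] - cum[lo] + n_c[lo]) - (n_c[lo] + n_c[hi]) / 2
      })
      s^2
    }
  )

  d_o <- sum(o * d2)
  d_e <- (outer(n_c, n_c) - diag(n_c)) # expected pair counts scale
  d_e <- sum(d_e * d2) / (n - 1)
  if (d_e <= 0) {
    stop("alpha undefined: zero expected disagreement", call. = FALSE)
  }
  1 - d_o / d_e
}

AGREEMENT_LEVELS <- c("unanimous", "majority_minor", "majority_major", "no_majority")

#' Resolve three rater scores by majority vote
#'
#' Three equal scores are `unanimous`; two equal scores yield the repeated
#' value, flagged `majority_minor` when the discrepant score differs by one
#' point and `majority_major` when it differs by more; three distinct scores
#' admit no majority and the repetition is excluded (`label` is `NA`).
#'
#' @param scores exactly three ordinal scores in \{1, 2, 3\}.
#' @return a list of class `resolved_label` with elements `label` (integer or
#'   `NA`) and `agreement` (one of `"unanimous"`, `"majority_minor"`,
#'   `"majority_major"`, `"no_majority"`).
#' @export
majority_vote <- function(scores) {
  scores <- as.integer(scores)
  if (length(scores) != 3L || anyNA(scores) || !all(scores %in% SCORE_LEVELS)) {
    stop("majority_vote requires exactly 3 scores in {1,2,3}", call. = FALSE)
  }
  tab <- tabulate(scores, nbins = 3L)
  out <- if (any(tab == 3L)) {
    list(label = which(tab == 3L), agreement = "unanimous")
  } else if (any(tab == 2L)) {
    maj <- which(tab == 2L)
    minority <- which(tab == 1L)
    agreement <- if (abs(minority - maj) == 1L) "majority_minor" else "majority_major"
    list(label = maj, agreement = agreement)
  } else {
    list(label = NA_integer_, agreement = "no_majority")
  }
  out$label <- as.integer(out$label)
  class(out) <- "resolved_label"
  out
}

#' @export
print.resolved_label <- function(x, ...) {
  cat(sprintf(
    "<resolved_label> %s (%s)\n",
    ifelse(is.na(x$label), "excluded", x$label), x$agreement
  ))
  invisible(x)
}

#' Summarize rater agreement over a set of items
#'
#' @param scores items-by-3 matrix of rater scores in \{1, 2, 3\}.
#' @return list with `proportions` (named, over the four agreement
#'   categories, summing to 1), `counts`, and `usable` (items admitting a
#'   majority vote).
#' @export
summarize_agreement <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 3L) stop("each item needs exactly 3 rater scores", call. = FALSE)
  res <- apply(scores, 1L, function(s) majority_vote(s)$agreement)
  counts <- table(factor(res, levels = AGREEMENT_LEVELS))
  list(
    proportions = stats::setNames(as.numeric(counts) / nrow(scores), AGREEMENT_LEVELS),
    counts = stats::setNames(as.integer(counts), AGREEMENT_LEVELS),
    usable = sum(res != "no_majority")
  )
}

#' Resolve all rater scores of a dataset into final labels
#'
#' Applies [majority_vote()] to every repetition carrying three rater scores,
#' stores the resolved label (or `NA` for excluded no-majority items), and
#' returns the updated dataset together with an agreement report.
#'
#' @param dataset an [imu_dataset()] whose repetitions carry 3 rater scores.
#' @param drop_excluded drop no-majority repetitions from the returned
#'   dataset (default `TRUE`, mirroring their exclusion from training data).
#' @return list with `dataset` (labels resolved), `report` (per-repetition
#'   data.frame of scores, label and agreement) and `summary`
#'   (see [summarize_agreement()]).
#' @export
resolve_labels <- function(dataset, drop_excluded = TRUE) {
  stopifnot(inherits(dataset, "imu_dataset"))
  n_scores <- vapply(dataset$repetitions, function(r) length(r$rater_scores), integer(1))
  if (any(n_scores != 3L)) {
    stop("every repetition must carry exactly 3 rater scores", call. = FALSE)
  }
  rows <- lapply(dataset$repetitions, function(r) {
    rl <- majority_vote(r$rater_scores)
    data.frame(
      repetition_id = r$repetition_id,
      subject_id = r$subject_id,
      score_1 = r$rater_scores[1], score_2 = r$rater_scores[2], score_3 = r$rater_scores[3],
      label = rl$label, agreement = rl$agreement,
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  score_mat <- as.matrix(report[, c("score_1", "score_2", "score_3")])
  reps <- dataset$repetitions
  for (i in seq_along(reps)) reps[[i]]$resolved_label <- report$label[i]
  if (drop_excluded) reps <- reps[!is.na(report$label)]
  list(
    dataset = imu_dataset(reps, dataset$layout, dataset$manifest),
    report = report,
    summary = summarize_agreement(score_mat)
  )
}
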
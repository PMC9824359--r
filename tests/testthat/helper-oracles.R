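# Independent oracles, deliberately written as plain enumerations so they
# share no code path with the package implementations they check.

# Krippendorff's alpha by explicit pair enumeration. Observed disagreement:
# every ordered pair of ratings within an item, weighted 1/(m_u - 1);
# expected disagreement: every ordered pair of pooled values across
# different pair slots. The ordinal difference uses the coincidence margins.
oracle_krippendorff <- function(values, metric = "ordinal") {
  values <- as.matrix(values)
  keep <- rowSums(!is.na(values)) >= 2
  values <- values[keep, , drop = FALSE]
  stopifnot(nrow(values) >= 2)
  cats <- sort(unique(as.vector(values[!is.na(values)])))
  if (length(cats) < 2) stop("oracle: all values identical")

  # margins n_g from the same weighted pair counts
  n_g <- setNames(numeric(length(cats)), cats)
  pair_list <- list()
  for (u in seq_len(nrow(values))) {
    v <- values[u, ]
    v <- v[!is.na(v)]
    m_u <- length(v)
    for (a in seq_len(m_u)) {
      for (b in seq_len(m_u)) {
        if (a != b) {
          w <- 1 / (m_u - 1)
          pair_list[[length(pair_list) + 1]] <- c(v[a], v[b], w)
          n_g[as.character(v[a])] <- n_g[as.character(v[a])] + w / 2
          n_g[as.character(v[b])] <- n_g[as.character(v[b])] + w / 2
        }
      }
    }
  }
  pairs <- do.call(rbind, pair_list)
  n <- sum(n_g)

  delta2 <- function(c1, c2) {
    if (metric == "nominal") {
      return(as.numeric(c1 != c2))
    }
    if (metric == "interval") {
      return((c1 - c2)^2)
    }
    lo <- min(c1, c2)
    hi <- max(c1, c2)
    inside <- cats >= lo & cats <= hi
    (sum(n_g[inside]) - (n_g[as.character(lo)] + n_g[as.character(hi)]) / 2)^2
  }

  d_obs <- sum(apply(pairs, 1, function(p) p[3] * delta2(p[1], p[2]))) / n

  # expected: all ordered cross pairs of the pooled margin mass
  d_exp_num <- 0
  for (c1 in cats) {
    for (c2 in cats) {
      mass <- n_g[as.character(c1)] * n_g[as.character(c2)]
      if (c1 == c2) mass <- mass - n_g[as.character(c1)]
      d_exp_num <- d_exp_num + mass * delta2(c1, c2)
    }
  }
  d_exp <- d_exp_num / (n * (n - 1))
  if (d_exp <= 0) stop("oracle: zero expected disagreement")
  as.numeric(1 - d_obs / d_exp)
}

# F1 metrics straight from an explicitly assembled confusion matrix
oracle_f1 <- function(true, predicted, label_set = 1:3) {
  k <- length(label_set)
  cm <- matrix(0, k, k)
  for (i in seq_along(true)) {
    r <- which(label_set == true[i])
    c <- which(label_set == predicted[i])
    cm[r, c] <- cm[r, c] + 1
  }
  f1 <- numeric(k)
  for (j in seq_len(k)) {
    tp <- cm[j, j]
    fp <- sum(cm[, j]) - tp
    fn <- sum(cm[j, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[j] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  support <- rowSums(cm)
  list(
    macro = mean(f1),
    weighted = sum(f1 * support) / sum(support),
    per_class = f1, confusion = cm
  )
}

# chain 100 random vectors through the camera and room frames explicitly:
# v_cam = R_imu_cam v_imu; v_room = R_room_cam^-1 v_cam; v_seg = R_seg_room^-1 v_room
oracle_chain_vectors <- function(r_imu_cam, r_room_cam, r_seg_room, vecs) {
  apply(vecs, 2, function(v) {
    v_cam <- r_imu_cam %*% v
    v_room <- solve(r_room_cam) %*% v_cam
    solve(r_seg_room) %*% v_room
  })
}

# naive direct 2D convolution with "same" padding (stride 1)
oracle_conv2d <- function(A4, W, b) {
  d <- dim(A4)
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  ph <- floor((kh - 1) / 2)
  pw <- floor((kw - 1) / 2)
  out <- array(0, c(d[1], d[2], d[3], cout))
  for (m in seq_len(d[1])) {
    for (oh in seq_len(d[2])) {
      for (ow in seq_len(d[3])) {
        for (oc in seq_len(cout)) {
          s <- b[oc]
          for (i in seq_len(kh)) {
            for (j in seq_len(kw)) {
              hi <- oh + i - 1 - ph
              wi <- ow + j - 1 - pw
              if (hi >= 1 && hi <= d[2] && wi >= 1 && wi <= d[3]) {
                s <- s + sum(A4[m, hi, wi, ] * W[i, j, , oc])
              }
            }
          }
          out[m, oh, ow, oc] <- s
        }
      }
    }
  }
  out
}

# pooled mean / population sd over explicitly enumerated values
oracle_pooled_stats <- function(mats, rows) {
  vals <- c()
  for (m in mats) {
    for (r in rows) {
      vals <- c(vals, m[r, ])
    }
  }
  list(mean = mean(vals), sd = sqrt(mean((vals - mean(vals))^2)))
}
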
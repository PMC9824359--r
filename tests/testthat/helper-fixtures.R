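# shared miniature fixtures, all generated in code

tiny_layout <- function(n_imus = 2L) imu_layout(n_imus)

# a deterministic repetition with recognizable values
make_rep <- function(id = "r1", subject = "s1", t_len = 10L, layout = tiny_layout(),
                     scores = integer(0), label = NA_integer_, fill = NULL) {
  C <- n_channel_rows(layout)
  data <- if (is.null(fill)) {
    matrix(seq_len(C * t_len) / 10, C, t_len)
  } else {
    matrix(fill, C, t_len)
  }
  repetition(id, subject, "DS", data, layout,
    rater_scores = scores, resolved_label = label
  )
}

make_dataset <- function(n = 3L, layout = tiny_layout(), t_lens = NULL) {
  t_lens <- t_lens %||% (9L + seq_len(n))
  reps <- lapply(seq_len(n), function(i) {
    make_rep(sprintf("r%d", i), sprintf("s%d", (i %% 2) + 1), t_lens[i], layout,
      scores = c(1L, 2L, 3L)[c(i %% 3 + 1, i %% 3 + 1, (i + 1) %% 3 + 1)],
      label = (i %% 3) + 1L
    )
  })
  imu_dataset(reps, layout)
}

# small, quickly separable synthetic dataset for training tests
separable_config <- function(seed = 11, n_subjects = 5L, reps_per_subject = 12L,
                             n_imus = 2L) {
  synthetic_config(
    n_subjects = n_subjects, reps_per_subject = reps_per_subject, n_imus = n_imus,
    duration_range = c(0.4, 0.8), deviation_amplitude = 3, restriction_factor = 0.5,
    subject_effect_scale = 0.05, noise_sd = 0.05,
    affected_segments = min(2L, n_imus), seed = seed
  )
}

# small architecture for fast structural / gradient tests
tiny_arch <- function(...) {
  cfg <- architecture_config(...)
  cfg$lstm_units <- 8L
  cfg$dense_units <- c(6L, 5L, 3L)
  cfg
}
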
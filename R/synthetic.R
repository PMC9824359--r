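#' Configuration of the synthetic repetition generator
#'
#' The generator emulates the statistical structure the scoring method
#' assumes, standing in for privacy-restricted clinical recordings:
#' repetitions of variable duration, a smooth per-segment motion template
#' shared by all subjects, per-subject amplitude and timing idiosyncrasies,
#' class-dependent deviations (quality "2": a localized compensation burst on
#' a subset of body segments; quality "1": the burst plus a global range
#' restriction), additive sensor noise, and — via [simulate_raters()] — noisy
#' three-rater scoring. It does not attempt biomechanically realistic
#' kinematics.
#'
#' @param n_subjects number of subjects (default 17).
#' @param reps_per_subject repetitions per subject (default 45).
#' @param class_probabilities length-3 probability vector over true quality
#'   scores (1, 2, 3); default `c(0.2, 0.4, 0.4)` — quality "1" is typically
#'   the rarest outcome in screening data.
#' @param duration_range repetition duration range in seconds, drawn
#'   uniformly (default 2 to 6 s).
#' @param sampling_rate Hz (default 120).
#' @param base_amplitude list with `accel` (g) and `gyro` (degrees/s) motion
#'   scales; defaults 0.5 g and 50 degrees/s, well inside the +-16 g and
#'   +-200 degrees/s sensor ranges.
#' @param deviation_amplitude amplitude of the class "1"/"2" compensation
#'   burst, as a multiple of the modality base amplitude (default 1).
#' @param restriction_factor multiplicative amplitude shrink of class "1"
#'   repetitions, in (0, 1) (default 0.6).
#' @param subject_effect_scale s.d. of the per-subject log-normal amplitude
#'   and time-warp multipliers (default 0.1).
#' @param noise_sd additive white Gaussian sensor noise, as a fraction of the
#'   modality base amplitude (default 0.05).
#' @param affected_segments number of IMUs carrying the class signal
#'   (default 4); drawn once per dataset.
#' @param n_imus number of IMUs in the layout (default 17).
#' @param exercise exercise code stored in the metadata (default `"DS"`).
#' @param seed integer seed; movement and rater streams are derived from it
#'   independently.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 17L, reps_per_subject = 45L,
                             class_probabilities = c(0.2, 0.4, 0.4),
                             duration_range = c(2, 6), sampling_rate = 120,
                             base_amplitude = list(accel = 0.5, gyro = 50),
                             deviation_amplitude = 1, restriction_factor = 0.6,
                             subject_effect_scale = 0.1, noise_sd = 0.05,
                             affected_segments = 4L, n_imus = 17L,
                             exercise = "DS", seed = 1L) {
  stop_if_not_count(n_subjects, "n_subjects")
  stop_if_not_count(reps_per_subject, "reps_per_subject")
  if (length(class_probabilities) != 3L || any(class_probabilities < 0) ||
    abs(sum(class_probabilities) - 1) > 1e-8) {
    stop("`class_probabilities` must be 3 nonnegative values summing to 1", call. = FALSE)
  }
  if (length(duration_range) != 2L || any(duration_range <= 0) ||
    duration_range[1] > duration_range[2]) {
    stop("`duration_range` must be positive and ordered", call. = FALSE)
  }
  if (!is_scalar_number(restriction_factor) || restriction_factor <= 0 || restriction_factor >= 1) {
    stop("`restriction_factor` must lie in (0, 1)", call. = FALSE)
  }
  if (deviation_amplitude < 0 || noise_sd < 0 || subject_effect_scale < 0) {
    stop("amplitudes and scales must be nonnegative", call. = FALSE)
  }
  stop_if_not_count(affected_segments, "affected_segments")
  stop_if_not_count(n_imus, "n_imus")
  if (affected_segments > n_imus) stop("`affected_segments` exceeds `n_imus`", call. = FALSE)
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      reps_per_subject = as.integer(reps_per_subject),
      class_probabilities = as.numeric(class_probabilities),
      duration_range = as.numeric(duration_range),
      sampling_rate = as.numeric(sampling_rate),
      base_amplitude = base_amplitude,
      deviation_amplitude = as.numeric(deviation_amplitude),
      restriction_factor = as.numeric(restriction_factor),
      subject_effect_scale = as.numeric(subject_effect_scale),
      noise_sd = as.numeric(noise_sd),
      affected_segments = as.integer(affected_segments),
      n_imus = as.integer(n_imus),
      exercise = match.arg(exercise, EXERCISES),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# smooth motion template: per channel, a sum of 3 Gaussian-windowed sinusoids
# evaluated on normalized phase u in [0,1]
draw_template_params <- function(n_channels, n_components = 3L) {
  list(
    amp = matrix(stats::runif(n_channels * n_components, 0.3, 1), n_channels),
    freq = matrix(stats::runif(n_channels * n_components, 0.5, 3), n_channels),
    phase = matrix(stats::runif(n_channels * n_components, 0, 2 * pi), n_channels),
    center = matrix(stats::runif(n_channels * n_components, 0.2, 0.8), n_channels),
    width = matrix(stats::runif(n_channels * n_components, 0.15, 0.4), n_channels)
  )
}

eval_template <- function(tpl, u, rows) {
  out <- matrix(0, length(rows), length(u))
  for (j in seq_len(ncol(tpl$amp))) {
    for (i in seq_along(rows)) {
      r <- rows[i]
      out[i, ] <- out[i, ] + tpl$amp[r, j] *
        sin(2 * pi * tpl$freq[r, j] * u + tpl$phase[r, j]) *
        exp(-(u - tpl$center[r, j])^2 / (2 * tpl$width[r, j]^2))
    }
  }
  out
}

#' Generate a synthetic labeled dataset
#'
#' Builds `n_subjects * reps_per_subject` repetitions. Each repetition is
#' constructed as (a) a smooth per-segment template (sum of Gaussian-windowed
#' sinusoids over the repetition's normalized phase), (b) subject-specific
#' multiplicative amplitude and global time-warp factors drawn once per
#' subject, (c) a class effect — score 3: template unchanged; score 2: one
#' localized deviation burst added on the affected IMUs at a random phase;
#' score 1: amplitudes shrunk by `restriction_factor` plus the burst — and
#' (d) additive white Gaussian noise. The true score is stored as
#' `resolved_label`. Fully reproducible from `config$seed`; the caller's RNG
#' state is untouched.
#'
#' @param config a [synthetic_config()].
#' @return an [imu_dataset()] whose manifest records the generator settings.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  layout <- imu_layout(config$n_imus)
  C <- n_channel_rows(layout)
  fs <- config$sampling_rate
  acc_rows <- accel_rows(layout)
  modality_scale <- numeric(C)
  modality_scale[acc_rows] <- config$base_amplitude$accel
  modality_scale[setdiff(seq_len(C), acc_rows)] <- config$base_amplitude$gyro

  with_seed(derive_seed(config$seed, "movement"), {
    tpl <- draw_template_params(C)
    affected <- sort(sample.int(config$n_imus, config$affected_segments))
    affected_rows <- sort(unlist(lapply(affected - 1L, imu_rows, layout = layout)))
    # fixed per-dataset burst signature across the affected channels
    burst_weight <- stats::runif(length(affected_rows), 0.5, 1) *
      sample(c(-1, 1), length(affected_rows), replace = TRUE)
    burst_freq <- stats::runif(1, 4, 8)

    n_total <- config$n_subjects * config$reps_per_subject
    labels <- sample.int(3L, n_total, replace = TRUE, prob = config$class_probabilities)
    subj_amp <- exp(stats::rnorm(config$n_subjects, 0, config$subject_effect_scale))
    subj_warp <- exp(stats::rnorm(config$n_subjects, 0, config$subject_effect_scale))

    reps <- vector("list", n_total)
    i <- 0L
    for (s in seq_len(config$n_subjects)) {
      for (k in seq_len(config$reps_per_subject)) {
        i <- i + 1L
        # drawn unconditionally on the label so the kinematic stream is
        # label-independent (degenerate configs carry no class signal)
        duration <- stats::runif(1, config$duration_range[1], config$duration_range[2])
        burst_center <- stats::runif(1, 0.15, 0.85)
        burst_width <- stats::runif(1, 0.04, 0.08)
        T_len <- max(1L, as.integer(round(duration * fs)))
        u <- (seq_len(T_len) - 1L) / max(1L, T_len - 1L)
        u_warped <- u^subj_warp[s]

        mat <- eval_template(tpl, u_warped, seq_len(C)) * subj_amp[s] * modality_scale
        lab <- labels[i]
        if (lab == 1L) mat <- mat * config$restriction_factor
        if (lab %in% c(1L, 2L)) {
          burst_env <- exp(-(u - burst_center)^2 / (2 * burst_width^2)) *
            sin(2 * pi * burst_freq * (u - burst_center))
          mat[affected_rows, ] <- mat[affected_rows, ] +
            config$deviation_amplitude * subj_amp[s] *
              (burst_weight * modality_scale[affected_rows]) %o% burst_env
        }
        if (config$noise_sd > 0) {
          mat <- mat + matrix(stats::rnorm(C * T_len), C, T_len) *
            (config$noise_sd * modality_scale)
        }
        reps[[i]] <- repetition(
          repetition_id = sprintf("S%02d_R%03d", s, k),
          subject_id = sprintf("S%02d", s),
          exercise = config$exercise,
          data = mat,
          layout = layout,
          sampling_rate = fs,
          resolved_label = lab
        )
      }
    }
    imu_dataset(reps, layout, manifest = list(
      generator = "imuqc-synthetic",
      seed = config$seed,
      config = config[setdiff(names(config), "base_amplitude")],
      base_amplitude = config$base_amplitude,
      affected_imus = affected
    ))
  })
}

#' Configuration of the simulated rater panel
#'
#' @param n_raters number of raters (default 3).
#' @param p_off_by_one probability a rater reports the true score +-1
#'   (clipped to the 1..3 scale, so extremes can only err inward).
#' @param p_off_by_two probability of a two-point error; for a true score of
#'   2 a two-point error is impossible on the 1..3 scale and degrades to an
#'   off-by-one error.
#' @param seed integer seed for the rater stream.
#' @return object of class `rater_config`.
#' @export
rater_config <- function(n_raters = 3L, p_off_by_one = 0.1, p_off_by_two = 0.02,
                         seed = 1L) {
  stop_if_not_count(n_raters, "n_raters")
  if (p_off_by_one < 0 || p_off_by_two < 0 || p_off_by_one + p_off_by_two > 1) {
    stop("rater error probabilities must be nonnegative with sum <= 1", call. = FALSE)
  }
  structure(
    list(
      n_raters = as.integer(n_raters),
      p_off_by_one = as.numeric(p_off_by_one),
      p_off_by_two = as.numeric(p_off_by_two),
      seed = as.integer(seed)
    ),
    class = "rater_config"
  )
}

#' Simulate independent noisy raters for a labeled dataset
#'
#' Each rater independently reports the true label, or with probability
#' `p_off_by_one` an adjacent score (true +-1, clipped to 1..3), or with
#' probability `p_off_by_two` a two-point error (1 <-> 3; impossible for a
#' true score of 2, where it degrades to an adjacent error). Reproducible
#' from `config$seed`; the movement data are untouched, so rater noise can be
#' varied at fixed kinematics.
#'
#' @param dataset an [imu_dataset()] with `resolved_label` set on every
#'   repetition (the true labels).
#' @param config a [rater_config()].
#' @return the dataset with `rater_scores` filled on every repetition.
#' @export
simulate_raters <- function(dataset, config) {
  stopifnot(inherits(dataset, "imu_dataset"), inherits(config, "rater_config"))
  truth <- dataset_labels(dataset)
  if (anyNA(truth)) stop("every repetition needs a true resolved_label", call. = FALSE)
  with_seed(derive_seed(config$seed, "raters"), {
    reps <- dataset$repetitions
    for (i in seq_along(reps)) {
      scores <- vapply(seq_len(config$n_raters), function(j) {
        draw_rating(truth[i], config$p_off_by_one, config$p_off_by_two)
      }, integer(1))
      reps[[i]]$rater_scores <- scores
    }
    imu_dataset(reps, dataset$layout, dataset$manifest)
  })
}

draw_rating <- function(true, p1, p2) {
  u <- stats::runif(1)
  if (u < p2) {
    if (true == 1L) return(3L)
    if (true == 3L) return(1L)
    # true == 2: two-point error impossible, fall back to adjacent
    return(if (stats::runif(1) < 0.5) 1L else 3L)
  }
  if (u < p2 + p1) {
    if (true == 1L) return(2L)
    if (true == 3L) return(2L)
    return(if (stats::runif(1) < 0.5) 1L else 3L)
  }
  as.integer(true)
}
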
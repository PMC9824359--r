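---
title: "Scoring exercise repetitions from body-worn IMU networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring exercise repetitions from body-worn IMU networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Screening systems such as the Functional Movement Screen grade a single
exercise repetition on an ordinal quality scale: **3** (perfect execution),
**2** (complete execution with compensation movements), **1** (incomplete
execution). `imuqc` implements an automatic scorer for repetitions recorded
by a body-worn network of inertial measurement units (IMUs) — by default 17
units, one per body segment, each providing a 3-axis accelerometer (±16 g)
and a 3-axis gyroscope (±200 °/s) at 120 Hz. One repetition is a matrix of
`6 × n_imus` channel rows by a *variable* number of time steps: repetitions
differ substantially in duration, and the quality label refers to the whole
repetition, so the classifier must consume an entire repetition rather than
fixed-length snippets.

The package covers the full workflow: dataset container and plain-text
storage, multi-rater label resolution with reliability estimation,
sensor-to-segment alignment, the windowed input representation, three
CNN-LSTM network variants with training and evaluation protocols, a seeded
random hyperparameter search, and a synthetic-data generator that stands in
for the (privacy-restricted) kind of clinical dataset the method targets.

## Label resolution and reliability

Each repetition is scored independently by three raters. `majority_vote()`
resolves a triple into a final label: unanimous triples keep their value;
two-against-one triples take the repeated value, flagged `majority_minor`
(discrepancy of one point) or `majority_major` (more than one point);
triples with three distinct values admit no majority and are excluded from
training data. Over all 27 possible triples the categories partition as
3 / 12 / 6 / 6.

Interrater reliability uses Krippendorff's alpha with the ordinal
difference function,
$$\alpha = 1 - D_o / D_e, \qquad
  \delta^2(c,k) = \Big(\sum_{g=c}^{k} n_g - \tfrac{n_c + n_k}{2}\Big)^2,$$
computed from the coincidence matrix over pairable values, with missing
ratings excluded pairwise. The coincidence formulation is the canonical
implementation; the test suite checks it against an independent
pair-enumeration oracle to 1e-10. Alpha is undefined (the function raises
an error) when all pairable values coincide, since the expected
disagreement is then zero.

## Sensor-to-segment alignment

Mounting orientation differs between subjects, so triaxial data are rotated
into per-segment frames before learning. The rotation is composed from
marker-derived orientations (`R_a_to_b` maps coordinates from frame `a` to
frame `b`):
$$R_{imu \to seg} = R_{seg \to room}^{-1}\, R_{room \to cam}^{-1}\, R_{imu \to cam}.$$
`apply_alignment()` applies one rotation per IMU to both the accelerometer
and the gyroscope triplet (rigid-sensor assumption); norms are preserved at
every sample. Marker detection and camera calibration are upstream,
hardware-bound steps and out of scope: rotations are consumed as matrices.
Alignment is treated as dataset preparation preceding all preprocessing.

## Input representation

1. **Stacking.** Channels are arranged as rows, IMU by IMU, accelerometer
   x/y/z then gyroscope x/y/z; channel `c` of IMU `k` (0-based) is row
   `6k + c`.
2. **Standardization.** Pooled mean and population s.d. are computed
   separately for all accelerometer and all gyroscope values *of the
   training split only* and applied everywhere; pooling across channels
   (not per channel) preserves relative axis amplitudes. Constant pools
   are an error.
3. **Zero padding.** Every repetition is padded with exact zeros to `L`
   samples, where `L` defaults to the training split's maximum length
   rounded up to a multiple of the window count. Padding happens *after*
   standardization so the pad value is exactly zero and the all-zero-window
   test below is well defined. A repetition longer than `L` raises an error
   rather than being silently truncated.
4. **Windowing.** The padded matrix is cut into `X` equal, non-overlapping
   windows (default `X = 10`; the window width `W = L/X` must be at least 8
   samples). A boolean mask marks windows that overlap the recorded
   samples; all-padding windows are masked out.

Resampling repetitions to a common length is deliberately not offered: it
destroys the temporal context (measured acceleration relative to measured
time) that the recurrent stage relies on.

The mask is computed from the raw windows and carried alongside the data to
the recurrent stage. This is a deliberate design choice: convolution biases
make the CNN output of an all-zero window nonzero, so value-sniffing after
the CNN could not identify padding reliably.

## Network architectures

All variants share the same skeleton: a stack of 1–3 **CNN-blocks**
(convolution + 2×2 max-pooling + dropout(0.2) or batch normalization)
applied identically to every window (shared weights), a masked recurrence
of 1–2 LSTM layers with 256 units (tanh activation, sigmoid recurrent
activation), and a dense head of 512 / 128 / 3 neurons with softmax output.
Filters increase over blocks as 16/32/64. The variants differ only in how
convolution sees the channels:

* **baseline** — one stacked channels-by-time image; square kernels, either
  5×5 throughout (`fixed_kernel`) or 9×9 / 5×5 / 3×3 (`decreasing_kernel`);
* **imu_centric** — one convolutional branch per IMU on its own 6-row
  image, kernels (1, 5); per-window branch outputs are concatenated before
  the recurrence;
* **channel_centric** — the stacked image, but (1, 5) kernels so each
  channel row is convolved over time with shared filters.

Fixed constants: Glorot-uniform initialization, Adam with learning rate
0.0001, categorical cross-entropy. Tunable hyperparameters and their
domains (`hyperparameter_grid()`): activation ReLU/ELU/LReLU, 1–3 blocks,
two kernel schemes, dropout vs batch norm, 1–2 LSTM layers, batch size
4/8/16/32 — a 288-cell grid sampled uniformly by the seeded
`random_search()` (90 runs by default; independent draws may repeat, a
`dedupe` switch is available but off by default).

### Numerical choices

* Convolutions use "same" spatial padding (stride 1), so 1–3 block stacks
  remain valid for small windows and for the 6-row per-IMU images.
* Pooling is 2×2 with *clipping*: an axis shorter than 2 is not pooled
  (needed for the per-IMU branch, whose channel axis shrinks 6 → 3 → 1 → 1);
  output sizes use floor division, and trailing odd rows receive no
  gradient, matching common framework behaviour.
* A masked step leaves the LSTM hidden and cell state bit-identical, so
  appending masked windows never changes the output (the masking contract is
  exact, not approximate).
* LeakyReLU slope 0.3; ELU α = 1; batch normalization ε = 1e-3 with
  momentum 0.99 on running statistics; Adam ε = 1e-7; LSTM forget-gate bias
  initialized to 1, all other biases 0 (weights Glorot-uniform).
* The engine is implemented natively on BLAS matrix products (no
  deep-learning framework dependency); gradients of every layer are
  validated against central finite differences in the test suite, using a
  smooth configuration (ELU + batch normalization) because dropout is
  stochastic and ReLU/LReLU kinks break finite differences.

## Training and evaluation protocols

**Within-subject evaluation** (`run_cv()`): `n` independent stratified
shuffle splits — 20% test, 16% validation, 64% training of the whole set
(the validation set is 20% of the remaining 80%). Standardization
parameters and the pad length are refitted per fold from that fold's
training split only; the suite asserts this no-leakage property. Headline
metric: macro F1, the unweighted mean of per-class F1 over the fixed label
set {1, 2, 3} with the 0-convention for undefined precision/recall (a class
absent from both truth and prediction contributes 0 — conservative).

**Unknown-subject evaluation** (`run_losocv()`): each fold holds out the
complete data of one subject; the rest splits 80/20 stratified. Held-out
subjects are drawn by seeded sampling without replacement when fewer folds
than subjects are requested. Headline metric: weighted (support-weighted)
F1, because single subjects often carry one-sided label distributions that
would distort macro F1.

**Stopping rule.** The epoch budget is not prescribed by the protocol the
package follows; the package default is at most 300 epochs with early
stopping on validation loss (patience 30) and restoration of the
best-validation weights — bounded desk-scale runtime with stable selection.
`patience = 0` stops after the first non-improving epoch.

**Headline configuration** (`headline_config()`): baseline variant, three
blocks with fixed 5×5 kernels, ELU, dropout 0.2, two LSTM layers, batch
size 32 — the combination that wins the random search in the study this
design follows.

## The synthetic generator: what it emulates, and what it does not

Real screening datasets of this kind are privacy-restricted, so the
package ships a generator (`generate_dataset()`) that reproduces the
*statistical structure* the method assumes:

* **variable durations** — drawn uniformly from `duration_range` (default
  2–6 s) and rounded to whole samples at 120 Hz; no duration distribution is
  assumed beyond the stated range;
* **shared motion template** — per channel, a sum of three
  Gaussian-windowed sinusoids over normalized phase, drawn once per
  dataset;
* **subject idiosyncrasy** — one multiplicative amplitude factor and one
  global time-warp exponent per subject, log-normal with spread
  `subject_effect_scale`; raising it makes leave-one-subject-out harder in
  a controlled way;
* **class effects** — score 3: template unchanged; score 2: a localized
  oscillatory burst at a random phase, confined to `affected_segments`
  IMUs (default 4) so that detection requires multi-sensor integration;
  score 1: global amplitude shrink by `restriction_factor` (default 0.6)
  plus the burst — mirroring "compensation" vs "restriction" semantics;
* **sensor noise** — additive white Gaussian noise, s.d. expressed as a
  fraction of the modality base amplitude (defaults 0.5 g / 50 °/s motion
  scale, noise 0.05);
* **noisy raters** (`simulate_raters()`) — each rater independently reports
  the truth, an adjacent score (probability `p_off_by_one`, clipped to the
  scale so extremes err inward), or a two-point error (`p_off_by_two`;
  impossible for a true score of 2, where it degrades to an adjacent
  error). Movement and rater noise use independent seeded streams, so rater
  noise can be varied at fixed kinematics.

Class probabilities default to (0.2, 0.4, 0.4): screening data are
typically skewed with the lowest score rarest. The kinematic draws are
label-independent, so degenerate settings (zero deviation, restriction ≈ 1,
zero noise) yield classes that genuinely carry no signal.

The generator makes no attempt at biomechanical realism: there is no
skeleton model, no gravity component in the accelerometer channels, no
inter-segment kinematic consistency, and the burst model for compensation
movements is an artifact choice, not an empirical claim. A green end-to-end
test therefore establishes that the pipeline can recover planted class
structure of the stated form at the stated noise levels — not that it
reaches any particular performance on real clinical recordings.

## Scale of the shipped acceptance checks

The two training-based acceptance tests run at reduced scale so the whole
suite fits a single-CPU budget: sub-second repetitions (the window width is
held at its minimum of 8 samples), 5 IMUs for the within-subject recovery
check (17 subjects × 35 repetitions, headline configuration, 30-epoch
budget) and 4 IMUs / 120 repetitions with a 2-block, 1-LSTM configuration
for the subject-effect degradation check. Runtime grows roughly linearly in
repetitions × channel rows × padded length, so full-scale runs (102 rows,
multi-second repetitions) are possible but take hours per configuration on
one CPU.

## Known limitations

* Ordinal structure of the labels is ignored by the loss (categorical
  cross-entropy treats 1/2/3 as nominal), as in the protocol followed.
* Label resolution is defined for exactly three raters.
* The native engine is CPU-only and single-threaded apart from BLAS; it is
  meant for desk-scale experiments, not GPU-scale training.
* Repetition segmentation (cutting a recording into repetitions) is
  upstream and out of scope.
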
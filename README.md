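# carrysense

Automatic detection of infant **carrying and holding (C/H)** — episodes of
physical infant–caregiver contact — from multi-sensor wearable IMU
recordings (one tri-axial accelerometer + gyroscope per limb, nominally
52 Hz), for researchers quantifying caregiver interaction or cleaning
"carried" periods out of at-home infant motor-assessment recordings.

## What it implements

* **Annotation scheme.** Five interaction categories — independent movement
  (IM), passive/active support (PS/AS), passive/active carry (PC/AC) — plus
  an out-of-screen (OOS) mask, with five binary collations of
  carry-vs-non-carry ranging from strict (def1: carry = {AC}) to loose
  (def5: carry = {PS, AS, PC, AC}).
* **Classifier.** An end-to-end neural sequence model over 2.3 s frames
  (120 samples, 50% overlap): a multi-head convolutional encoder performs
  frame-level intra- and inter-sensor fusion of the accelerometer and
  gyroscope channels into a latent vector, and a temporal module of
  residual blocks with gated dilated 1-D convolutions (kernel 3, dilations
  1, 2, 4, 8) models frame-to-frame dynamics before a softmax readout.
  Training uses inverse-class-frequency weighted cross-entropy, Adam
  (lr 1e-4, beta1 0.9, beta2 0.999, eps 1e-8), batches of 100 consecutive
  frames, sample and sensor dropout (p = 0.3), and epoch selection by
  held-out unweighted average F1. The forward and backward passes are
  implemented in vectorized base R; no deep-learning framework is needed.
* **Metrics.** Confusion matrices on jointly valid frames; Cohen's kappa
  (binary closed form `2(tp·tn − fn·fp) / [(tp+fp)(fp+tn) + (tp+fn)(fn+tn)]`
  and the general multi-class form), accuracy, one-vs-rest
  precision/recall/F1 with proportion-weighted and unweighted averages;
  dual-annotator consensus evaluation.
* **Actigraphy baseline.** Single-sensor activity counts: accelerometer
  magnitude → 1–6 Hz band-pass (4th-order Butterworth, zero-phase) →
  per-frame sum of absolute values, thresholded over a swept grid.
* **Synthetic data.** A semi-Markov label process over the five categories
  (IM ≈ 85% occupancy, interaction segments mostly 1–10 s) driving a
  physically motivated signal model (wandering gravity orientation,
  independent limb bursts during IM, a shared low-frequency oscillation
  across sensors while the caregiver moves the infant), plus simulated
  annotators with boundary jitter, label confusion and OOS insertions.
* **Ablation harness.** Sensor subsets × sampling rates (52/26/13 Hz,
  simulated by decimate–upsample–low-pass) × input modalities
  (acc+gyro, gravity-split accelerometer, raw accelerometer), with shared
  cross-validation folds and paired two-tailed t-tests between cells.

## Worked example

```r
library(carrysense)

cfg  <- synth_config(duration_s = 600)       # 10-minute recordings
ds   <- synth_dataset(10, cfg, seed = 1)     # recordings + 2 annotators each
fcfg <- framing_config()                     # 2.3 s / 50% overlap

# inter-rater agreement of the simulated annotators (def2 carry scheme)
fr  <- make_frames(assemble_input(ds[[1]]$rec, "acc_gyro"), fcfg)
a1  <- to_frame_labels(ds[[1]]$annotations[[1]], fr, "def2")
a2  <- to_frame_labels(ds[[1]]$annotations[[2]], fr, "def2")
kappa_multiclass(confusion(a1, a2))
#> [1] 0.7920612

# train the def2 classifier with 5-fold cross-validation (reduced width)
items <- prepare_items(ds, scheme = "def2", use_truth = TRUE)
mcfg  <- model_config(n_sensors = 4, latent_dim = 32, enc_filters = c(8, 16))
tcfg  <- training_config(epochs = 15, learning_rate = 1e-3, n_folds = 5,
                         seed = 1, class_weight_power = 0.5)
cv <- crossvalidate(items, mcfg, tcfg)
cv
#> <ch_cv> 5 folds over 10 recordings
#>   kappa: mean 0.549 (range 0.268-0.717)

# actigraphy baseline on the first recording: far below the classifier
act <- actigraphy_counts(ds[[1]]$rec, "left_arm", fcfg)
ref <- to_frame_labels(ds[[1]]$truth, fr, "def2")
threshold_sweep(act, ref)
#> <ch_sweep> 200 thresholds; best kappa 0.169 (acc 93.8%) at 85.4
```

The cross-validated kappa (here ≈ 0.55 at this reduced size; ≈ 0.62 at the
reference benchmark's 20 recordings and 30 epochs) measures
chance-corrected frame-level agreement between the classifier and the
ground truth; the actigraphy sweep's best kappa (≈ 0.17) shows that
thresholded activity counts barely separate carrying from the infant's own
movement, because both produce signal energy — the discriminating
information is the *cross-sensor synchrony* of the movement, which the
classifier's inter-sensor fusion captures.

A command-line interface wrapping these functions is installed at
`inst/cli/carrysense` (`convert`, `synth`, `evaluate`, `actigraphy`,
`train`, `predict`, `ablate`).

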
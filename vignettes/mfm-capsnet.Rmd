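---
title: "Multiband feature matrices and capsule networks for EEG emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiband feature matrices and capsule networks for EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Affective state leaves measurable traces in scalp EEG: the balance of
oscillatory power across the canonical frequency bands differs between, say,
calm and aroused states, and the spatial distribution of that power across
the scalp carries additional information. `eegcaps` implements a complete
pipeline that turns multi-channel EEG trials into a compact image-like
representation — the *multiband feature matrix* (MFM) — and classifies it
with a capsule network, one independent binary problem per affective
dimension (valence, arousal, dominance, each self-rated on a continuous 1–9
scale and binarized at 5, with a rating exactly at 5 counting as "high").

The expected recording layout is the standard 32-channel affective-computing
format: per subject, 40 trials of 63 s at 128 Hz (the first 3 s being a
pre-stimulus baseline), with a 40 × 4 matrix of self-assessment ratings
(valence, arousal, dominance, liking — liking is carried through but never
used as a classification target).

# From signal to features

**Segmentation.** The 3-s baseline of each trial is discarded (not
subtracted — the pipeline treats the post-baseline signal as-is), and the
remaining 60 s are cut into non-overlapping 3-s windows: 20 windows per
trial, 800 per subject, each inheriting its trial's binarized labels. Any
tail shorter than one window is dropped; with the default geometry there is
none. Treating windows as independent samples multiplies the training set
by 20 at the cost of within-trial dependence between samples; see
*Evaluation protocol* below for the consequences.

**Band power.** Each window's per-channel power spectral density is
estimated with Welch's method: 1-s (128-sample) periodic Hann tapers with
50% overlap (five tapers per 3-s window), one-sided, in linear units of
µV²/Hz — no log transform. The mean PSD over the bins of each band is the
feature:

* theta 4–8 Hz, alpha 8–15 Hz, beta 15–32 Hz, gamma 32–45 Hz.

Band membership uses half-open intervals [low, high), so a shared edge
(8, 15, 32 Hz) is counted once, in the upper band. With 32 channels × 4
bands each window yields 128 features. For throughput the batched feature
path evaluates only the DFT bins that fall inside some band, as two real
matrix products with the taper folded into the basis; this is numerically
identical (to ~1e-14 relative) to the FFT-based estimator exposed by
`welch_psd()`, and the test suite cross-checks both against a brute-force
O(N²) DFT oracle.

**Per-subject normalization.** Within each subject and each feature column
(channel × band pair), features are min–max normalized as

    F' = (Fmax − F) / (Fmax − Fmin)

Note the orientation: the column *maximum* maps to 0 and the *minimum* to 1.
This order-reversing form is the package default (`orientation =
"inverted"`); since a fixed monotone relabeling of the input scale carries
the same information, a classifier is essentially indifferent to it, but the
orientation is exposed (`orientation = "standard"` restores
`(F − Fmin)/(Fmax − Fmin)`) so users can choose. A degenerate column
(`Fmax == Fmin`) maps to 0. Extrema are computed per column over *all* of a
subject's segments before any train/test split; this leaks rank information
across folds, so a fold-safe mode (`extrema_rows =` training rows, with
out-of-range values clipped to [0, 1]) is provided as an option. Whether
normalization should pool all 128 columns into one per-subject min–max
rather than work per column is a genuinely open choice; per column is
implemented because it gives every channel–band pair the full [0, 1]
dynamic range.

# The multiband feature matrix

Each band's 32 channel values are placed on a 9 × 9 grid that mirrors the
10–20 electrode layout: rows run anterior to posterior, columns left to
right, the midline (Fz, Cz, Pz, Oz) sits in column 4 (0-based), and every
homologous left/right pair occupies mirror columns (col and 8 − col) of the
same row — an invariant the test suite enforces. Cells without an electrode
take a configurable fill value, 0 by default. The grid coordinates are a
declared package constant (`deap_montage()`), replaceable via the `montage`
argument should a user prefer a different reading of the scalp topology.

The four 9 × 9 band grids tile into the 18 × 18 MFM in a fixed 2 × 2 layout
(theta top-left, alpha top-right, beta bottom-left, gamma bottom-right).
The tiling order is a configuration constant: classification is invariant
to any fixed quadrant relabeling. Each MFM carries exactly 4 × 32 = 128
electrode cells; a pooled 32-subject run yields 25,600 MFMs (800 × 32).

# The capsule network

The classifier reads one 18 × 18 MFM (values in [0, 1] after
normalization):

1. **Conv + ReLU** — 3 × 3 kernels, stride 1, no padding, 256 filters:
   output 16 × 16 × 256.
2. **Primary capsules** — a second conv, 3 × 3, stride 2, no padding,
   giving 7 × 7 × 256, read as 49 spatial capsules of 256 dimensions (the
   reference grouping); a multi-type grouping (e.g. 32 capsule types of 8
   dimensions per position) is available through
   `primary_capsule_dim`. No ReLU is applied between this convolution and
   the squash. Each capsule vector is squashed:

       v = (‖s‖² / (1 + ‖s‖²)) · s / ‖s‖

   so norms live in [0, 1), short vectors shrink quadratically and long
   ones saturate.
3. **Emotion capsules with dynamic routing** — every primary capsule i
   predicts every class capsule j through its own transformation matrix,
   `û_j|i = W_ij u_i` (no weight sharing; 256 × 32 per pair in the
   reference model). Routing logits start at 0; for each of 3 iterations
   the coupling coefficients are the softmax of the logits over j (hence
   `Σ_j c_ij = 1`, uniform on the first pass), the class input is
   `s_j = Σ_i c_ij û_j|i`, the output is `v_j = squash(s_j)`, and the
   logits are incremented by the agreement `û_j|i · v_j`. The class score
   is `‖v_j‖`; prediction is the argmax (first index on exact ties).
4. **Margin loss** — per class e,

       L_e = T_e max(0, m⁺ − ‖v_e‖)² + λ (1 − T_e) max(0, ‖v_e‖ − m⁻)²

   with m⁺ = 0.9, m⁻ = 0.1, λ = 0.5, summed over classes and averaged over
   the batch.
5. **Reconstruction decoder** — the winning class capsule (the true class
   during training, the predicted one at inference) feeds a 512 → 1024 →
   324 fully connected decoder (ReLU, ReLU, sigmoid) that reconstructs the
   row-major flattened input; the total loss adds 5 × 10⁻⁴ × the
   reconstruction sum of squares (per batch mean). The small weight keeps
   reconstruction a regularizer rather than an objective.

**Training and gradients.** The implementation is pure R: convolutions are
im2col gathers followed by BLAS matrix products, and all gradients are
hand-derived. During backpropagation the coupling coefficients are treated
as constants of the final routing iteration — the gradient path through the
iterative c-updates is deliberately dropped, following the convention of
the original routing implementation. With `routing_iterations = 1` this
treatment is exact, which is how the finite-difference gradient test is
run; probes whose ±h perturbation flips a ReLU activation mask are skipped
there, because the central difference itself is invalid at a kink.
Optimization is Adam (learning rate 10⁻³, β = 0.9/0.999, no schedule),
batch size 40, with per-epoch reshuffling from the model's seed stream.
Transformation matrices are initialized from a truncated normal (sd 0.05,
clipped at ±2 sd); conv kernels and decoder layers use He-scaled normals.
All randomness (init, shuffling, splits, synthesis) is seed-controlled, so
identical seed + config + data reproduce identical results.

**Presets.** `capsnet_preset()` exposes the explored model grid: five
width variants (32–512 channels, 2 × 16 outputs) and six structure
variants A–F (kernel 3/5/9, widths 128/256, single or multi-type primary
grouping, 2 × 16 or 2 × 32 outputs). Model A — the configuration above —
is the reference.

# Evaluation protocol

`run_cv()` supports 10-fold cross-validation (default) and a stratified
8:1:1 train/validation/test hold-out. The k-fold split is a seeded
permutation dealt into near-equal unstratified folds, and pooled samples
are split at the *segment* level, so segments of one trial can appear in
both training and test folds. That pooled protocol is the package default
because it is the conventional one for this representation; it flatters
accuracy relative to a subject- or trial-disjoint split. A trial-grouped
mode (`group_by_trial = TRUE`) that keeps each trial's 20 segments in one
fold is provided as the leakage-safe alternative. Each fold trains a
freshly initialized model from a fold-derived seed; a fold whose training
data contains a single class is skipped with a warning and recorded as NA.
The protocol-scale defaults (k = 10, 400 epochs, batch 40, 3 routing
iterations) reflect the intended full-scale use; the tests and examples use
deliberately reduced schedules.

# The synthetic generator

`synth_config()` / `generate_recording()` emulate the recording layout so
the full pipeline is exercisable without any external dataset. The study
conditions fixed by the defaults:

* background: AR(1)-colored Gaussian noise (φ = 0.6, stationary sd 1 µV),
  independent per channel and trial;
* one latent binary class per trial, balanced Bernoulli, driving all three
  target dimensions; ratings are drawn uniformly from [6, 9] (high class)
  or [1, 4] (low class), so binarization at 5 recovers the latent class
  exactly and never lands on the threshold;
* class signal: a coherent narrowband alpha carrier (white noise
  brick-wall-filtered to 8–15 Hz, unit sd) added to eight posterior
  channels (O1, Oz, O2, PO3, PO4, P3, Pz, P4) at amplitude 1 µV for the
  low class and 3 µV for the high class — a strong, spatially and
  spectrally localized effect, chosen so that the classes are linearly
  separable from the feature table (the recoverability the learnability
  tests rely on);
* the 3-s baseline contains background noise only; carriers start after it;
* a pure-tone mode (`band_effect(type = "tone")`) exists for
  spectral-placement unit tests.

What the generator does *not* emulate: true 1/f spectral slopes, artifacts
(blinks, EMG), volume-conduction correlation structure, non-stationarity,
or inter-subject variability beyond independent noise seeds. Passing tests
therefore demonstrate that the pipeline recovers class-dependent band-power
structure it was designed to represent — not that any particular accuracy
is attainable on real recordings.

# Problem sizes in tests and the acceptance script

The package's own checks run at reduced scale by choice: structural count
checks use one full-size synthetic subject and one 32-subject cohort
(25,600 MFMs); the learnability check uses 2 subjects (1,600 MFMs), a
narrow network (16 conv filters, 49 × 32-d primary capsules, 2 × 8-d
emotion capsules, 64/128 decoder) and 2-fold cross-validation with 8
epochs, which reaches mean accuracy ≥ 0.95 on the default effect size; a
label-permuted rerun with 4 epochs stays within ±0.05 of chance. These
sizes are stated here so that results are interpreted at the scale they
were computed.

# Known limitations

* The capsule network runs on CPU in R; the full 25,600-sample, 400-epoch
  protocol is possible but slow — the package's value at that scale is the
  pipeline and reference semantics, not raw training throughput.
* Normalization's default full-dataset extrema leak ranks across folds
  (use `extrema_rows` for hygiene), and the default segment-level split
  leaks trial context (use `group_by_trial = TRUE`).
* The montage's exact cell assignment is a documented package convention;
  alternative topographies can be supplied but are not validated against
  any external standard beyond the symmetry invariants.
* The DEAP-layout reader consumes the documented `data`/`labels` structure
  serialized as RDS; it does not parse the original pickle files.
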
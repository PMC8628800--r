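---
title: "Image-based sleep staging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based sleep staging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sleepstager)
```

## The problem and the approach

Rodent sleep is scored per fixed epoch (20 s for mice) into wake, NREM and
REM from two biosignals: cortical EEG and nuchal EMG. The stage signatures
are classical — NREM shows dominant delta-band (1–4 Hz) EEG power with low
muscle tone, REM shows dominant theta-band (6–9 Hz) power with muscle
atonia, and wake shows mixed fast EEG with high EMG. The approach
implemented here turns scoring into an image-classification problem: every
epoch is rendered as one square grayscale image whose top half is the raw
EMG trace on a fixed vertical axis and whose bottom half is a brightness
heatmap of the 1–20 Hz EEG power spectrum in 1-s bins, min–max normalized
per image. A VGG-style convolutional network classifies the images; a
Wasserstein GAN with gradient penalty (WGAN-GP) synthesizes extra minority
class (REM) images to counter the natural ~10:10:1 wake:NREM:REM epoch
imbalance; a rule-based smoother removes an identifiable error mode
(isolated REM predictions inside continuous wake); and scoring reports
accuracy, per-class precision/recall/F1, macro F1 and Cohen's kappa,
averaged per animal.

Because licensed rodent recordings cannot ship with a package, sleepstager
includes a first-class synthetic generator that produces hypnograms and
stage-conditioned EEG/EMG with exactly the statistical structure the
classifier relies on. Every result the package's tests and acceptance
script report is computed on this synthetic substrate.

## The synthetic generator

`simulate_hypnogram()` draws stages from a first-order Markov chain. The
default transition matrix (rows WAKE, NREM, REM)

```
0.950  0.050  0.00
0.015  0.945  0.04
0.350  0.050  0.60
```

was solved so that its stationary distribution is exactly 10:10:1 and its
mean REM bout is 1/(1 − 0.60) = 2.5 epochs (≈ 50 s), with `P(WAKE→REM) = 0`
because REM is entered only through NREM. The literature gives bout
durations only loosely ("several minutes" of polyphasic sleep), so the bout
scale is a modeling choice, fixed once: self-transitions of 0.95/0.945 give
wake and NREM bouts of ~20 and ~18 epochs. The stationary ratio was
verified by eigen-decomposition before the REM-fraction interval
(`[0.02, 0.10]`) used in the tests was frozen.

`synthesize_signals()` builds each epoch's EEG as three sinusoid combs —
delta {1,2,3,4} Hz, theta {6,7,8,9} Hz, broadband {11,13,15,17,19} Hz —
with per-epoch random phases and ±0.15 Hz frequency jitter, scaled by the
stage's band weights, plus 1/f background noise; the EMG is white Gaussian
noise at the stage's RMS amplitude (30/8/4 µV for wake/NREM/REM — the
atonia ordering is validated, not assumed). A comb of sinusoids rather than
filtered noise was chosen deliberately: band powers then have closed-form
expectations, so an independent direct-DFT oracle can verify the
preprocessing exactly. The default sampling rate of 128 Hz with 20-s epochs
makes every 1-s FFT bin land on integer frequencies.

Seeding is counter-based: epoch *i* of a record uses a sub-seed derived
from (user seed, *i*), so any prefix of a record is bit-reproducible
independently of what follows.

What this generator does *not* emulate: movement and electrode artifacts,
drifting electrode impedance, stage-transition ambiguity, inter-animal
spectral variation beyond the seeded phase/jitter randomness, and
arbitrarily non-Markov bout-length distributions. Tests that pass on this
substrate therefore demonstrate that the pipeline's machinery is correct
and that the classifier can recover stages whose spectral/EMG signatures
are present; they do not certify performance on noisy laboratory
recordings.

## Preprocessing and rendering

`compute_power_spectrum()` uses rectangular-windowed, non-overlapping 1-s
segments and takes squared DFT magnitudes at 1..20 Hz. The window function,
overlap and power scaling are not forced by the method description, so the
simplest choices were made and logged: rectangular windows make integer-Hz
tones exactly recoverable (leakage-free), which in turn lets the oracle
tests demand 1e-9 relative agreement. Normalization is per-image min–max
over the whole 20×T matrix (each heatmap is self-contained); an optional
`log_power` flag applies `log1p` before scaling but is off by default.
Constant matrices normalize to all zeros — the degenerate-case convention.

`render_epoch_image()` is a pure rasterizer, no plotting toolkit: both
panels are exact box-area integrals of a resolution-independent continuous
field. The EMG panel rasterizes the segment-envelope of the clipped trace
(fixed axis ±`emg_range`, default 6× the record's global EMG standard
deviation — the fixed-axis requirement with a dataset-global constant) with
a minimum stroke thickness of 1% of the panel height; the heatmap panel
area-maps spectrogram cells, lowest frequency at the bottom. Because both
resolutions sample the same continuous field, rendering at the 800-px
native size and box-downscaling to the 180-px training size agrees with
direct 180-px rendering to < 0.05 mean absolute pixel error (tested at
0.01). Axis ticks and colorbars are constant decorations across images and
are omitted entirely. Images are single-channel in [0,1].

Window modes: 1-epoch images span their own epoch; 2-epoch images span the
preceding plus current epoch and take the *latter* epoch's label, with the
record's first epoch dropped rather than zero-padded (one epoch per record,
simplest consistent convention). `window_s_override` trims a window to its
most recent seconds, giving the 40→35→30→25→20 s shortened-window ladder.

## The classifier

`build_classifier()` assembles five blocks of [3×3 conv, 3×3 conv, 2×2 max
pool] followed by flatten → dense 128 → dropout → dense 96 → dense 64 →
dropout → dense softmax. The head is stated as "four dense layers and two
dropout layers" with first width 128 and last hidden width 64; counting the
softmax output as the fourth dense layer reconciles both statements, and
the middle width of 96 is a free choice. Filter counts are not published;
the default ladder 16/32/64/128/128 at 180 px input is a scaled-down VGG,
and the test profile halves it (8/16/32/64/64 at 64 px). Odd feature-map
sizes floor at pooling ("valid" semantics), so 180 px maps to a 5×5 final
grid. Training minimizes cross-entropy with Adam (lr 1e-4, batch 32),
stops when validation loss fails to improve for `patience` epochs, and
restores the best-validation weights. Activations of the first (128) and
last (64) hidden dense layers are exposed for embedding analyses; the
embedding itself (UMAP etc.) is out of scope.

The network framework underneath (im2col convolutions over BLAS, pooling,
dropout, Adam, reverse-mode gradients for both weights and inputs) is part
of this package and is verified by finite-difference gradient checks in the
test suite. One numerical caveat found during testing: with zero-initialized
biases, dead-ReLU regions produce pre-activations exactly at the leaky-ReLU
kink, where a central finite difference straddles two subgradients — the
gradient checks therefore nudge biases off zero; the analytic gradients are
valid subgradients everywhere.

## The WGAN-GP augmentor

`build_wgan_gp()` builds a generator that projects a 100-dim latent vector
to a 4×4 seed map and doubles resolution per upsample-conv block —
`log2(resolution/4)` blocks, so five blocks give 128×128 and two more reach
the 512×512 ceiling — ending in a sigmoid so outputs live in [0,1]. The
critic mirrors it (conv + leaky ReLU + average pooling) and ends in one
linear unit: a Wasserstein critic scores, it does not classify. The critic
loss is `mean(critic(fake)) − mean(critic(real))` plus the gradient penalty
`λ·mean((‖∇_x̂ critic(x̂)‖₂ − 1)²)` at uniform interpolates x̂; λ = 10 and
`n_critic` = 5 are the community-standard values. One generator is trained
per stage; there is no conditional GAN and no fake-image rejection filter
(generated REM is known to be diverse — callers should keep fakes out of
evaluation sets, which `train_classifier()` enforces).

Two numerical choices matter here. First, the penalty's gradient with
respect to the critic weights needs ∂²c/∂x∂w; instead of hand-deriving
double backpropagation through every layer, the package uses the
central-difference Hessian-vector-product identity — with g = ∇_x c(x̂)
held constant, ∇_w (vᵀg) ≈ [∇_w c(x̂+εv) − ∇_w c(x̂−εv)]/2ε — costing two
ordinary backward passes, with ε scaled to the perturbation norm. The
penalty *value* is exact (closed-form tests to 1e-12); only its weight
gradient is approximated, and the training tests confirm the critic's
gradient norms are in fact driven toward 1. Second, learning rates: the
canonical WGAN-GP recipe (1e-4, many thousands of steps) does not move the
generator measurably inside a few-hundred-step desk-scale budget, so both
Adam rates (betas 0/0.9) default to 5e-4, at which smoke-trained fakes
reproduce the row-brightness profile of real REM images with correlation
above 0.95 within ~300 steps at 32–64 px. The 512-px configuration is
supported but not exercised by the tests.

## Post-filter and metrics

`smooth_rem_in_wake()` relabels every maximal REM run of length ≤
`max_bout` whose immediate left and right neighbours are both WAKE (resting
wake EEG can resemble REM). Default `max_bout = 1` epoch — the most
conservative reading of "short" — and runs at the sequence boundary are
left alone (no flank to certify the context). The implementation is a
single pass over run-length encoding; an exhaustive test compares it with a
brute-force specification on all 3⁸ hypnograms of length 8 for
`max_bout` ∈ {1,2,3}. The filter only removes wake-flanked REM; on poor
predictions, or where such bouts are real, it removes genuine REM — it is
a precision tool for already-accurate scorers, not a general smoother.

Scoring: accuracy = trace/N; per-class precision/recall with F1 = 0 when
both are 0 (REM can be absent from short stretches and scores must still
aggregate); Cohen's κ = (p_o − p_e)/(1 − p_e), with κ ≡ 1 for perfect
agreement when p_e = 1 (both raters constant) and 0 otherwise. The
reporting unit is the animal: `aggregate_reports()` takes unweighted means
of each scalar metric across subjects, which is generally *not* the score
of the pooled confusion matrix — both are returned, clearly labeled.

## Desk-scale problem sizes

All tests and the acceptance script run on one CPU with fixed problem
sizes, chosen once as the package's desk-scale profile: the end-to-end
recovery experiment uses 2000 epochs over six synthetic animals (four
train, two held out) at 64×64 px with the halved filter ladder and at most
a handful of training epochs (validation accuracy saturates after the
first); the augmentation comparison uses one training animal and two
held-out animals (~250 epochs each, so roughly a dozen real REM images —
the tiny-dataset regime where augmentation matters), a 200-step REM
generator at 64 px, and three classifier seeds per condition. On this
substrate the classifier reaches per-animal mean accuracy and κ near 1.0,
the unaugmented one-animal baseline often fails REM entirely (recall 0 at
~1/21 prevalence), and both GAN equalization and tenfold duplication
restore REM recall — the GAN at least matching duplication. These numbers
characterize the synthetic substrate, not any laboratory dataset.

## Known limitations

- No artifact or noise robustness: the generator is clean by design and no
  denoising is implemented.
- The Markov hypnogram has geometric bout lengths; real bout distributions
  are heavier-tailed.
- The GAN weight-gradient of the penalty is a finite-difference
  approximation (exact value, approximate gradient).
- EDF support covers plain continuous 16-bit EDF, not EDF+ annotations or
  discontinuous records.
- Scores on synthetic data saturate near 1.0; the substrate separates
  stages by construction and says nothing about inter-scorer ambiguity.
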
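---
title: "Methods: semi-supervised video-based SpO2 estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-supervised video-based SpO2 estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spo2cam)
```

## The problem

Peripheral oxygen saturation (SpO2) can be estimated without contact from
ordinary RGB video because oxygenated and deoxygenated hemoglobin absorb red
and blue light differently: the cardiac pulse modulates skin color by a
fraction of a percent, and the *ratio of the pulsatile (AC) to the static
(DC) component* in the red channel, relative to the same ratio in the blue
channel, tracks SpO2. The classical calibration is linear,

$$\mathrm{SpO2} = A - B \cdot R, \qquad
  R = \frac{\mathrm{AC}_R/\mathrm{DC}_R}{\mathrm{AC}_B/\mathrm{DC}_B},$$

with device-specific constants $A$, $B$. The signal is fragile: it is
orders of magnitude smaller than illumination drift, motion, and sensor
noise, and labeled clinical recordings are scarce. This package implements a
semi-supervised pipeline that (1) learns to extract multi-channel remote
photoplethysmography (rPPG) signals from face and hand video with a 3-D
convolutional network pre-trained by *contrastive losses on power spectral
densities* (no labels needed), (2) fine-tunes the extractor against
reference photoplethysmograms with a cosine-similarity loss, and (3)
regresses per-window SpO2 through a CNN-BiLSTM head fused with a manual
feature attention module under the structural constraint
$k_1 + k_2 = 100$.

## The rPPG estimator

The backbone maps a `(3, T, S, S)` video block to a `6 x T` time series:
per-clip standardization, a `1x5x5` convolution (32 channels at reference
width), spatial average pooling, three stacks of two `3x3x3` convolutions
with temporal dilation 2 (64 channels) separated by average poolings — the
second of which halves the temporal axis — temporal linear interpolation
back to `T`, a further `3x3x3` convolution, global spatial average pooling,
and a final `3x3x3` convolution onto 6 output channels. Each non-output
convolution is followed by channel normalization and a ReLU.

Three realization choices deserve note:

* **Channel continuity through pooling.** Average pooling cannot change the
  channel count, so the 64 channels entering the second pooling are
  preserved through it; the channel widths are fixed by the convolution
  stages alone.
* **Normalization.** "Batch" normalization is realized as per-clip,
  per-channel normalization (instance-norm style), because the CPU training
  loop processes one clip at a time. It is deterministic and needs no
  running statistics, which keeps checkpoints self-contained.
* **Resolution adaptivity.** All pooling after the first stage adapts to
  the input extent and the last spatial pooling is global, so a single set
  of weights serves the nominal 128 x 128 input, CPU-friendly reduced
  resolutions, and the quadrant sub-ROIs (half resolution) used by the
  contrastive losses. A width multiplier scales all channel counts for desk
  use; the full-width network is the reference configuration.

The temporal pooling/interpolation round trip requires an even `T`; the
interpolation uses half-sample-centered linear weights along time only.

## Contrastive pre-training (stage 1)

Short skin-video segments from *different body regions of the same person
at the same time* share a pulse rate, hence nearly identical band-limited
power spectra, while their phases and amplitudes differ. The PSD is
therefore the natural invariant feature: spectra are Hann-windowed
periodograms restricted to the cardiac band 0.5–4 Hz and L1-normalized,
which removes phase entirely and amplitude up to scale.

Each training tuple holds four half-window clips: `x_a` (face, first half,
stationary), `x_b` (hand, first half), `x_d` (face, second half, where any
rotation perturbation lives), and `x_c`, a *pseudo clip* built by
replicating one chromatically augmented frame of `x_a` — it carries the
scene's spatial and chromatic structure but no pulse. The positive loss
pulls together all ordered pairs of quadrant-region spectra (four face,
four hand, across the batch, divided by $16N^2$) plus the whole-clip terms
$\lVert f_a - f_b\rVert^2 + \lVert f_a - f_d\rVert^2$; the negative loss
pushes $f_a$ away from every $f_c$ in the batch,
$-\sum_{n_1,n_2}\lVert f_a^{(n_1)} - f_c^{(n_2)}\rVert^2 / N^2$, bounded
below by $-4$ for normalized spectra. The whole-clip terms carry no
pairwise batch sum of their own and are averaged over the batch.

Because the loss needs gradients through the spectrum, the loss-side PSD is
computed with explicit cosine/sine DFT bases (zero-padded to 128 points so
1-second half-windows get a usable frequency grid); the user-facing
`compute_psd()` defaults to no padding. Region spectra are the
channel-mean of the six per-channel normalized output spectra, computed by
running the shared-weight estimator on each quadrant clip.

Stages are optimized with Adam (reference learning rates 0.001 for stage 1,
0.0001 for stage 2, 0.005 for stage 3 with 300/200/50 epochs at full
scale). All shuffling, initialization and augmentation is seeded, so loss
histories are bit-reproducible.

## Supervised fine-tuning (stage 2)

With a small labeled set, the estimator is fine-tuned by cosine similarity
between the channel-mean output of each half-window and the aligned
reference PPG halves: $L_s = 2 - \mathrm{sim}(y_a, \tilde y_1) -
\mathrm{sim}(y_d, \tilde y_2)$, which is 0 for perfectly matching (up to
positive scale) predictions and 4 for negated ones. The channel-mean
reduction is the symmetric choice given a single-channel reference.

## SpO2 head and fusion (stage 3)

The deep branch feeds, per analysis window, the globally standardized
`6 x T` rPPG output — standardized with a *single* mean and scale so that
relative channel amplitudes survive — stacked with the window's per-channel
AC/DC modulation traces (`clip_acdc_features()`: each channel's
spatial-mean trace as percent modulation around its mean). These traces are
the classical pulse-oximetry observable; feeding them alongside the learned
channels is the package's realization of passing clip-level features into
the deep head, and matters because the per-channel normalizations inside
the backbone deliberately discard absolute amplitude, which is exactly
where the red/blue ratio information lives. The stack passes through two
1-D convolutions (kernel 5), a bidirectional LSTM, and a sigmoid readout of
the concatenated final hidden states, giving $M_1 \in [0, 1]$ on the
fractional SpO2 scale.

The manual branch computes the six handcrafted statistics (per-channel
pixel means and variances over the window — variances, not standard
deviations),
attention-weights them with `softmax(relu(W c + b))`, and sums. Summing
the softmax outputs themselves would be identically 1 and carry no
information; the attention-weighted *feature* sum is the form consistent
with the module's role as a feature extractor. Because raw pixel
statistics live well below the fractional SpO2 scale (means around
0.3–0.6), the attention sum passes
through a learned scalar affine calibration to produce $M_2$; without it
the fusion is structurally unable to reach the upper physiological range
unless $k_1 \to 100$, which empirically drives the sigmoid readout into
terminal saturation and kills head training.

Fusion is $y = k_1 M_1 + k_2 M_2$ with $k_1 = 100\,\sigma(\theta)$,
$k_2 = 100 - k_1$: a single free parameter, so $k_1 + k_2 = 100$ holds
*exactly* after every optimizer step, and $\theta = 0$ gives the 50/50
initialization. Both branch readouts are initialized at the physiological
midpoint (logit of 0.96): early in training an off-scale output mean
otherwise produces a transient in which the sigmoid saturates irrecoverably.
Training minimizes MSE on the percent scale with the backbone frozen; only
head, attention and fusion parameters move.

## The synthetic-data generator

The generator renders the study conditions end to end: a textured static
background, an elliptical face patch (a rounded rectangle for the hand)
whose pixels follow
$\mathrm{DC}_c (1 + r_c(t)\, p(t))\, L(t) + \varepsilon$, with $p$ a
cardiac pulse (fundamental plus a 30% second harmonic), $L$ a 0.1 Hz
multiplicative lighting drift, $\varepsilon$ i.i.d. Gaussian sensor noise,
and in-plane rotation of the face patch at 0.2 Hz when enabled. The
AC/DC ratios encode ground truth through the linear ratio-of-ratios law
with documented constants $A = 110$, $B = 13$, chosen so the collection
range 93–100% maps to red/blue ratio values around unity
($r_B = 0.01$ fixed, green strongest at $r_G = 0.02$, hand pulsatility
scaled by 0.8). `invert_ratio_of_ratios()` closes the loop: on clean
scenes it recovers the configured trace to well under 0.5% MAE, verifying
that the videos really encode SpO2 rather than merely labeling it.

What the generator does *not* emulate: photorealistic skin texture or
melanin variation, specular highlights, out-of-plane pose, camera
compression artifacts, and physiological pulse-shape variability beyond the
fixed harmonic. Tests passing on this generator therefore demonstrate that
the pipeline's machinery is correct and that it can recover a
ratio-encoded saturation signal under drift, rotation and noise — not that
it is clinically calibrated.

## Desk-scale study conditions

All training-dependent checks run a documented desk profile chosen once for
single-CPU reproducibility: 6 subjects of 60 s at 30 fps, 64 x 64 rendered
frames, ROI resolution 16 x 16 (quadrants 8 x 8), backbone width multiplier
0.25, 60-frame analysis windows, stage epochs 8/8/120, and desk learning
rates 0.001 / 5e-4 / 0.02 (the stage-3 rate is raised from the full-scale
0.005 because a short schedule must traverse the percent output scale;
stage 2 similarly). Heart rates are spread across subjects (62–86 bpm) and
each subject carries a breath-hold-style desaturation dip of distinct
depth and timing. The contrastive-learning recovery check uses 8 subjects
and the 20+20 epoch schedule on 8-s recordings. Leave-one-subject-out folds
are a pure function of the subject list and the seed.

The ablation baseline follows the frozen-backbone end-to-end protocol for
all variants: the backbone is frozen during stage 3 everywhere, and the
baseline variant simply skips the two pre-training stages (random frozen
backbone) with a generic unidirectional LSTM head on the 6 signal channels
alone — the AC/DC trace input and the convolution stack belong to the
proposed head design, and the attention fusion to the MFAM variant, so each
ablation removes exactly one contribution.

## Numerical choices and degenerate inputs

* The band-pass filter is a windowed-sinc FIR applied forward-backward
  (zero phase), order `4 * rate / low_hz` rounded odd, with design cut-offs
  widened by half a transition band so the nominal band edges sit in the
  flat response region; the first and last second of output are edge
  transients. Reflection padding tames the transient amplitude.
* Normalized PSDs get an additive `1e-12` floor so that spectra of
  constant signals (the pseudo clips) are well-defined (uniform) and the
  loss gradients stay finite.
* Resampling is linear interpolation on the time grid; rates equal means
  samples are returned unchanged.
* Bilinear crop-resize uses half-pixel-centered sampling, which makes a
  same-size resize the exact identity and keeps outputs inside `[0, 1]`.
* Estimator inputs must be square, even-sized (at least 8 px) and have even
  `T`; violations raise typed errors (`spo2cam_error_shape`,
  `spo2cam_error_invalid_parameter`, ...), and constant inputs to
  normalization or similarity raise `spo2cam_error_degenerate_signal`.
* Predictions are clipped to `[0, 100]` percent.

## Known limitations

The desk-scale network is narrow and trained for minutes, so absolute
desk-scale error numbers are not comparable to full-scale training on real
recordings. The manual-feature branch saturates quickly on synthetic scenes
(its statistics barely vary within a subject), so the learned fusion weight
typically settles heavily on the deep branch. Ratio-of-ratios calibration
constants are generator-true by construction; on real cameras $A$ and $B$
must be fitted per device. Finally, the skin detector is a color-threshold
heuristic intended for synthetic scenes and controlled recordings, not a
face detector replacement; any learned detector can be plugged in as a
function.
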
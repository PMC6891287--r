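---
title: "Decoding grasp-and-lift EEG with CSP spatial filters and Morse wavelet scalograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding grasp-and-lift EEG with CSP spatial filters and Morse wavelet scalograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cspcwt)
```

## The decoding problem

A grasp-and-lift trial contains six motor events in fixed sequential order —
handstart (HS), grasp (GS), lift (LT), hold (HD), replace (RP) and release
(RL) — recorded as multichannel EEG at 500 Hz with per-sample binary event
annotations. The decoding question is whether each short window of EEG can be
attributed to its event. The electrodes that matter most are the motor-cortex
row C3, Cz, C4 and the parietal row P3, Pz, P4 (10/20 system), because the
discriminative activity lives in the sensorimotor mu rhythm (8–13 Hz) and
beta band (13–30 Hz).

The package implements the full chain: band-pass filtering, one-vs-rest
common spatial pattern (CSP) filtering, Morse-wavelet scalogram imaging, a
pluggable image classifier with a small self-contained reference CNN, and
ROC-based evaluation — plus a synthetic EEG generator, so the entire chain is
exercisable and testable without any recorded dataset.

## Band-pass filtering

The raw signal is filtered to 7–30 Hz with a linear-phase equiripple FIR
filter: passband 7–30 Hz with at most ±0.5 dB ripple, stopbands below 5 Hz
and above 33 Hz with at least 65 dB attenuation. This band excludes the
dominant artifact sources — eye blink (below 4 Hz), heartbeat (about 1.2 Hz),
mains hum (60 Hz) and muscle activity (above 30 Hz) — which is why no
separate artifact-removal stage is needed.

Design choices worth stating:

* The filter order comes from the standard Herrmann/Kaiser equiripple order
  estimate for the template, rounded up to even (547 taps at 500 Hz); the
  realized magnitude response is then *measured* at 64 probe frequencies per
  band and the order grown until the template is met, so the contract is on
  the measured response, not the estimate.
* Group delay is compensated by shifting the causal output left by
  `(L-1)/2` samples and zero-padding the tail. Forward–backward filtering is
  deliberately avoided: it would square the magnitude response, doubling the
  stopband attenuation and deviating from the stated 65 dB design.
* Z-score normalization (per channel, whole recording) happens after
  filtering, matching the filter-then-normalize stage order of the method.

## CSP: joint diagonalization of two class covariances

For a window $X \in \mathbb{R}^{N\times T}$ the trace-normalized spatial
covariance is $R = XX^\top/\mathrm{tr}(XX^\top)$; per-class averages
$\bar R_1,\bar R_2$ are formed over windows. The composite
$R_c = \bar R_1 + \bar R_2 = U\Delta U^\top$ is whitened by
$P_w = \Delta^{-1/2}U^\top$, making $Q_i = P_w \bar R_i P_w^\top$ share
common eigenvectors $V$ with paired eigenvalues satisfying
$\Delta_1 + \Delta_2 = I$. The spatial filter is $W = V^\top P_w$, rows
ordered by descending $\Delta_1$: the first row maximizes event-class
variance relative to the composite, the last minimizes it. Projection
$Z = WX$ is inverted by $X = W^{-1}Z$, and the columns of $W^{-1}$ are the
spatial patterns. `csp_fit()` returns this decomposition as a classed model
object with `print`, `summary`, `coef`, `predict` and `plot` methods.

Numerical conventions, chosen once and frozen:

* Eigenvalue ties are broken by original index (stable sort); eigenvector
  signs are fixed by making each column's largest-magnitude entry positive,
  so fits are bit-reproducible.
* Whitening aborts with a rank-deficiency error when an eigenvalue falls
  below $10^{-10}$ of the largest, unless shrinkage regularization
  $R \leftarrow (1-\lambda)R + \lambda\,\mathrm{tr}(R)/N \cdot I$ is enabled
  (`shrinkage`, default 0 — CSP's outlier sensitivity makes the hook worth
  having, but the reference configuration runs without it).
* All $N$ components are retained (no m-pair truncation): the downstream
  imaging stage needs six component rows to mirror the six-electrode
  grouping.

The multiclass extension is one-vs-rest: six binary fits, one per event,
each against a pooled rest class. The five non-target events admit
$5! = 120$ orderings and full pooling would let the rest covariance dominate,
so the rest pool is a balanced, seeded subsample: an equal number of windows
from each of the five other events, totalling about the event count.
Covariance averaging is over sliding windows as delivered by the epoching
stage; row $i$ of $Z$ is identified with electrode $i$ for naming and triad
assignment, and that identification is recorded in the image manifest.

## Morse wavelet scalograms

Each CSP component row of a 400-sample window is transformed with a bank of
analytic generalized Morse wavelets,
$\Psi(\omega) \propto \omega^\beta e^{-\omega^\gamma}$ for $\omega > 0$,
with symmetry $\gamma = 3$ and time-bandwidth product $P^2 = 60$
($\beta = P^2/\gamma = 20$), 10 voices per octave. The scalogram is the
magnitude of the transform coefficients, computed by frequency-domain
multiplication.

The scale bounds follow an energy-spread rule: the smallest scale puts the
wavelet's peak frequency $\omega_p = (\beta/\gamma)^{1/\gamma}$ at Nyquist
($s_{\min} = \omega_p/\pi$), and the largest scale limits the wavelet's time
support to the window, $s_{\max} = n/(k\,\sigma_t)$, where $\sigma_t$ is the
mother wavelet's time standard deviation (computed in closed form from
gamma-function moments; $\sigma_t = 2.9227$ for these parameters) and $k$ is
a cutoff constant. $k = 1.9803$ was calibrated once so that the default
configuration (400 samples at 500 Hz) yields exactly 69 scales — the 69×400
scalogram dimension of the reference configuration — and is frozen in the
package. The scale grid is anchored at $s_{\min}$, so lengthening the window
adds scales only at the low-frequency end.

Scalograms are quantized to 8-bit grayscale, resized to 224×224 with
separable bicubic (cubic-convolution, Keys $a=-0.5$) interpolation without
antialias prefiltering, and stacked into two RGB composites per window: the
motor triad (component rows 1–3 ↔ C3, Cz, C4) and the parietal triad (rows
4–6 ↔ P3, Pz, P4). Rounding is half-up; resize output is clipped to
[0, 255]. Both triads enter one training pool, tagged with their triad
identity in the manifest so a per-triad readout remains possible.

**Grayscale normalization.** `to_grayscale()` implements per-image min–max
mapping, but the dataset generator defaults to *dataset-level* (global)
normalization: all magnitudes are mapped against the common maximum of the
dataset. The reason is structural. CSP concentrates each class's variance
into known components, so the class information in the projected signal is
carried by *amplitude* differences between windows; per-image normalization
rescales every image to full range and erases exactly that information —
with near-perfect unmixing, an event window and a rest window produce
visually identical normalized images, and no classifier can separate them.
Global normalization preserves the cross-window amplitude ordering (at the
cost of sensitivity to a single extreme magnitude, which quantization
clipping bounds). The mode and reference value are recorded per image in the
manifest.

## The classification stage

The classifier stage is pluggable: anything exposing `train`/`predict` can
sit behind it (a fine-tuned large pre-trained network being the natural
choice when downloaded weights and GPU time are available). The bundled
reference backend is a deliberately small CNN trainable on one CPU in
minutes:

    avgpool(7) → conv(3×3, 16) + ReLU + maxpool(2)
               → conv(3×3, 32) + ReLU + maxpool(2)
               → global average pool → dense + softmax

The fixed initial 7×7 average-pooling layer reduces the 224×224×3 input to
32×32×3 before the first convolution. The on-disk data contract (224×224×3
RGB PNG) is unchanged; the pooling layer is an architectural choice of the
reference backend that trades spatial resolution it does not need (the
discriminative structure is a few broad spectral ridges) for a training cost
that keeps six one-vs-rest models within minutes on one core.

Training pools both triad images of every window into one binary problem
per contrast and follows the reference protocol: stratified 0.8:0.1:0.1
train/validation/test split, at most 30 epochs, mini-batch size 10. The
pipeline stratifies the split over *windows* (both triad views of a window
land in the same fold); splitting over images would let one view of a window
train while its sibling view is tested, which inflates test scores through
within-window correlation. The
optimizer is SGD with momentum 0.9 and learning rate 0.05; inputs are
standardized by the training set's scalar pixel mean and SD (stored with the
model for inference), because scalogram images are predominantly near-black
and an unstandardized input leaves the class signal buried in a constant
background at a scale where reasonable step sizes cannot move the loss.
Early stopping (patience 5, or perfect validation accuracy) returns the
parameters with the best validation accuracy; the full per-epoch history is
kept. A fixed seed controls the split, initialization and batch order, so
training is reproducible.

## Evaluation

The decoding unit of the pipeline's report is the *window*: the two triad
images of a test window are scored independently by the classifier and their
event scores averaged into one window score. The two views carry unequal
information — the motor triad holds the event-maximizing CSP components,
while the parietal triad holds the event-suppressed components whose
eigenvalues are nearly tied and therefore mix — and score fusion lets the
strong view dominate gracefully instead of averaging test metrics over
images of very different quality. Image-level readout remains available from
the per-image score files the pipeline writes.

Per contrast: precision $TP/(TP+FP)$, sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$, accuracy $(TP+TN)/\text{total}$ at the 0.5 score threshold,
and the ROC curve of the positive-class score with trapezoidal AUROC
(thresholds at unique score values; tied scores grouped at one threshold,
which makes the trapezoid equal to the Mann–Whitney statistic with ties
counted half). Metrics with zero
denominators are reported as `NA` — explicitly undefined, never silently 0,
because small test sets do hit those cases. The macro report averages the
six contrasts unweighted, over images (the per-contrast test-set size `n` is
recorded alongside).

## The synthetic generator

`generate_eeg()` emulates the structure the pipeline exploits, not the
biophysics of EEG. Six band-limited Gaussian sources (center frequencies
9–25 Hz, 4 Hz bandwidth, generated with 4th-order Butterworth bands —
deliberately a different filter family than the analysis FIR, so tests never
validate a filter against itself) are mixed by a fixed full-rank matrix;
each trial runs the six events in sequential order with block durations
drawn uniformly from 0.8–2.0 s; artifacts (blink pulses, 1.2 Hz heartbeat
waveform, 60 Hz line, band-limited muscle noise above 30 Hz) and white
sensor noise are added. All randomness flows through one explicit seed.

The standard scenarios rotate which source carries elevated variance: event
$k$ boosts source $k$ by 10:1 (strong) or 1.5:1 (weak) against unit-variance
others, under a seeded random orthogonal mixing. Through the CSP eigenvalue
relation this plants known spectra: the boosted source's generalized
eigenvalue is $10/11 \approx 0.91$ for the strong case and $1.5/2.5 = 0.6$
for the weak case, which is what the bracket tests (max $\Delta_1 \ge 0.8$
strong, $\le 0.65$ weak) check through the full preprocessing chain. The
planted discriminative direction — the unmixing row of the known mixing
matrix — is exposed for parameter-recovery tests. Artifact amplitudes
default to blink 40, heartbeat 5, line 10, muscle 3 µV against 10 µV sources
and 1 µV sensor noise: large enough that unfiltered decoding degrades,
small enough to be realistic.

What the generator does *not* emulate — nonstationarity across sessions,
volume-conduction correlations, event-related (de)synchronization dynamics,
non-Gaussian artifacts — bounds what passing tests show: they validate the
algorithmic chain (filters, decompositions, imaging, training, metrics), not
clinical decoding performance on recorded EEG.

## Problem sizes used by the test suite

The bundled checks run the chain at desk scale, chosen as the smallest sizes
at which each property is stably expressed: covariance-level oracles at
$N \le 6$ with hundreds of random pairs; scenario-level checks at 20 trials
(roughly 50 windows per event); and the end-to-end surrogate at 130 trials,
300 windows per class per contrast — 600 RGB scalograms per class — through
CSP, imaging, reference-CNN training and window-fused ROC evaluation, which
reaches macro test AUROC above 0.95 on the strong scenario. Per-contrast
values at that scale rest on about 60 test windows each, so they are noisier
than the macro mean.

## Known limitations

* The reference CNN is a sanity-scale stand-in for a large pre-trained
  image network; absolute accuracy on real recordings is out of its scope.
* One-vs-rest CSP with balanced subsampling discards part of the rest pool;
  filter-bank CSP, Riemannian variants and true multiclass joint
  diagonalization are deliberately out of scope.
* The CSV reader targets the two-file grasp-and-lift dialect only; no
  EDF/BDF, streaming, or re-referencing.
* Epochs are cut within one recording and never across file boundaries.
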
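---
title: "Classifying systemic sclerosis from three-phase multi-site PPG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying systemic sclerosis from three-phase multi-site PPG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Systemic sclerosis (SSc) is a rare connective-tissue disease whose vascular
involvement shows up early in the microcirculation of the extremities.
Photoplethysmography (PPG) measures heart-synchronous blood-volume changes
optically and cheaply, and a dynamic challenge — a supine baseline, five
minutes of arm-cuff occlusion at 300 mmHg, then release and a reactive
hyperaemia ("flush") phase — exposes vascular function that a resting trace
does not: healthy vessels overshoot strongly after release and recover
quickly, while sclerotic vascular beds show attenuated pulse amplitudes,
weak flush, slow recovery and marked inter-finger heterogeneity.

`ppgssc` implements an automated screening pipeline over such recordings:
six channels (both earlobes, index fingers and great toes) sampled
simultaneously, divided into 30-s windows, turned into time–frequency
percent-energy scalogram images, and classified by an image network, with
window-level predictions aggregated to a participant-level diagnosis by
majority vote. A classical comparator branch extracts 144 discrete-wavelet
features per participant and classifies with LDA and KNN. Both branches
share one participant-wise stratified 10-fold partition, and evaluation
reports accuracy, sensitivity and specificity with exact binomial 95%
confidence intervals. Because clinical recordings of this protocol are not
publicly available, the package ships a seeded synthetic cohort generator
so every stage is testable end to end.

## The synthetic cohort generator

The generator is a study-conditions emulator, not a haemodynamic model.
Each participant is a phenotype profile drawn from per-class distributions;
each channel is a quasi-periodic pulse train multiplied by a phase
envelope, plus band-limited noise, times the channel's amplifier gain.

**Pulse train.** One beat per cardiac cycle at the participant's heart rate
(drawn in 0.7–2 Hz, ~2% beat-interval jitter). The beat template is two
Gaussian bumps — a systolic peak and a smaller, wider dicrotic bump — made
zero-mean and unit-peak, so the signal is locally AC-coupled like a real
PPG front end. No waveform model is claimed for real pulses; the template
is smooth, morphologically PPG-like plumbing.

**Phase envelope.** Non-occluded channels keep a multiplier near 1
throughout (a slow sinusoidal drift bounded by `drift_amp`, default 2%).
The occluded channel (left finger — the only default site distal to a
left-arm cuff) decays exponentially to ~0 after cuff inflation (time
constant 5 s), jumps to `flush_overshoot` at release, and relaxes back to
1 with time constant `flush_tau`. Controls default to overshoot > 1 with
fast recovery (τ ≈ 15 s); SSc to overshoot ≤ 1 with slow recovery
(τ ≈ 60 s).

**Class phenotypes.** The `"literature"` preset encodes reported multi-site
PPG findings: Control pulse amplitude 56 ± 19 a.u. against SSc 24 ± 24 a.u.
(truncated at zero), homogeneous Control finger amplitudes (CV 5%) against
marked SSc heterogeneity (CV 35%). Two morphology parameters are the
generator's own design choice: SSc pulses are rendered damped and rounded
(wider systolic bump, weaker dicrotic wave). The rationale is structural:
the scalogram stage normalises energy per window, so absolute amplitude —
the most-reported class difference — cancels out of the images, and a
generator without any within-window morphological cue would make the image
branch unlearnable by construction rather than by method. Damped distal
pulse contours in SSc are consistent with the reduced-amplitude,
heterogeneous picture the literature reports, but they are an assumption,
not a reproduced measurement. Measurement noise is 2% of the participant's
baseline amplitude with an absolute instrument floor of 0.3 a.u., so
low-amplitude (SSc) recordings genuinely have lower SNR. Noise is low-pass
filtered at 20 Hz, emulating the 0.5–20 Hz analogue bandwidth of the
amplifiers.

The `"strong"` preset keeps the same class means but shrinks within-class
spread. It exists for pipeline sanity benchmarks: a cohort on which a
correct implementation *should* classify well, so a failure indicates a
defect. Passing it says nothing about performance on real, overlapping
clinical phenotypes — the literature preset overlaps substantially by
design (24 ± 24 vs 56 ± 19), and no claim is made that the synthetic
cohort reproduces the published clinical accuracies.

**What the generator does not emulate:** probe-contact artefacts, motion,
respiratory and autonomic low-frequency modulation, arrhythmias,
vasospastic attacks during measurement, and any physiological coupling
between sites beyond a shared heart rate.

## Windows, scalograms, images

Recordings are gain-normalised (each channel divided by its amplifier gain
setting — the only pre-processing; no digital filtering) and divided into
consecutive, non-overlapping 30-s windows per channel; a trailing partial
window is discarded so every image has identical time support. A full
20-min recording yields 40 windows per channel, 240 per participant.

Each window is transformed with an analytic continuous wavelet transform
using the generalized Morse wavelet (symmetry γ = 3, time-bandwidth
P² = 60 — the common analytic default; the source protocol does not state
these) at 12 voices per octave. Scales span 0.3 Hz to min(25, fs/2.1) Hz,
covering the 0.5–20 Hz PPG band; the wavelet is peak-normalised so tones of
equal amplitude register equally across frequency. Windows are
reflection-padded to the next power of two before the FFT to suppress
circular wrap-around at the low-frequency scales.

The scalogram is the squared coefficient magnitude normalised to a grand
total of 100 — each cell is the percentage of the window's energy at that
time and frequency. Identically zero windows (possible during occlusion if
noise were disabled) have no energy to distribute and are excluded with a
warning rather than propagating NaNs.

Images are rendered by cropping to 0–20 Hz, bicubic resizing (Keys kernel,
a = −0.5, antialiased when shrinking — the standard `imresize` behaviour)
to 224 × 224, per-image min–max scaling, and mapping through a fixed
256-level perceptually uniform colour map (viridis family; brighter =
more energy). Per-image min–max scaling matches default scalogram-plotting
behaviour and, together with the percent-energy normalisation, makes the
rendered image exactly invariant to positive scaling of the source signal.
The native logarithmic frequency spacing of the CWT is kept; rows are not
resampled to linear frequency.

## The image classifier

The reference pipeline fine-tunes large pretrained networks (GoogLeNet,
EfficientNetB0). The value being tested here is the pipeline, not the
pretrained weights, so the package's default backbone is `tiny_test_cnn`:
an 8 × 8 average-pooling front end honouring the 224 × 224 × 3 input
contract (pixel values rescaled to [−1, 1], which conditions the loss
surface well enough that the fixed 0.005 learning rate converges reliably
across fold seeds), then three 3 × 3 convolution blocks (8, 16, 32 filters; ReLU;
2 × 2 max-pool after the first two), global average pooling and a softmax
head — about 6,000 parameters, trained from scratch. Large pretrained
backbones can be registered as plug-ins via `register_backbone()`.

Training follows the reported regime where stated: stochastic gradient
descent at learning rate 0.005, cross-entropy loss, ten minibatches per
epoch (batch size ⌈n/10⌉). Momentum (0.9) and the epoch count (10) are not
reported in the source protocol and are surfaced in `train_config()`. No
augmentation is applied. Everything is driven by the configuration seed —
initialisation, shuffling — so runs are exactly reproducible; each CV fold
derives its own seed from the master seed.

## The comparator feature branch

Each gain-normalised channel of the *whole* recording (the feature branch
does not window) is decomposed by a ten-level db4 DWT. Boundary handling is
periodization, chosen because it makes the transform orthonormal:
coefficient counts halve exactly per level and Parseval's identity holds to
machine precision, which the tests assert at 1e−8 relative. Detail level j
occupies (fs/2^(j+1), fs/2^j) Hz; bands d6–d10 plus the final approximation
jointly cover the analogue passband at the clinical 2000 Hz rate, and band
edges are always computed from the actual sampling rate in use.

Four features per band — energy Σx², Shannon entropy of the normalised
squared-coefficient distribution (in bits; the printed entropy form is not
scale-coherent on raw coefficients, so the normalised convention is the
default with the unnormalised −Σx²log₂x² variant behind a flag), mean
absolute value (literal |mean(x)|, with the conventional mean(|x|) behind a
flag), and population skewness — give 6 channels × 6 bands × 4 = 144
features per participant, ordered channels → bands (d6…ap) → features.

LDA uses a pooled within-class covariance with diagonal loading
(ε = 1e−4 × mean diagonal variance): with 144 features and a few dozen
training participants the pooled covariance is singular and unregularised
LDA is undefined. KNN uses Euclidean distance with K = 9, equidistant
neighbours taken in stable training order and vote ties (impossible for
odd K in two classes, but defined anyway) broken by the nearest neighbour.
Both classifiers consume z-scored features — energies and skewnesses live
on wildly different scales and KNN is scale-sensitive — with
standardisation statistics estimated on the training folds only.

## Cross-validation and evaluation

Folds are participant-wise and stratified: within each class participants
are shuffled by seed and dealt round-robin, the dealing pointer continuing
across classes, which bounds both per-fold class counts and fold sizes to
differ by at most one. On a 20 SSc / 51 Control cohort with k = 10 every
fold holds exactly 2 SSc and 5–6 Controls. One serialised plan
(`folds.json`) is the explicit input to both branches, and every executor
asserts train/test participant disjointness at runtime — sharing data
*values* across participants is fine; sharing a *participant* is a hard
error.

The per-fold test predictions are pooled into combined confusion matrices
(SSc positive). Participant-level classification takes the majority class
over each test participant's image predictions; an exact tie goes to SSc,
the sensitivity-preserving direction, on the argument that missing a
life-threatening disease costs more than a false referral. Accuracy,
sensitivity and specificity are reported as percentages with Clopper–
Pearson exact binomial 95% intervals (beta-quantile inversion of the
binomial tails). The exact interval was identified from the published
tables: the printed interval for 15/20 (50.9–91.3) matches Clopper–Pearson
to the decimal and is wider than Wilson, as exactness requires. Printed
tables round half away from zero, so `round_half_up()` is used for all
table-facing rounding. The crosshair export transforms specificity to the
false positive rate (100 − specificity) with interval endpoints swapped,
for meta-analysis-style comparison plots.

## Problem sizes and numerical choices

The package's benchmark configuration (`synthetic_benchmark()`, also used
by the analysis scripts) is 35 participants (10 SSc / 25 Control) under a
desk-scale protocol: 200 Hz sampling, 300 s with the clinical 2:1:1 phase
structure (150 s baseline, 75 s occlusion, 75 s flush). These sizes were
chosen so a full two-branch 10-fold run completes in minutes on one CPU
while still exercising 2,100 images; the clinical 2000 Hz / 1200 s protocol
remains the documented default of `ppg_protocol()`. DWT band edges and CWT
scale grids always derive from the sampling rate actually in use.

Other numerical choices: signals are truncated to a multiple of 2^levels
samples before DWT (at most ~5 s of a 20-min record) so periodization stays
exact; degenerate zero-energy windows are excluded with a warning;
zero-variance coefficient sets define skewness as 0 with a warning;
constant images map to the bottom colour; the saturation check uses a
plateau tolerance of 1e−4 of the signal range over 10-s spans with a 2%
threshold, calibrated so a clean sinusoid passes while a trace clipped at
60% amplitude for 30 s fails.

## Known limitations

- The synthetic phenotype is a stand-in: passing benchmarks demonstrate
  pipeline correctness, not clinical performance. The published clinical
  accuracies (83%/87% participant-level) are not reproducible without the
  original cohort and pretrained-backbone training, and the package does
  not attempt them.
- The compact backbone is far smaller than the pretrained networks of the
  reference pipeline; its role is to make the training contract testable.
- Beat-to-beat amplitude extraction (the classical flush analysis) is
  deliberately out of scope; classification never consumes it.
- PRP (primary Raynaud's) is merged into the Control class throughout, as
  in the source protocol; no third class is modelled.
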
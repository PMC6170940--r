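---
title: "Methods: multi-feature seizure detection from multi-channel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-feature seizure detection from multi-channel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegseizer)
```

## The problem and the pipeline

Long-term scalp EEG review for epilepsy is slow and error-prone: a
neurologist scans hours of 19-channel traces looking for ictal discharges,
most commonly generalized ~3 Hz spike-and-slow-wave runs. `eegseizer`
implements an automated screening pipeline for this task:

1. **Preprocess** — 50 Hz notch, 0.5–40 Hz bandpass, ICA-based artifact
   rejection.
2. **Segment** — non-overlapping 0.5 s windows per channel (64 samples at
   128 Hz).
3. **Features** — per window: maximum Yule–Walker AR(4) power spectral
   density, histogram Shannon entropy, histogram Rényi entropy of order 2,
   and the averaged Teager energy.
4. **Validate** — per-class descriptive summaries and a two-sided Wilcoxon
   rank-sum test confirm the features separate the classes before any
   classifier sees them.
5. **Classify** — a single-hidden-layer perceptron (10 tanh units, sigmoid
   output) trained by scaled conjugate gradient under a stratified 70/30
   holdout.
6. **Score** — window decisions are fused across channels, merged into
   events, and reported as event sensitivity (S⁺), segment specificity
   (S⁻), false detections per hour (FDR) and ROC/AUC.

Because clinical recordings cannot be redistributed, the package carries a
seeded synthetic EEG generator that reproduces the statistical structure
the method relies on; every stage is tested against it.

## The four features

Let $x_1,\dots,x_N$ be one 0.5 s window ($N = 64$).

**Yule–Walker maximum PSD.** The biased autocorrelation
$r_k = \frac1N\sum_{n=1}^{N-k} x_n x_{n+k}$ ($k = 0,\dots,4$) defines the
Toeplitz normal equations of an AR(4) model, solved by Levinson–Durbin
(the biased estimator guarantees a positive semi-definite system). The
one-sided spectrum $\sigma^2 / (f_s\,|A(e^{i\omega})|^2)$ is evaluated on a
uniform 256-point grid over $[0, f_s/2]$ and the grid maximum is the
feature. AR spectra place poles close to the unit circle and resolve the
narrow-band power rise of ictal EEG well at this very short window length,
where nonparametric estimates are badly smeared. The reported maximum is
grid-resolution dependent by construction; 256 points (≈ 0.25 Hz at
128 Hz) is far below the AR(4) peak width. Zero-variance windows return 0
with a warning rather than propagating a singular system.

**Histogram entropies.** Bin probabilities $p_i$ come from a uniform-width
histogram over the window's own $[\min, \max]$ range. Shannon entropy is
$E = -\sum_i p_i \log_2 p_i$ (empty bins contribute zero) and the Rényi
entropy of order $\alpha$ is
$E = \frac{1}{1-\alpha}\log_2 \sum_i p_i^\alpha$, with $\alpha = 2$ as the
working order; $\alpha \to 1$ recovers Shannon, which the code enforces as
an explicit redirect rather than a numerically unstable limit. Defaults:
`n_bins = 16` for $N = 64$ — enough resolution to distinguish spiky from
Gaussian amplitude distributions while keeping expected bin counts ≈ 4, so
the histogram does not degenerate into singletons. The per-window range
makes both entropies exactly invariant to affine amplitude rescaling; a
global-range variant would confound entropy with amplitude, which the PSD
and Teager features already capture.

**Teager energy.** The discrete Teager operator
$\psi_n = x_n^2 - x_{n-1}x_{n+1}$ is summed over the interior samples and
normalised as $\mathrm{TE} = \frac{1}{N-1}\sum_{n=2}^{N-1}\psi_n$. For a
sinusoid $A\cos(\Omega n)$ each term equals $A^2\sin^2\Omega$, so the
operator responds jointly to amplitude and instantaneous frequency — both
elevated during seizures. The $1/(N-1)$ normalisation over $N-2$ terms is
kept verbatim from the formulation this package follows (a conventional
mean would use $N-2$); the ≈ 1.6 % scale difference is absorbed by the
classifier's feature scaling and is irrelevant to ranks and tests.

## Preprocessing choices

*Notch*: a second-order IIR biquad at 50 Hz. Only the order is prescribed
by the usual clinical description, so the width is this package's choice:
quality factor $Q = 35$ (−3 dB width ≈ 1.4 Hz), wide enough to absorb
small line-frequency drift and narrow enough to leave the 40 Hz band edge
untouched. Measured steady-state attenuation of a 50 Hz tone is ≈ 35 dB;
whole-record RMS of a *finite* tone shows less because spectral leakage at
the tone's onset/offset lies outside any narrow notch.

*Bandpass*: elliptic design, 3 dB passband ripple, 40 dB stopband
attenuation, corners 0.5 and 40 Hz. The band is realised as an order-5
elliptic highpass cascaded with an order-5 elliptic lowpass: a direct
10th-order bandpass polynomial with a lower edge at 0.008 of Nyquist is
numerically fragile in transfer-function form, while the cascade keeps
each polynomial at order 5 and meets the same tolerance scheme.

*Zero phase*: both filters run forward–backward by default (attenuations
double, passband ripple doubles in dB), because causal IIR phase would
shift spike timing and bias event onsets; the test suite demonstrates a
symmetric pulse stays symmetric. Edge transients are controlled by odd
reflection padding of 3× the measured impulse-response length.

*ICA artifact rejection*: the decomposition is a pluggable backend — any
function returning sources with exact mixing/unmixing maps. The default is
a deterministic symmetric fixed-point ICA (tanh contrast, PCA whitening,
rotation estimated on ≤ 20 000 columns, applied to the full record).
Rejection criteria are not prescribed anywhere authoritative, so the
default rule is this package's design: reject a component when its
absolute excess kurtosis exceeds 50 (sparse pops/spike artifacts; the
synthetic two-source artifact fixture measures ≈ 130) **or** when more
than half its power lies below 1 Hz (slow drifts). The kurtosis threshold
is deliberately high: generalized 3 Hz spike-wave activity itself forms a
moderately super-Gaussian component (occupancy ~10 % of a 20 min record),
and a low threshold would delete the very signal being detected. Motion
artifacts are instead caught by the low-frequency rule, by the 0.5 Hz
highpass, and downstream by the channel-consensus vote.

## Classifier

Features are affinely mapped to $[-1,1]$ per feature, with the scaler
fitted on training rows only (raw PSD maxima reach hundreds of µV²/Hz and
would saturate tanh units). The network is `4 → 10 tanh → 1 sigmoid`,
trained on mean squared error against 0/1 targets with Møller's scaled
conjugate gradient (σ = 5·10⁻⁵, initial λ = 10⁻⁶, no line search);
analytic gradients are verified against central finite differences in the
tests. A 15 % validation slice carved from the training rows drives early
stopping (patience 6 epochs, best-validation weights returned). All
randomness — split, weight init — descends from one integer seed, and
training is bit-reproducible.

Rows are pooled across channels for training (one row per channel ×
window). Whether the original protocol pooled channels or voted per
channel is not recorded; pooling is the default here, and the evaluation
stage provides the complementary channel vote.

## From window decisions to seizure events

Segment-level specificity, accuracy and AUC are measured on the held-out
30 % of rows. Event-level sensitivity and false detection rate are defined
on the whole record: per time window, the fraction of channels voting
ictal must reach 0.5 (the generalized-seizure assumption — a discharge
appears on most channels, a motion artifact on a few); consecutive
positive windows merge into events, bridging gaps ≤ 0.5 s, and events
shorter than 1 s are dropped. A true seizure is detected if any predicted
event overlaps it; predicted events overlapping nothing are false
detections, normalised per hour. How 0.5 s epoch decisions become
"seizures" is genuinely underdetermined in the source protocol — these
merge parameters (1 s minimum, 0.5 s gap, any-overlap detection) are the
package's documented defaults, all configurable. The specificity
denominator is taken as *total normal windows* (standard specificity);
the alternative reading "all windows" is not used.

## The synthetic generator

The generator emulates exactly the structure the method exploits, no more:

* **Background**: pink noise (1/f power) scaled to 20 µV RMS plus one
  alpha sinusoid per channel (uniform 8–12 Hz, random phase, 14 µV peak) —
  typical resting adult scalp amplitudes.
* **Seizures**: a peak-normalised spike-and-slow-wave cycle (≈ 70 ms
  biphasic spike, half-sine slow wave filling the 3 Hz period), repeated
  with half-cycle amplitude ramps at the edges, added on all channels
  (generalized model; focal injection is a config option). The added train
  peaks at $(gain-1)\times$ the local background RMS, so `gain = 1` is an
  exact identity and the default `gain = 5` produces the unmistakable
  high-amplitude discharge of the target seizure type.
* **Contamination**: a common-mode 50 Hz sinusoid (15 µV) and five 2.5 s,
  150 µV, ~0.7 Hz Hann-windowed transients on 3 random channels each
  (electrode/cable movement).
* **Determinism**: one global seed fans out to per-channel streams, so
  identical configs are bit-identical and adding channels never reshuffles
  earlier ones. Every injected event is annotated exactly once with exact
  onset/offset.

The default study fixture is 20 min of 19-channel, 128 Hz EEG with ten
gain-5 seizures of 10–25 s — a seizure burden chosen to give stable
event-level statistics in a desk-scale experiment while keeping class
imbalance realistic (~12 % ictal windows).

What the generator does **not** model: spatial correlation from volume
conduction, non-stationary background state changes (sleep stages, drowsiness),
focal seizure evolution and propagation, electrode impedance drift, EMG
contamination, or patient-to-patient variability. Passing the end-to-end
test therefore shows the pipeline is internally correct and recovers
planted structure under realistic amplitudes and noise — it does not
certify clinical performance, which can only be established on annotated
patient data.

## Numerical and degenerate-input conventions

* Constant windows: entropies return 0 (single occupied bin); the PSD
  returns 0 with a warning; Teager energy is exactly 0.
* Annotation intervals are closed; same-label events that touch are
  merged; different labels never merge.
* Quartiles use linear interpolation between order statistics (type 7),
  SD uses the $n-1$ denominator, and the semi-interquartile deviation is
  IQR/2 — stated explicitly so tabulated summaries are reproducible.
* Rank-sum: mid-ranks for ties; z from the tie-corrected normal
  approximation with 0.5 continuity correction; exact enumeration of all
  $\binom{n}{n_1}$ rank assignments replaces the approximate p when
  $\min(n_1,n_2) \le 8$ and the pooled sample is tie-free.
* Prediction threshold: label 1 iff score > 0.5; an exact 0.5 (e.g. an
  all-zero network) is normal.
* EDF output quantises to 16 bits over each channel's physical range;
  round-trip error is bounded by one quantisation step. Annotations travel
  in a sidecar CSV since plain EDF has no annotation container.

## Problem sizes used in the shipped experiments

The packaged end-to-end experiment (also what `scripts/acceptance.R`
reruns) uses the 20-minute default fixture: 45 600 feature rows
(19 channels × 2 400 windows), a 70/30 stratified split, and five model
fits (multi-feature plus four single-feature references). Unit and
property tests use 1–2 minute fixtures with 4–8 channels, 100–200-trial
Monte-Carlo checks, and brute-force oracles capped at $n \le 200$ — sizes
chosen so each check isolates one property with comfortable margins.

## Known limitations

* The fixed-point ICA backend is a generic contrast-based unmixing; it is
  deterministic but, like all ICA, permutation/sign-indeterminate — the
  rejection rule is therefore defined on component statistics, never on
  component order.
* Entropy direction is deliberately not asserted anywhere: published
  summaries of this feature family disagree internally on whether ictal
  Shannon entropy rises or falls, and on synthetic data its direction
  depends on the spike duty cycle. The classifier uses whatever direction
  the data provide.
* Event scoring on a single continuous record reuses windows that the
  classifier saw during training (only S⁻/AUC are strictly held out);
  with one recording there is no patient-level split. This mirrors the
  limits of any single-record protocol and is flagged in the report
  structure.
* `fs` below ~100 Hz squeezes the 40 Hz band edge against Nyquist; the
  config validator rejects impossible settings rather than silently
  redesigning filters.
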
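---
title: "Predicting P300 speller performance from RSVP features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting P300 speller performance from RSVP features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsvp300)
```

## The scientific question

Matrix P300 spellers infer the attended character of a 6 x 6 symbol grid
from the event-related potential (ERP) evoked by row/column flashes.
Their usefulness is limited by large between-subject performance
variation, so a practical question is whether a short, low-workload
screening task can predict how well someone will operate the speller.
`rsvp300` implements one candidate protocol: a rapid serial visual
presentation (RSVP) task — 21-character streams at 10 Hz, one green
target per stream, 40 trials — from which five per-subject features are
extracted:

* **X1, T1%** — percentage of correctly reported targets (non-response
  counts as wrong);
* **X2, P300 amplitude** and **X3, P300 latency** — means over target
  trials of the single-trial peak measures on the channel-averaged
  (Fz, Cz, Pz, CP1, CP2) waveform;
* **X4, X5** — the across-trial standard deviations of the same two
  per-trial series ("trial variations").

Speller performance is the subject's single-trial target/non-target
classification quality: a stepwise linear discriminant (SWLDA) is
trained on decimated epochs and scored by the area under the ROC curve
(AUC) under 10-fold cross-validation. Single- and multi-feature linear
predictors of that AUC are then compared under leave-one-subject-out
(LOSO) cross-validation.

Because no public recordings exist for this protocol, the package ships
a synthetic-data module with known ground truth; every analysis stage is
exercised against cohorts whose latent parameters are controlled.

## The generative model

### P300 template and spatial projection

Each attended target evokes a Gaussian bump (`p300_template()`): peak
amplitude `A` uV, peak latency `L` ms, 100 ms full width at half
maximum (sigma = width/2.355), hard-zeroed beyond three widths. A
Gaussian is the simplest unimodal surrogate of the P3b deflection; none
of the analyses depend on its exact shape, only on its peak location and
height. Per-trial amplitude is drawn from `Normal(amp_mean, amp_sd)`
truncated at 0, per-trial latency from `Normal(lat_mean, lat_sd)`
clipped to the epoch.

The template projects onto the 32-channel montage through a fixed gain
vector that is maximal (1.0) over Cz/Pz/CP1/CP2 and decays to 0.3 at the
periphery, mimicking the centro-parietal P3b topography. Because the
analysis pipeline re-references to the common average and then averages
five channels, a raw injection would reach the feature extractor
attenuated by the net gain (about 0.36). The generator therefore scales
the injected template by the inverse of that net gain, so that
**`amp_mean` is expressed in observed units**: a subject with
`amp_mean = 2.88` uV yields a measured channel-averaged amplitude of
about 2.88 uV plus the noise-driven peak-picking bias. This keeps the
latent parameters on the same scale on which such amplitudes are
conventionally reported.

### Background noise

Noise is an AR(1) process (coefficient 0.95, 80% of the power) plus
white noise (20%), scaled per channel by the same spatial gain and by
the subject's `noise_sd` (broadband SD in uV). The AR component gives
the 1/f-like spectrum of spontaneous EEG without extra dependencies.
After the 0.5-10 Hz band-pass, a `noise_sd` of 4 uV leaves roughly
2-3 uV of in-band background per channel, i.e. a single-trial peak
signal-to-noise ratio near one for an average subject — low enough that
single-trial latency picking is visibly noisy (as it is in practice),
high enough that the speller classifier performs well above chance.

### Attentional lapses and the engagement factor

Behavioral and electrophysiological performance are linked through two
mechanisms:

1. **A latent engagement factor.** Across subjects, each trait is drawn
   as `mu + sd * (rho * g + sqrt(1 - rho^2) * e)` with a shared
   standard-normal `g`. The default loadings are +0.7 on the T1
   detection probability, -0.7 on the latency jitter, and +0.4 on the
   P300 amplitude: attentive subjects report targets more reliably,
   lock their P300 more tightly, and produce somewhat larger responses.
   Setting all `rho = 0` in `cohort_population()` makes the traits
   independent.
2. **Per-flash lapses in the speller.** Each target flash is unattended
   with probability `2 * (1 - t1_prob)` (capped at 0.6), and an
   unattended flash evokes no P300. The lapse process that causes missed
   T1 reports in the brief RSVP streams recurs — amplified by the long,
   monotonous flash sequences — during spelling. This gives the
   behavioral feature a predictive channel that the RSVP ERP features
   cannot absorb, which is what makes a multi-feature predictor
   genuinely better than the best single feature rather than a
   re-weighting of one dominant axis.

### Population defaults

| Trait | Mean | SD | Bounds | Loading rho |
|---|---|---|---|---|
| `amp_mean` (uV) | 2.88 | 0.92 | [0.5, Inf) | +0.4 |
| `amp_sd` (uV) | 1.0 | 0.3 | [0.1, Inf) | 0 |
| `lat_mean` (ms) | 455.8 | 65.6 | [300, 650] | 0 |
| `lat_sd` (ms) | 60 | 12 | [5, Inf) | -0.7 |
| `t1_prob` | 0.92 | 0.06 | [0.5, 1] | +0.7 |
| `noise_sd` (uV) | 4 | 0.6 | [2.5, 6] | 0 |

Amplitude, latency and T1 means/SDs reproduce the reported cohort
statistics of the protocol this package models. The trial-level jitter
magnitudes and the noise level are not directly observable quantities;
they were fixed once so that the simulated study reproduces the
reported *structure* of the real one — a positive amplitude-AUC
correlation near +0.4, a strongly negative jitter-AUC correlation, a
T1%-AUC correlation near +0.3, and a narrow AUC dispersion — and are
not tuned per analysis. Truncation is by clipping (mass at the bounds),
adequate for these mild truncations.

All randomness flows from one seed: `sample_cohort()` draws the
profiles and then assigns each subject an independent simulation seed,
so any subject's sessions can be regenerated bit-identically in
isolation.

## Preprocessing

The chain is fixed: common average reference, zero-phase band-pass,
epoching with baseline correction, artifact rejection, and (RSVP only)
removal of the three non-targets following each target. All transforms
are pure; counts satisfy retained + flagged = extracted.

* **Band-pass.** The 4th-order Butterworth band-pass (0.5-10 Hz) is
  realised as a high-pass/low-pass cascade, each of order 4, because an
  8-pole transfer-function band-pass with a 0.5 Hz edge at 512 Hz is
  numerically fragile, while the cascade is robust and has the product
  magnitude response. It is applied forward-backward (zero phase) so
  filter group delay cannot shift ERP latencies; tests verify the
  measured response against the analytic cascade magnitude squared.
* **Epoching.** Half-open windows with floor sample counts: 0-800 ms at
  512 Hz gives 409 samples (onset sample included), the 200 ms baseline
  gives 102 samples (onset excluded). The baseline mean is removed per
  epoch and channel.
* **Artifact rejection.** An epoch is flagged if any sample exceeds
  100 uV, or if its per-channel peak absolute amplitude deviates from
  the across-trial distribution by more than 5 SD. The reference mean
  and SD exclude the epoch under test (leave-one-out): with an
  include-self SD the maximum possible standardized deviation among n
  trials is (n-1)/sqrt(n), so a 5-SD rule could never fire for n below
  ~26 no matter how extreme the epoch.
* **Adjacent non-targets.** At 10 Hz the epochs of the non-targets
  following a target contain the target-evoked response, so the three
  *following* stream positions are excluded. ("Adjacent" could also be
  read as preceding or nearest; preceding epochs end before the target
  response develops, so the forward reading is the physiologically
  motivated one.)
* An identity hook (`ica_hook`) marks where component-based ocular
  artifact correction would run on real recordings; the synthetic data
  carry no ocular artifacts, so the default is a pass-through.

## Feature extraction

Single-trial peaks are taken on the channel-averaged waveform: latency
is the time of the maximum within 250-750 ms (the canonical P300
range; earliest sample on ties), amplitude the mean of the samples
within +/-50 ms of that peak (window clipped at epoch edges). X2/X3 are
means of the per-trial series and X4/X5 their sample SDs (n-1), so one
consistent per-trial estimator feeds both the level and the variation
features. Peak-of-average and average-of-peaks differ in general; the
per-trial definition is the implemented one because the variation
features require it.

Two estimator properties matter for interpretation and are visible in
the tests: the windowed mean lies below the true peak for a curved
template (by about 6% for a 100 ms-wide Gaussian), and at realistic
noise the measured X5 is `sqrt(lat_sd^2 + picking-jitter^2)` — an
upward-biased estimate whose bias shrinks with the signal-to-noise
ratio. Parameter recovery is therefore verified at low noise, while at
cohort noise levels X5 acts as a *correlate* of the injected jitter
(and of the noise level), exactly the role it plays in the analysis.

In the noiseless limit X5 is exactly zero; X4 retains a ~0.04 uV floor
because the slow high-pass recovery of neighbouring targets leaks a
little trial-to-trial amplitude variation. The tests assert this
magnitude-scale distinction rather than exact zero.

## Speller classification (SWLDA)

Retained epochs are decimated by non-overlapping 24-sample block means
(409 samples -> 17 points; the trailing remainder is discarded) and
flattened channel-major into 32 x 17 = 544 features. Labels are coded
+/-1 and regressed with forward/backward stepwise selection: the
forward step adds the feature with the smallest partial-F p-value if
below `p_enter = 0.10`, the backward step removes any feature whose
p-value exceeds `p_remove = 0.15`, until no change or 60 features.
These thresholds are the long-standing defaults of BCI SWLDA practice;
with permissive thresholds the procedure reduces exactly to ordinary
least squares, which the tests exploit as an oracle. Internally the
selection runs on Gram matrices with incremental Gram-Schmidt updates,
so cross-validation reuses pooled sufficient statistics instead of
refitting from raw rows.

Folds are stratified (single seeded shuffle, classes dealt round-robin)
so every fold keeps the 1:5 target/non-target imbalance; an empty model
(nothing passes `p_enter`) contributes the chance AUC of 0.5. AUC uses
the rank (Mann-Whitney) formulation with ties counted one half, making
it invariant under monotone score transforms.

## Predictor evaluation

Features are z-scored with means/SDs from the training subjects only —
inside every LOSO fold — before multi-feature fitting, since the five
features carry different units. Three model kinds are compared: simple
regression on one feature, least squares on all five, and stepwise
selection over the five (`p_enter = 0.05`, `p_remove = 0.10`, the
conventional stepwise-regression defaults; no cap).

`predictor_report()` tabulates, for each of the seven predictors, the
Pearson r between LOSO predictions and actual AUC, its p-value and
F = t² with n-2 df, R² = r², and the MSE with predictions and outcomes
multiplied by 100 (the AUC's native 0-1 scale makes raw MSEs
uninformatively small). Fitting always happens on the 0-1 scale; the
x100 factor is applied only when reporting MSE. An `r_insample` column
carries the raw feature-outcome correlation (single features) or the
fitted-value correlation (multi-feature models), since prediction-based
and in-sample correlations answer different questions and the
literature is not always explicit about which is printed. A caveat
worth knowing: for a feature with no signal, LOSO predictions of a
simple regression are *negatively* correlated with the outcome (the
held-out subject is missing from the training mean), so strongly
negative LOSO r values mark useless predictors, not useful inverse
ones.

## Cohort statistics

Group contrasts use the pooled-variance two-sample t-test on the
top-10 vs bottom-10 performers (Welch's form available via a flag).
Channel-wise feature-AUC correlation maps attach Benjamini-Hochberg
flags at q = 0.1. Outlier screening flags subjects below
`mean - 2.5 SD` of the cohort AUC — one-sided low, since the screen
targets disengaged subjects; analyses are reported with and without
them. The trial-count sweep recomputes all features from trials 1..N
for N = 5..40 (subjects with fewer retained trials use all remaining)
and tracks each feature's correlation with AUC, plus the two
multi-feature predictors' LOSO correlations.

## Validation studies and their limits

The package's own validation (test suite and `scripts/acceptance.R`)
runs replicate studies at a deliberately reduced size chosen to keep a
full 20-replicate battery within minutes on one CPU: 48 subjects,
128 Hz sampling, the complete 40-trial RSVP task with a 1 s response
window, and a speller run of two test words at three repetitions
(504 flash epochs). Identity checks (event counts, 409 -> 17
decimation) run at the published full-size settings. On these replicate
cohorts the measured behavior reproduces the qualitative structure of
the protocol's published findings: trial variation in latency is the
strongest (negative) single correlate of speller AUC, amplitude and T1%
correlate positively, and the stepwise multi-feature predictor's LOSO r
exceeds the best single feature's in roughly three quarters of
replicates.

What passing these tests does **not** show: the generator has no ocular
or muscle artifacts (so the rejection stage is exercised only by its
statistical rule, not by realistic contaminants), no volume-conducted
correlated noise between channels, a stylized Gaussian P300 with no
overlapping N200/P3a components, and stationary noise within a session.
Conclusions about real recordings require the real-data adapter path
(session directories plus the ICA hook), not the simulator.
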
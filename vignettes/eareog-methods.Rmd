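---
title: "Ear-based electrooculography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ear-based electrooculography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eareog)
```

## The measurement problem

The eye carries a standing electrical dipole — the cornea is positive
relative to the retina — whose orientation follows gaze. Skin electrodes
pick up the projection of that dipole, so a *differential pair* (montage)
of electrodes yields a voltage that tracks eye rotation: this is
electrooculography (EOG). Conventional EOG glues wet electrodes around the
eyes; `eareog` analyses the same signal taken from electrodes arranged
around the ears, where they could live in an ordinary headphone. The
package answers three questions for that setting:

1. **Which periauricular montage tracks gaze best?** Candidate pairs are
   correlated against gold-standard periorbital EOG and against a
   camera eye tracker during smooth-pursuit trials, with a constrained lag
   search absorbing device latency.
2. **How does the saccade voltage deflection relate to saccade
   amplitude?** Step-shaped gaze changes produce step-shaped montage
   deflections; the per-angle mean deflections are compared to the gold
   standard and checked for linearity.
3. **How well can a linear model predict the gaze-angle change of a
   saccade from deflections alone?** Evaluated as mean absolute angular
   error with Bland–Altman agreement against the gold standard.

Because the corresponding laboratory recordings are not publicly
deposited, the package ships a forward simulator that generates the full
study's conditions, and every claim the test-suite makes is made about
that simulator's output.

## The forward model

Each eye is modelled as a point dipole at the eye center with moment
$m\,\hat g(\theta_h,\theta_v)$, where $\hat g$ is the unit gaze vector.
The potential at electrode position $\mathbf e$ in a homogeneous medium is

$$V(\mathbf e) = m \sum_{\text{eyes}} \frac{\hat g \cdot (\mathbf e - \mathbf c)}{\lVert \mathbf e - \mathbf c \rVert^{3}},$$

with $\mathbf c$ the eye center. No skull/tissue conductivity structure is
modelled: the analysis pipeline only needs a realistic *gain and
correlation structure* across electrode positions, not biophysical
fidelity, and the homogeneous dipole already reproduces the qualitative
findings that motivate the analysis (electrodes nearest the eyes are most
sensitive; cross-ear pairs roughly double the gain of within-ear pairs;
vertical sensitivity at ear level is several-fold weaker than horizontal,
from geometry alone — no ad-hoc attenuation factor is applied).

Key defaults, chosen once on physiological grounds:

* **Dipole moment** `0.21 uV m^2` per eye: gives a ~40 uV noiseless
  cross-ear (L8–R8) step for a 15° saccade — the scale reported for
  periauricular measurements — and ~10 uV/° for gold-standard horizontal
  EOG, inside the textbook 10–20 uV/° range.
* **Electrode ring**: eight electrodes on a 5 cm-radius ring around each
  ear canal, with positions 8 and 1 anterior (nearest the eyes) at/near
  eye level; reference and ground sit below the ears; periorbital
  electrodes at the outer canthi (hEOG) and above/below the left eye
  (vEOG). True coordinates are not published, so the layout is a
  plausible adult-head placeholder and fully overridable.
* **Noise**: 2 uV white sensor noise, 3 uV/sqrt(s) random-walk baseline
  drift, 5 uV of 50 Hz mains (removed by the 15 Hz low-pass edge).
* **Camera**: 60 Hz, 0.3° angular noise, 2 % dropout, 100 ms latency
  (up to 500 ms supported — the lag search against the camera allows
  ±64 samples ≈ 500 ms for exactly this reason).
* **Saccades**: 200 ms reaction latency, and a raised-cosine ballistic
  profile whose duration follows the main sequence
  (≈ 21 ms + 2.2 ms/°), rather than an instantaneous step.

What the simulator deliberately does **not** emulate: blinks and EMG
artifacts, head movement, electrode-skin impedance drift beyond the
random walk, and real EEG background. Passing tests therefore show the
pipeline is correct and well-behaved under the modelled conditions; they
do not certify performance on real recordings, whose artifact structure
is richer.

## Signal conditioning

All channels are band-pass filtered at ingest: 0.1–15 Hz, 5th-order
Butterworth, applied forward and backward so the lag analysis does not
inherit the filter's group delay. Two numerical points deserve record:

* The transfer-function (b, a) representation of this filter — a
  10th-order band-pass whose lower edge sits at 0.0016 of Nyquist — is
  numerically singular in double precision. The package therefore designs
  the filter analytically (Butterworth prototype poles → band-pass
  transform with prewarped edges → bilinear transform) and applies it as
  a cascade of second-order sections, each initialised in its step steady
  state, on an odd-reflection extension of the signal. The implemented
  response matches the closed-form Butterworth magnitude to six
  significant digits across 0.05–50 Hz.
* A 0.1 Hz high-pass has transients that outlive a 6-s trial (its slowest
  pole decays with a ~5 s time constant). Trial-level camera filtering is
  therefore done with up to 3 s of surrounding recording as context,
  trimmed off after filtering. The EOG chain never refilters trials: the
  band-pass is applied once to the whole recording.

The trial-level chains follow the order: EOG —
detrend → 50-sample mean filter → min–max normalization to [−1, 1];
camera — interpolate missing samples → resample to 125 Hz → band-pass →
mean filter → normalize. Min–max (not max-abs) normalization guarantees
both interval endpoints are attained; a constant trial cannot be scaled
and is flagged *degenerate* (and excluded from correlations) instead of
producing NaNs. The mean filter truncates its window at the edges, the
simplest contract that preserves length.

## Montage selection

For every candidate pair and trial, the conditioned differential signal is
correlated with the conditioned reference at every integer lag within
±12 samples (≈100 ms) for gold-standard EOG or ±64 samples (≈500 ms) for
the camera; the signed correlation at the |r|-maximizing lag is kept
(pair order fixes the sign arbitrarily, so ranking uses |r|). Ties break
toward the smaller |lag|, then the negative lag — a fixed, documented
rule rather than an implementation accident. Per-trial correlations are
averaged through the Fisher z-transform; |r| = 1 (possible on noiseless
synthetic data) is clipped to 1 − 10⁻⁶ to keep the transform finite.

Montages are compared with a Friedman test on participant-level Fisher
means (the observation unit is configurable — the literature often leaves
it implicit), followed, when p < 0.05, by all-pairs two-sided Wilcoxon
signed-rank tests with Bonferroni correction. A pair with all-zero
differences is reported as p = 1 and flagged rather than dropped.

## Saccade deflections

Epochs of 2 s are cut per outbound stimulus jump, starting 0.75 s before
the jump so the saccade (after its ~0.2 s reaction latency) sits near the
window center. Center-return saccades are extracted on request but
excluded from amplitude analyses, which assume a center resting position.
A velocity-threshold labeler replaces manual annotation: smooth,
differentiate, find the velocity peak whose sign matches the stimulus
direction, and walk outward to the nearest 15 %-of-peak crossings; the
label is invalid when the peak does not exceed 5 MADs of the window
velocity ("no clear start and end"). Both thresholds are arguments.

The deflection statistic is the mean of ten samples around the saccade
end minus ten around the start — *post minus pre*, so rightward/upward
saccades give positive deflections on positively oriented channels; the
opposite order would contradict the sign of every reported deflection.
Where exactly the ten samples sit is a genuine design fork, and the
package implements all three readings (`mode` argument):

* `"flank"` (default): the ten samples immediately outside the labelled
  span. The slow tails the 0.1 Hz high-pass leaves behind neighbouring
  saccades change little across the ~300 ms involved, so they cancel in
  the difference, and ~99 % of the step height is retained.
* `"span"`: the first/last ten samples inside the span. With a 15 Hz
  low-pass at 125 Hz a labelled span is only ~15–17 samples, shorter than
  the 20 samples this estimator needs, so it frequently abstains and
  keeps only ~65 % of the step when it does not.
* `"window"`: the first/last ten samples of the whole 2-s window. The
  window edges lie ~2 s apart, where the neighbouring-saccade tails do
  *not* cancel and the step itself has decayed to ~50 %.

The flank estimator is the default because it is the only one that is
simultaneously well-defined for every saccade amplitude and linear in the
step height; the measured per-angle mean deflection against signed
amplitude is linear with r > 0.999 on noiseless cohorts. Ear-vs-gold
agreement per direction correlates the *absolute* per-angle mean
deflections, so each montage's polarity convention cancels.

Vertical epochs are processed identically but flagged `reliable = FALSE`
in every report: at ear level the dipole geometry gives vertical montages
a several-fold weaker gain, and the package treats vertical earEOG as
exploratory rather than silently equal.

## Gaze-angle prediction

Ordinary least squares maps deflection features (uV) to the signed
camera-measured angle change (degrees) — one model per feature set: the
best horizontal pair, all configured pairs, and the gold standard. The
evaluation is leave-one-participant-out by default (a pooled in-sample
option exists): the published description is a one-model-fits-all
approach without a stated split, and LOPO is the evaluation that matches
that claim while keeping train and test participants disjoint. Errors are
reported as mean ± SD of |predicted − truth| per direction and amplitude
with per-direction and overall totals, plus Bland–Altman mean difference
and 1.96 SD limits of agreement between methods.

## Problem sizes and determinism

The bundled smoke configuration simulates 2 participants × 1 cycle; the
acceptance script uses 4 participants × 1 cycle for ranking and
prediction and 8-participant cohorts appear in the test-suite's
linearity and noise-sweep checks. These sizes were chosen so the full
grid (six opening angles, three pursuit frequencies, four saccade
directions) is exercised end to end at desk scale; all of them are plain
arguments.

Determinism is a contract, not an aspiration: a single global seed fans
out to per-participant sub-seeds through a fixed counter scheme (adding a
participant never perturbs existing ones), every random draw goes through
those seeds, and two runs of the same configuration produce
byte-identical artifacts — which the test-suite asserts.

## Known limitations

* The electrode coordinates, dipole gains and noise magnitudes are
  plausible stand-ins, not measurements; absolute correlation values on
  synthetic data (e.g. the near-unity horizontal mean r) are optimistic
  relative to the published real-data values, and only the *structure*
  (which montage wins, linearity, horizontal ≫ vertical) transfers.
* The labeler assumes exactly one saccade per window in the stimulus
  direction; it is not a free-viewing saccade detector.
* Vertical-angle prediction is excluded by design, mirroring the weak
  vertical sensitivity; vertical results are flagged unreliable
  throughout.
* Blink artifacts are absent from the simulator, so the exclusion rate of
  the labeler on synthetic data (≈0) underestimates real-world exclusion.
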
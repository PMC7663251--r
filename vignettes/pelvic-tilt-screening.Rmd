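---
title: "Methods: accelerometer inclinometry and mobility screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerometer inclinometry and mobility screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelviscreen)
```

## The measurement model

A 3-axis accelerometer held still measures only gravity, so the measured
acceleration vector gives the sensor's orientation relative to vertical.
With the sensor mounted across the sacrum (X sagittal, Y frontal, Z away
from the body), pelvic pitch and roll follow from

$$\theta = \arctan\!\left(\frac{-A_x}{\sqrt{A_y^2 + A_z^2}}\right),
\qquad \phi = \operatorname{atan2}(A_y, A_z),$$

both reported in degrees. Pitch is the clinically relevant quantity here
(the lateral radiograph only measures the sagittal plane); roll is carried
through as a diagnostic. The pitch formula depends only on the direction of
the measured vector, so it is invariant to positive gain error — a useful
property for an uncalibrated wearable.

**Assumptions.** The patient is stationary during the analysed segment
(gravity-only signal); the clamp tracks the pelvis rigidly; accelerations
are expressed in g (a configurable unit scale is applied on ingest). The
static assumption fails intermittently — patients sway and occasionally
knock the device — which is exactly what the stable-window step absorbs.

## Stable-window selection

Each capture (nominally 5 s at 200 Hz) is reduced to a single tilt value:

1. Smooth each channel with a **zero-phase moving average**: a causal
   moving average run forward and then backward, so the pass-band delay of
   the two passes cancels and stable segments are not displaced in time.
2. Compute the per-sample pitch series from the smoothed channels.
3. Score every candidate window of length `window_s` (default 0.3 s) whose
   start is a multiple of `hop_s` (default 0.1 s) and which fits entirely
   inside the trace, by the standard deviation of pitch inside the window.
4. Select the window with the lowest SD; report the **mean** pitch (and
   roll) over it, together with the window bounds and SD for auditability.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `window_s` | 0.3 | s | stability window length |
| `hop_s` | 0.1 | s | spacing of candidate window starts |
| `filter_len_s` | 0.05 | s | moving-average length (10 samples at 200 Hz) |
| `sample_rate_hz` | 200 | Hz | nominal sampling rate |
| `threshold_deg` | 13 | deg | high-mobility classification threshold |
| `loa_k` | 1.96 | – | limits-of-agreement multiplier (~95% coverage) |
| `anterior_sign` | +1 | – | mounting-orientation sign flip |
| `mode` | absolute | – | threshold on \|Δ\| (absolute) or signed Δ |

The window length, hop, threshold and rate are the protocol values. The
filter length is a design choice of this package: 50 ms is long enough to
suppress sample-level sensor noise yet much shorter than the 300 ms window,
so it cannot blur genuine sway into apparent stability. It is configurable,
and all file-based runs echo the full effective configuration into their
reports.

## Numerical and design choices

Several details of the procedure are genuinely open; the package fixes them
as follows and exposes each as a parameter where it could matter.

- **What "lowest standard deviation" is measured on:** the smoothed pitch
  series, since pitch is the measurand. (Scoring raw channels instead would
  privilege whichever axis happens to carry the most noise.)
- **Window summary statistic:** the mean pitch over the selected window —
  the minimum-variance summary under the static assumption.
- **Filter edge handling:** reflect padding at both trace ends, so the
  first and last windows are not biased by start-up transients of the
  filter. A constant signal passes through unchanged, and a one-sample
  filter is the identity.
- **Ties in window SD:** earliest window wins (deterministic).
- **Partial windows:** candidate starts are only those with
  `start + window_s ≤ duration`; no partial windows are scored.
- **Baseline pairing:** each functional capture is compared against the
  *nearest preceding* standing capture, matching a protocol that re-takes a
  standing baseline before every functional position.
- **Classification direction:** the default thresholds the *absolute*
  change, counting anterior and posterior rotation alike; a signed
  (anterior-only) mode is available, as is a flexed-seated-only screen
  (`positions = "flexed_seated"`). The overall per-patient flag is an OR
  over positions: a screening instrument should favour sensitivity.
- **Bland–Altman:** bias is the mean of device-minus-reference differences;
  SD uses the sample (n−1) denominator; limits are bias ± k·SD with
  k = 1.96 by default. `agreement_limits()` reconstructs limits from a
  published bias/SD pair when raw pairs are unavailable.
- **Quantiles:** absolute-error median and third quartile use linear
  interpolation (R type 7), stated in the output because published
  quartiles depend on the convention.
- **Poisson overlay:** absolute errors are binned to the nearest degree and
  the Poisson rate is their maximum-likelihood estimate (the sample mean of
  the binned values). This is a descriptive overlay, not a claim that a
  Poisson mechanism generates the errors.
- **Degenerate inputs:** a zero acceleration vector (no gravity component),
  `ay = az = 0` (roll undefined), traces shorter than the window, empty
  pair sets, constant correlation inputs and zero metric denominators all
  raise errors or flagged `NA`s — never silent zeros.

Two reporting quirks of validation studies in this area are surfaced rather
than resolved: squared Spearman coefficients are sometimes reported as
"R²", so `tilt_correlation()` emits both the coefficient and its square and
leaves the interpretation to the reader; and a published contingency table
may not sum to the stated cohort size (e.g. 33 entries against 32
patients). `diagnostic_metrics()` treats counts as given.

## The synthetic cohort generator

`simulate_cohort()` exists so every stage — trace ingest, window selection,
baseline deltas, classification, agreement statistics — can be tested
end-to-end with known ground truth. Per patient it draws a true standing
pitch and true flexed-seated (FS) and step-up (SU) tilt changes, emits a
four-capture session in protocol order (standing, FS, standing, SU), and
produces a radiograph-like reference delta (truth plus Gaussian noise).
Device deltas are then obtained by running the *full pipeline* on the
simulated traces.

Defaults describe a plausible pre-THA clinic population, chosen once:

- FS change ~ N(−10°, 12°): wide, both directions, ≈ 43% of patients past
  the 13° threshold — similar to the roughly 40% prevalence seen in
  validation cohorts of this size.
- SU change ~ N(2°, 4°): markedly narrower than FS, as observed.
- Standing pitch ~ N(5°, 5°); age ~ N(57.4, 9.4) years, BMI ~ N(29.2, 4.6)
  kg·m⁻², P(female) = 17/32 — covariates have *no* effect on the error
  structure by default, mirroring the reported absence of BMI and gender
  effects.
- Reference noise SD 2°: the radiograph is treated as ground truth for
  labels but still carries plausible measurement noise in the paired
  comparisons.
- Device noise: white accelerometer noise of 0.01 g per channel, a 1°
  sinusoidal sway at 0.3 Hz with random phase, and with probability 0.1 a
  0.5 g raised-cosine knock burst. Bursts are confined so that the final
  0.5 s of a capture is always clean — a stable window is guaranteed to
  exist, which is an assumption of the protocol, not of the search.
- SU device error includes a Gaussian component with SD proportional to
  |Δ| (slope 0.1), emulating the observed magnitude–error correlation for
  step-up; this is a phenomenological device-side term, not a mechanism
  claim.

**What the simulator does not emulate:** spine–pelvis biomechanical
coupling, skin-motion artefact spectra, radiograph image analysis,
multi-frequency sway, or any covariate-dependent error. Passing tests on
synthetic data therefore demonstrate that the *algorithms* are correct
under the stated signal model — not that the device achieves any particular
accuracy on real patients.

## Problem sizes and verification

The test suite verifies the window search against an exhaustive brute-force
minimum-SD oracle on 100 randomised traces, exact (≤ 1e−9°) recovery of
noiseless poses, sub-1° recovery under 0.01 g white noise, and a
200-patient seeded cohort whose FS deltas are recovered with mean absolute
error below 2°. The end-to-end check simulates 50 patients to disk,
re-screens every stored session, and confirms byte-identical reports across
runs with the same seed. `scripts/acceptance.R` uses the same sizes (200
simulated patients; 2 s captures), chosen so a full run completes in
seconds while leaving Monte-Carlo summaries stable to well under a degree
across seeds.

## Limitations

- Static captures only: no gyroscope/magnetometer fusion and no dynamic
  tilt tracking; pitch alone is classified.
- The standing posture is the only baseline; supine baselines are out of
  scope.
- All cohort-level numbers produced from the simulator are properties of
  the stated synthetic population, not re-measurements of any real cohort.
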
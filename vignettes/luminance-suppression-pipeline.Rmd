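---
title: "Modeling chromatic suppression of luminance responses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling chromatic suppression of luminance responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromsupp)
```

This vignette documents the science implemented in `chromsupp` and the
design choices made where the experimental record leaves the design open:
what each model assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic-data generators emulate (and
deliberately do not), and the numerical decisions inside the fitters.

## The paradigm

Two linked experiments probe how colored patches modulate
luminance-driven processing:

* **fMRI.** Ten patches — the Munsell principal hues at Value 5 and a common
  Chroma of 0, 2, 4 or 6 — ring the center of an achromatic ellipse texture
  (or a black background, in the control experiment). Block-design BOLD
  responses (15 s stimulation alternating patch and pixel-scrambled patterns
  at 1 Hz, 15 s rest) are averaged per chroma condition over 54 blocks and
  modeled per subject and visual area.
* **Psychophysics.** A vertical achromatic grating (0.67 cyc/deg), its
  contrast declining exponentially with eccentricity (1/e at 3.75°), carries
  the same patch ring; observers judge in a temporal 2AFC which of two
  gratings (reference 50% contrast, test 34–66%) has the higher luminance
  contrast.

The package reimplements the full computational chain for both arms and
feeds it, by default, with seeded synthetic data possessing the structure
the analysis assumes.

## Stimuli

Chip colorimetry is embedded as a 31-row table (ten hues × Chroma 2/4/6 at
Value 5, plus the neutral N5) derived from the Munsell renotation color map
and expressed against the D65/sRGB white point; the neutral chip sits
exactly on the white point, and colorimetric purity grows with chroma for
every hue. Luminance depends on Munsell Value alone (ASTM D1535 polynomial),
scaled so a Value-5 chip renders at 16.0 cd/m² on the scanner projector and
19.8 cd/m² on the psychophysics CRT (`white_for_value5()`).

Renderers are pure functions of (spec, seed, geometry): identical inputs are
bit-identical. Degrees map to pixels linearly with pixel centers at
half-integer coordinates — adequate at these eccentricities and exactly
invertible. Choices the protocol leaves open, fixed here with documented
defaults:

* fixation rectangle 0.3° (white at the display-white luminance);
* grating carrier vertical, cosine phase fixed so the screen center is a
  luminance trough;
* the eight background/mask luminance levels equally spaced across the
  stated ranges (0.23–30.24 cd/m² ellipses, 0.32–30.37 cd/m² mask squares).
  The stated realized mean (15.4 cd/m²) slightly exceeds the equal-spacing
  mean and is treated as descriptive; the level list is configurable;
* texture pixels never covered by one of the 600 ellipses take the fourth
  (middle) level, so every texture pixel carries one of the eight levels;
* the patch ring's hue arrangement is permuted per block seed and the whole
  ring jittered by one of −12/0/+12°, matching the randomization unit of
  the protocol.

**Measuring grating contrast.** Two Michelson measures are provided. The
plain min–max quotient `(Lmax − Lmin)/(Lmax + Lmin)` is correct for
unenveloped patterns, but for the enveloped grating it necessarily
understates the carrier contrast: the central trough and the nearest crest
are half a period apart, so the crest is attenuated by
`exp(−1/(2 f λ)) ≈ 0.82`, giving ≈ 0.476 for a 50% grating. The *maximum*
contrast the stimulus presents is the modulation contrast at the
most-modulated point — the center — which `method = "modulation"`
(`max |L − Lmean| / Lmean`) recovers as C to within pixel discretization.
That is the measure used for the 50%-reference check.

## The BOLD block-response model

`model_response()` implements the two-Gaussian-pulse model with the window
integrals in closed form via the Gaussian CDF (validated against
quadrature to 1e−8 relative). The objective is the relative squared error
`EV` summed over the four conditions and 13 grid points, with the four
temporal parameters shared. Assumptions worth stating:

* the 13-point grid is the *averaged* block response; no within-block
  autocorrelation model is fitted;
* relative error weights early, near-baseline samples heavily — the
  objective is faithful to the original analysis, and its consequences
  (below) are handled by explicit guards rather than by changing the loss.

Numerical design of `fit_joint_hrf()`:

* **Nested optimization.** Outer: multi-start Nelder–Mead on
  logistic-transformed coordinates over T1 ∈ [2, 12] s, T2 ∈ [8, 25] s
  (T1 < T2 enforced by a dynamic floor), α ∈ [0.5, 8] s; the first start is
  a canonical HRF-like point (6, 16, 2.5, 4) s, the rest seeded uniform
  draws. Inner: per-condition L-BFGS-B with analytic gradient on
  (a1, a2, b, d) under a1 ≥ 1e−6, a2 ≤ −1e−6, warm-started across outer
  evaluations, with sign-clamped least-squares and pulse-dominated moment
  starts as alternatives.
* **Drift bounds.** |b| ≤ 0.2 %sc/s and |d| ≤ 5 %sc (configurable). Without
  them the relative-error objective can trade the pulse response for a
  runaway ramp on noisy data (the "peak" then being the drift value at
  30 s) — a pathology of the loss, not of the data.
* **Denominator guard.** Model values below ε = 1e−3 %sc in the EV
  denominator are clamped to ±ε and counted; occurrences are reported.
* **Convergence.** After a tight polish, a fresh simplex restart must fail
  to improve EV by more than 1e−6 relative; otherwise the fit is returned
  flagged, never silently.
* **Peak.** Dense-grid (0.01 s) maximum of the fitted curve over [0, 30] s,
  drift included by default ("the fitted curve" read literally); a
  pulse-only mode is available since the original analysis does not say
  whether drift was excluded. Normalization subtracts the four-condition
  mean by default; a ratio-to-mean mode exists because the two published
  phrasings ("subtracted from the mean", "normalized by the average")
  conflict — subtraction is the default as the more specific of the two.

## Psychometrics

`fit_psychometric()` estimates (μ, σ) by trialwise maximum likelihood
(Bernoulli likelihood on per-level counts), the method of choice when the
original estimator is unreported; least squares on proportions is retained
for comparability and the two agree closely on clean tables. Faithful to the
model definition, there is no lapse or guess parameter by default (a lapse
is available in the *generator* to probe robustness). σ is constrained to [1e−4, 1]; boundary
hits (e.g. degenerate all-same responses) are flagged. The sensitivity
index is 1/σ; no d′ claims are made beyond this monotone reading.
`threshold_at_criterion()` returns μ + σΦ⁻¹(c). The subject-exclusion rule
flags cohort members whose mean σ across conditions exceeds three times the
cohort median — the documented case (a 0.35 outlier against a 0.05–0.12
cohort) is excluded exactly.

## Group statistics

`rm_anova_oneway()` computes the textbook within-subject decomposition
directly (SS_total = SS_condition + SS_subject + SS_residual, F on
(k−1, (k−1)(n−1)) df), cross-validated against `aov()` in the tests; the
direct form keeps the 10⁴-table null-calibration check fast. No sphericity
correction is applied, matching the original report. `tukey_hsd()` uses the
studentized-range distribution (`ptukey`), validated against direct
numerical integration of the range distribution to 1e−6. The main-vs-control
magnitude comparison defaults to Welch's t (the cohorts overlap only
partially); paired mode exists. The inside/on ratio is a plain quotient of
condition-averaged magnitudes, exposed as a helper.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *design*: 18 runs × (1 dummy + 12 blocks) with
each condition exactly three times per run in seeded pseudorandom order;
awareness-task errors at a rate calibrated to the reported 98.7% accuracy,
with runs exceeding three errors excluded; 12 sessions × 36 trials (9
contrasts × 4 chroma, each once per session) with the first two sessions
discarded; ISI 1000–2000 ms.

Noise choices (the record reports none):

* **BOLD:** additive Gaussian per sample and block (optional AR(1)),
  per-block sd 0.3 %sc and baseline offset d = 0.3 %sc by default. These
  were calibrated once so that 54-block-averaged fits produce EV values in
  the published 0.0137–0.1219 range (the preset run spans ≈ 0.05–0.13);
  larger noise against a near-zero baseline is incompatible with that EV
  scale. Averaged-level simulation (noise sd/√n on the mean) is the default
  since that is what the analysis consumes; per-block simulation exists and
  is used to verify the √54 averaging law.
* **Observer:** exact Bernoulli draws from the cumulative Gaussian, lapse 0.
* **Paper-like presets:** group-mean responses at the reported per-area
  magnitudes with condition offsets (+0.10, −0.10, −0.03, +0.03 %sc for
  /0, /2, /4, /6) expressing the qualitative suppression ordering
  /0 > /6 > /4 > /2, subject gains log-normal (sd 0.25); psychometric truth
  μ = 0.5 with σ = (0.080, 0.110, 0.070, 0.078) scaled by log-normal subject
  factors, expressing the σ elevation in the /2 condition.

What passing tests therefore show: that the estimators recover the
parameters of data with this structure, at this noise scale, and that the
group-level pattern propagates through the chain. What they cannot show:
anything about physiological BOLD noise (spikes, drift beyond linear,
vascular effects), real inter-subject variability, learning or attention
dynamics in the 2AFC task, or the true effect sizes — those require the
original recordings. Numeric agreement with the published group statistics
is *not* claimed; the synthetic presets reproduce orderings, not magnitudes.

Hierarchical seeding (one master seed, children derived per
subject/run/session) makes every stage — including the full
`run_pipeline()` bundle — byte-identical under a fixed config.

## Problem sizes and known limitations

The shipped tests run noise-free joint-fit recovery, 20-seed noisy recovery
(per-block σ = 5% of the mean peak), 2AFC recovery at 200 trials/level, a
10⁴-table null calibration of the ANOVA, and full small-cohort pipeline
runs; these sizes keep the suite comfortably reproducible on one CPU while
leaving the statistical checks well-powered. Limitations to keep in mind:
the EV objective is non-convex and the optimizer, though multi-started and
flagged, can in principle return a local optimum on adversarial data; the
peak of weakly responding areas (the published V3A/B case) is correspondingly
less stable; the embedded chip table covers exactly the chips the stimuli
need (Value 5, Chroma ≤ 6) and refuses anything else; and the renderers
target calibrated-display luminance maps, not device gamma.
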
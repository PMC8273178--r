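# chromsupp

Analysis tools for a paired fMRI/psychophysics paradigm on the suppression of
luminance responses by weakly saturated color. In the paradigm, ten colored
patches (Munsell hues at Value 5, Chroma 0/2/4/6) ring an achromatic
luminance texture while block-design BOLD responses are recorded in
retinotopic visual areas; a companion two-alternative forced-choice (2AFC)
experiment measures luminance-contrast discrimination on a grating carrying
the same patch ring. The package implements the full computational chain for
both experiments — stimulus generation, hemodynamic model fitting,
psychometric fitting and group statistics — together with seeded
synthetic-data generators that emulate the experimental design, so the whole
pipeline runs end to end with no external data. Real data enter through the
same plain-CSV schemas the simulators emit.

It is written for vision scientists who want to reuse, audit or extend this
analysis: every stage is an exported, documented, unit-tested function.

## The models

**BOLD block response.** The averaged response to a 15 s stimulation block,
sampled at t = 0, 2.5, …, 30 s, is modeled by two Gaussian pulses (positive
activation, negative undershoot) integrated over the trailing 15 s window and
gated at stimulus onset, plus a linear drift:

    ModelR_Ch(t_n) = ∫_{t_n−15}^{t_n} [ a1,Ch H(τ) e^{−(τ−T1)²/2α1²}
                                      + a2,Ch H(τ) e^{−(τ−T2)²/2α2²} ] dτ
                     + b_Ch t_n + d_Ch

with a1 > 0, a2 < 0 and H the Heaviside step. The four temporal parameters
(T1, T2, α1, α2) are shared across the four chroma conditions of one
subject/area; the per-condition parameters (a1, a2, b, d) are free. The joint
fit minimizes the relative squared error

    EV = Σ_Ch Σ_n [ (R_Ch(t_n) − ModelR_Ch(t_n)) / ModelR_Ch(t_n) ]²

by a nested search (derivative-free bounded outer search over the temporal
parameters, bounded quasi-Newton inner refinement per condition). The
response measure per condition is the peak of the fitted curve (% signal
change), normalized against the four-condition mean.

**Psychometrics.** The probability of judging the test grating as
higher-contrast is a cumulative Gaussian of the test contrast x,
P(x) = Φ((x − μ)/σ), with no lapse term. μ is the point of subjective
equality and σ — via signal detection theory — is inversely proportional to
the effective luminance signal-to-noise ratio, so 1/σ serves as the
luminance-sensitivity index.

**Group statistics.** One-way repeated-measures ANOVA (subject as blocking
factor), Tukey HSD pairwise comparisons via the studentized range, and
paired/Welch t comparisons.

## Worked example

Simulate one subject's block-averaged time courses under the paper-like
preset (suppression ordering /0 > /6 > /4 > /2 built into the ground truth),
fit the joint model, and extract normalized peaks:

```r
library(chromsupp)

truth <- paper_like_bold_truth(n_subjects = 1, seed = 42)[[1]]
tc    <- simulate_bold(truth, schedule_fmri(seed = 42), subject = 1)
fit   <- fit_joint_hrf(tc, hrf_fit_config(n_starts = 2))
fit
#> Joint two-Gaussian HRF fit
#>   temporal: T1 = 5.90 s, T2 = 16.49 s, alpha1 = 2.34 s, alpha2 = 4.40 s
#>   EV = 0.081512 (converged)
#>   /0: a1 = 0.5435, a2 = -0.0731, b = 0.00109, d = 0.3348, peak = 3.386%
#>   /2: a1 = 0.5200, a2 = -0.0536, b = -0.00099, d = 0.3219, peak = 3.240%
#>   /4: a1 = 0.5503, a2 = -0.0795, b = 0.00587, d = 0.2925, peak = 3.429%
#>   /6: a1 = 0.5463, a2 = -0.0761, b = 0.00407, d = 0.3066, peak = 3.404%

round(normalize_peaks(fit$peaks), 4)
#>      /0      /2      /4      /6
#>  0.0212 -0.1244  0.0641  0.0391
```

The fitted temporal parameters sit near the generating values
(T1 = 6, T2 = 16, α1 = 2.5, α2 = 4 s) and EV lands in the range a
well-behaved 54-block average produces. The normalized peaks are the
per-condition responses relative to the condition mean: /2 is clearly
suppressed in this subject; single-subject estimates of the smaller /0 vs /6
offsets are noisy, and the group ordering emerges across subjects — e.g. via
the end-to-end driver:

```r
res <- run_pipeline(pipeline_config(experiment = "fmri-main", seed = 1,
                                    out_dir = "fmri-demo"))
res$anova   # repeated-measures ANOVA on the 13 subjects' peaks, df (3, 12, 36)
res$tukey   # all six pairwise chroma comparisons
```

The psychophysical arm works the same way
(`pipeline_config(experiment = "psycho", ...)`): it simulates Bernoulli 2AFC
observers, discards the first two of twelve sessions, fits per-subject
psychometric functions, applies the outlier-subject exclusion rule and runs
the group ANOVA on σ.

A thin CLI over these functions ships in `inst/cli/chromsupp`
(subcommands `render-stimuli`, `simulate`, `fit-bold`, `fit-psycho`,
`stats`, `run-all`).

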
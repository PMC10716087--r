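# pupilbreadth

Does the pupil dilate when covert attention is directed further into the
visual periphery? Studies of *attentional breadth* test this with a cueing
paradigm: a symbolic cue directs attention to one of three annuli at fixed
eccentricities (near 1.16°, medium 3.47°, far 10.40° of visual angle), a
dynamic-noise display follows, and a faint luminance increment/decrement
must be discriminated while pupil size is recorded at 1000 Hz. The
hypothesis is a positive slope of baseline-corrected pupil size on the
ordinal cue eccentricity, coded −1/0/+1 for near/medium/far:

> pupil ~ ecc + (1 + ecc | participant)

with the analysis window localized inside a predetermined 750–3000 ms
post-cue range by four-fold cross-validation over participants, so that no
observation's window is chosen using that observation.

`pupilbreadth` implements the whole pipeline of such a study as tested R
code, validated end-to-end on synthetic data with known ground truth:

* **design** — reproducible 330-trial session schedules (10 equal blocks,
  80/20 cue validity enforced exactly per cued eccentricity,
  counterbalanced cue-symbol mappings) for three experiment variants;
* **staircase** — n-up-1-down opacity staircases (1% steps) that hold
  validly-cued accuracy near the equilibrium `0.5^(1/n)` (≈70.7% for
  2-up-1-down);
* **synthdata** — a psychometric observer (logistic, lapse rate, validity
  sensitivity gain) and a 1000-Hz pupil-trace generator with cue-locked
  light response, a breadth effect ramping in from 1750 ms, blinks and
  per-participant random intercepts/slopes;
* **preprocess** — blink interpolation, 10× downsampling, arbitrary-unit to
  millimetre conversion, 50-ms baseline correction, ±2 z baseline-outlier
  exclusion, in a fixed order with a processing-state marker;
* **windowstats** — cross-validated window selection with per-bin
  mixed-model screening, a non-circular confirmatory LME (lme4), the
  eccentricity × breadth-type interaction model, per-participant Pearson
  effect sizes;
* **behavior** — mixed logistic cue-validity model, RT model, a
  repeated-measures JZS Bayes factor for staircase efficacy (implemented
  in-package with quadrature over the g-priors), performance-deviance
  scoring and iterative participant exclusion.

## Worked example

Simulate a 12-participant cohort, preprocess it, and run the full analysis:

```r
library(pupilbreadth)

cfg <- default_config()
cfg$design$n_participants <- 12L
cfg$design$seed <- 42L
cfg$pupil <- list(sampling_rate_hz = 100, trace_end_ms = 3100,
                  breadth_slope_mm = 0.03)
cfg$preproc <- list(downsample_factor = 1L, mm_coeff_a = 0.001, mm_coeff_b = 0)
cfg$analysis <- list(search_start_ms = 750, search_end_ms = 3000,
                     n_folds = 4L, bin_ms = 50, window_ms = 100)
report <- run_pipeline(cfg)
print(report)
```

```
Pipeline report (exp1, n = 12)
  trials excluded: 175 (4.42%)
Cross-validated window selection (4 folds, 50-ms bins)
  fold peak bins (ms): 2950, 2950, 2950, 2900
  held-out t: 3.93, 12.16, 29.98, 4.97
  selected window: 2900-3000 ms
  full-data fit (intercepts_and_slopes): b = 0.02291, SE = 0.0097, t = 2.36, p = 0.01817
  validity effect: b = 0.693, z = 5.27, p = 1.375e-07
  RT on eccentricity: b = -2.530, t = -0.68, p = 0.4952
  staircase-efficacy BF01 = 3.05 (jzs_quadrature)
```

Reading the numbers: about 4.4% of trials were excluded (baseline z-scores
beyond ±2 plus missing trials — close to the ~4.55% expected under
normality). Each cross-validation fold's training peak lies late in the
search range, where the generated breadth effect has plateaued, and the
confirmatory mixed model recovers a positive eccentricity slope
(`b` ≈ 0.023 mm per ordinal-eccentricity step, here generated with a 0.03
mm population slope) with `p < .05`. Accuracy is much higher on validly
cued trials (log-odds `b` ≈ 0.69, `z` ≈ 5.3) because the simulated observer
has a validity sensitivity gain, while RT shows no eccentricity effect, as
designed. The staircase-efficacy Bayes factor `BF01 > 3` indicates
substantial evidence that the staircases equated accuracy across
eccentricities.

Per-participant effect sizes (the Pearson correlation between eccentricity
code and window-mean pupil size) are in
`report$pupil$effect_sizes`; in this run 9 of 12 participants show a
positive `r`, e.g. `-0.72 … 0.94` sorted.

A thin command-line wrapper over the same functions ships in
`inst/cli/pupilbreadth.R` (subcommands `design`, `simulate`, `preprocess`,
`analyze-pupil`, `analyze-behavior`, `check-staircase`, `run-all`).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the generative
model, every tunable parameter with units and defaults, the numerical
choices (window snapping, convergence handling, Bayes-factor quadrature),
what the synthetic data do and do not emulate, and known limitations.
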
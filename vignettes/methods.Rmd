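---
title: "Attentional-breadth pupillometry: models, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentional-breadth pupillometry: models, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Covert spatial attention can be focused narrowly around fixation or spread
into the visual periphery; its spatial extent is called *attentional
breadth*. Because a small pupil favours foveal acuity while a large pupil
favours peripheral sensitivity, an account of pupil control as *sensory
tuning* predicts that the pupil dilates as attention is directed further
into the periphery — even with visual input, task difficulty and gaze held
constant. The experiments this package models test that prediction with a
cueing paradigm: on every trial a symbolic cue directs attention to one of
three annuli at fixed eccentricities (near 1.16°, medium 3.47°, far 10.40°
of visual angle), a dynamic-noise display follows, and a faint luminance
increment or decrement must be discriminated. Pupil size is recorded at
1000 Hz, and the question is whether baseline-corrected pupil size increases
with the ordinal eccentricity of the cued annulus (coded −1/0/+1 for
near/medium/far), beginning well after the cue and before the target can
appear.

`pupilbreadth` implements the full inferential pipeline of such a study as
tested, reusable code: design generation, adaptive difficulty staircases, a
synthetic observer and pupil-trace generator, the preprocessing chain,
cross-validated time-window inference with linear mixed-effects models
(LMEs), and the behavioral/exclusion statistics. Everything runs on
synthetic data, so every step can be validated against known ground truth.

# Session designs

`build_session(variant, participant_id, seed)` creates the complete
trial-by-trial schedule. All variants have 330 trials in 10 equal blocks of
33. Variants `exp1`/`exp2` have 90 practice and 240 experimental trials;
`exp3` has 30 practice and 300 experimental trials, split 150/150 between a
*size* condition (only an annulus is cued) and a *location* condition (an
annulus plus a position within it), each occupying five contiguous blocks
whose order alternates across participants.

Two structural constraints — ten equal blocks and the practice/experimental
counts — are only jointly satisfiable if practice trials are distributed
over blocks, so each block opens with its share of practice trials (9 + 24
for `exp1`/`exp2`; 3 + 30 for `exp3`). Experimental trials are exactly 80%
valid within each cued eccentricity; this is enforced combinatorially, not
sampled, so design counts are deterministic and testable. Invalid targets
are spread uniformly over the non-cued eccentricities (size condition) or
non-cued annulus/location combinations (location condition), target polarity
(increment/decrement) is balanced 50/50 within cells, and practice trials
mirror the experimental proportions; none of these allocation details are
constrained by the design's published summary, so the simplest balanced
choices were fixed once. In the location conditions 150 trials cannot split
evenly over 12 cue cells, so cells within an eccentricity receive 12 or 13
trials by largest remainder while the per-eccentricity 80/20 split stays
exact.

Cue-symbol counterbalancing assigns the three symbols to the three
eccentricities as one of the six permutations, cycling deterministically
through participant indices; the combined location cues use the fixed code
scheme (1/2/3 = near/medium/far annulus, U/D/R/L = up/down/right/left), as a
per-participant remapping of ten distinct cues would be unlearnable.

The target appears at a uniformly random moment in \[3000, 4000) ms after
cue onset. The display sequence (1000-ms cue, then dynamic noise) fixes
3000 ms as the earliest possible target onset, which is also the upper
boundary of the pupil analysis range; the target is known to fall somewhere
in the final second of the noise display, and the uniform distribution over
that second is a modelling choice, as no finer timing distribution is
documented.

# Staircases

Target opacity is governed by an n-up-1-down staircase per eccentricity with
1% steps (`staircase_init()`, `staircase_update()`): after `n_up`
consecutive correct responses opacity drops by 1% (harder), after any error
it rises by 1% (easier), clamped to \[1, 100\]%. The equilibrium
percent-correct solves \(p^n = 1/2\): ≈70.7% for the 2-up-1-down rule used
with symbolic cues, ≈79.4% for 3-up-1-down. `simulate_staircase()` couples a
staircase to the synthetic observer and verifies convergence; the first 500
trials are discarded as burn-in so the trajectory can descend from its 50%
start into the equilibrium band. Only validly cued trials update the
staircase, since the accuracy criterion the staircase serves is defined on
validly cued trials. The floor of 1% keeps the target from vanishing
entirely; both it and the 50% start are conventions, not published values.

# The synthetic observer and pupil generator

The observer (`observer_params()`) performs the two-alternative
increment/decrement judgement with

\[ p(\text{correct}) = 0.5 + (0.5 - \lambda)\,F\!\big(s\,(g\,o - \theta)\big), \]

where \(F\) is the logistic CDF, \(o\) the opacity, \(\theta\) the
threshold, \(s\) the slope, \(\lambda \le 0.05\) the lapse rate, and \(g\)
a multiplicative sensitivity gain (≥ 1) applied on validly cued trials —
attention improves the effective signal, which yields the behavioral cueing
effect at matched opacity. A zero-opacity target carries no signal, so
\(p(0) = 0.5\) exactly. Placing the gain on the signal (rather than on the
opacity–threshold difference) is deliberate: it makes valid trials better
than invalid ones at every positive opacity, including at threshold.
Reaction times are log-normal (median 600 ms, sdlog 0.25) and independent of
eccentricity, matching the null RT result the staircase design is meant to
produce.

Pupil traces (`pupil_gen_params()`, `generate_trace()`) are sums of
piecewise-linear components in mm of diameter, sampled at 1000 Hz by
default:

* a participant-specific baseline, mean 5 mm, between-participant SD 0.5 mm;
* a slight dilation during the 1000-ms cue (peak 0.05 mm) that decays after
  noise onset;
* the pupillary light response to the noise display: a −1 mm constriction
  starting 220 ms after noise onset and rising linearly over 500 ms;
* the attentional-breadth effect: ordinal eccentricity code × a
  participant-specific slope, ramping linearly from zero at 1750 ms to its
  full value at 2500 ms and held thereafter. The onset and peak-window
  timing follow the reported time course; the linear ramp is a choice, as no
  functional form is published;
* white measurement noise (SD 0.05 mm per sample) and blinks as zeroed runs
  (0.1 blinks/s, 100 ms), the EyeLink convention for signal loss;
* conversion to arbitrary recorder units, `au = 1000·mm`.

The population mean breadth slope defaults to 0.008 mm per ordinal unit —
the order of the reported group effect — with a between-participant SD of
0.03 mm. That SD reproduces two features of the reported data at once: a
group-level standard error near 0.003 mm at n = 100, and roughly
two-thirds of participants with a positive individual effect. Piecewise
linearity makes the generator exactly decomposable: with noise and blinks
zeroed, the plateau value of a near trial is
`intercept + light_amplitude − slope`, which the tests assert to machine
precision.

`generate_dataset()` composes everything: per participant a fresh design,
per-eccentricity staircases coupled to the observer, one response and one
trace per trial, and participant effects drawn from the stated
between-participant normals. All randomness descends from one master seed
through named substreams (`substream_seed()`), so any stage can be
reproduced in isolation. Generator staircases start at the observer's
threshold opacity rather than 50%: a 1%-step staircase cannot travel from
50% to its ~22% equilibrium inside a 330-trial session, and the emulated
studies' sessions operate with accuracy already near the staircase target —
the start value models a calibrated session, not an arbitrary cold start.

What the generator does *not* emulate: luminance-driven trace shape beyond
the stylized light response, autocorrelated (pink) pupil noise, slow
drift/fatigue, gaze-contingent artifacts, or any dependence of RT and trace
shape on the breadth-type manipulation. Passing tests therefore demonstrate
that the *inferential machinery* is correct and calibrated under the
generative assumptions, not that real pupil data satisfy those assumptions.

# Preprocessing

`preprocess_pipeline()` applies the standard pupillometry chain in a fixed
order — blink interpolation, 10× downsampling by block means, arbitrary-unit
to millimetre conversion, baseline correction, baseline-outlier flagging —
and refuses to re-run a step: a processing-stage marker travels with the
samples table (and survives CSV round trips as a header comment).

* **Blinks** are flagged samples or zero/missing runs of at least 20 ms,
  extended by a 50-ms margin on both sides, and replaced by linear
  interpolation between the flanking valid samples (nearest value at the
  edges). A fully blinked trial is marked missing rather than invented.
* **Downsampling** averages each block of 10 consecutive samples (1000 Hz →
  100 Hz), the noise-reducing convention of this workflow; a trailing
  partial block is dropped.
* **mm conversion** is the affine map `mm = a·au + b`. The published
  recorder-specific formula is not printed, so the coefficients are
  configuration values; for synthetic data they invert the generator's
  scaling.
* **Baseline correction** subtracts each trial's mean pupil size over the
  half-open window \[0, 50) ms after cue onset and stores the baseline in
  the trial table.
* **Outlier flagging** z-scores baselines within participant and excludes
  trials beyond ±2 z (≈4.55% under normality); trials with missing
  baselines are excluded as `missing`. Within-participant z-scoring is the
  conservative scoping choice, as the published description does not state
  the normalization scope; participants with fewer than 3 analyzable trials
  are left unflagged with a warning. On default synthetic data total
  exclusions land in the 3–10% band around the ~6% reported in comparable
  data.

# Time-window inference

The dependent variable of every pupil model is the per-trial mean
baseline-corrected pupil size over a time window; the fixed effect of
interest is the ordinal cue-eccentricity code, so a single slope (mm per
ordinal unit) captures the breadth effect. `fit_window_lme()` fits
by-participant random intercepts and, by default, random eccentricity
slopes (lme4, REML); if the slopes model genuinely fails to converge — after
an optimizer restart from the incumbent estimates, which clears lme4's
frequent false-positive gradient warnings on large, nearly singular fits —
it is downgraded to intercepts only and the downgrade is recorded. Fixed
effects are tested with two-sided Wald tests on the normal scale
(`p = 2·pnorm(−|t|)`), the convention of the mixed-model software this
workflow descends from.

`crossval_select_window()` localizes the effect inside a predetermined
750–3000 ms search range without circular inference. Participants are split
into four seed-deterministic folds. For each fold, the other three folds
yield a per-bin |t| profile of the eccentricity effect (intercepts-only LMEs
per 10-ms bin — screening only ranks bins, so the cheap random structure
suffices; the fitted structure is reused across bins via `refit`), and the
training peak bin is recorded (ties break toward the earlier bin) together
with the held-out fold's own t at that bin. The confirmatory full-data LME
(full random structure) pools, for each fold's participants, window means
over the 100-ms window centred on *their training folds'* peak: no
observation's analysis window was chosen using that observation. This
matters quantitatively: in null simulations, confirming on the full data at
a single window selected from all fold peaks rejects at roughly 9% instead
of 5%, because the full data share three quarters of each training set;
with per-fold windows the measured rate is statistically compatible with
the nominal 5%. A single descriptive `selected_window` — the 100-ms window
centred on the mean of the four peaks, snapped to the bin grid and clipped
to the search range — is still reported and used for the follow-up
analyses, mirroring how a single consensus window is reported in this
literature. The 100-ms width matches the reported selection; the window
snapping and clipping rules are fixed here so results are well defined.

Follow-ups: `fit_interaction_lme()` adds breadth type (size condition as
reference, random intercepts only, as the richer model does not converge in
the emulated analysis) and its interaction with eccentricity;
`per_participant_effect()` computes each participant's Pearson correlation
between eccentricity codes and window means (r = 0 with a degenerate flag
when variance vanishes), the basis for individual-differences displays.

# Behavioral inference and exclusion

`accuracy_validity_model()` is a binomial mixed logistic regression of
accuracy on cue validity (invalid as reference; random intercepts and
validity slopes) — the published analysis reports a z statistic, which is
the Wald statistic of exactly this logistic model, so a logistic link is
used despite the "LMM" label. `rt_model()` regresses RT on the eccentricity
code with random intercepts and slopes; under the staircase design its fixed
effect should be null.

`bf01_rm_anova()` is the staircase-efficacy check: per-participant mean
accuracy on validly cued trials per eccentricity enters a one-factor
repeated-measures Bayes factor with Zellner–Siow (JZS) defaults — Cauchy
priors of scale 0.5 on the condition effects and 1 on the participant block,
both projected onto orthonormal sum-to-zero contrasts. In a balanced design
the two blocks are orthogonal, so after two eigendecompositions each
marginal-likelihood evaluation is closed-form and the two g parameters are
integrated on a log-scale trapezoid grid (101 points over log g ∈ \[−15,
15\]); the quadrature is validated in the tests against an independent
Monte-Carlo estimate of the same integrals using the naive full-covariance
formula. BF01 > 3 is read as substantial evidence that the staircases
equated accuracy. Exact agreement with other default-prior implementations
is not promised — only the >3 / ≤3 classification on clear cases, which is
how the criterion is used. A BIC-approximation fallback (`bf01_bic()`) covers
unbalanced input; the method actually used is always recorded.

`performance_deviance()` scores how much a participant's accuracy differs
across eccentricities: the sum of absolute deviations of the three
per-eccentricity accuracies from their unweighted mean. The published
formula prints the near term twice and omits far — an evident typo, since
the quantity is meant to measure deviation across all three eccentricities;
the symmetric formula is the default and the printed variant is available
behind `printed_formula = TRUE`. `iterative_exclusion()` drops participants
in decreasing deviance order (ties by id), recomputing BF01 until it
exceeds 3 or the cohort is exhausted (an explicit failure status), logging
when the cohort falls below the target sample size.

# Orchestration and numerical choices

`run_pipeline()` executes simulate → preprocess → analyze-pupil →
analyze-behavior from a single YAML-backed configuration
(`default_config()`, `read_config()`); unknown keys are errors at every
level so typos cannot silently fall back to defaults. The behavioral stage
depends only on preprocessing, so it still runs when the pupil analysis is
refused (e.g. too few participants for four folds). Identical configurations
produce byte-identical result files. A thin command-line wrapper over these
functions ships in `inst/cli/pupilbreadth.R`.

Degenerate inputs are handled explicitly: unknown variants and missing mm
coefficients are refused with messages naming the valid options; cohorts
below two participants (models) or eight participants (cross-validation)
are refused; single-validity participants and incomplete Bayes-factor cells
are dropped with warnings; zero-variance effect sizes are flagged rather
than propagated as NaN.

# Problem sizes used in the validation suite

The test suite validates the statistics at sizes chosen to make Monte-Carlo
error small relative to each check: staircase convergence uses 5,000–5,500
trials with a 500-trial burn-in; slope recovery uses 20 replicates of
full-study-scale cohorts (100 participants × 240 experimental trials) generated
directly at 100 Hz — the post-downsampling rate — with traces run to
2700 ms, since the analysis consumes nothing later; type-I calibration uses
200 reduced-scale replicates (10 participants, 25 Hz, 100-ms bins over
750–2600 ms). Criteria on these simulations are binomial-band checks at the
stated replicate counts.

# Known limitations

* The Wald/normal p-values ignore the finite number of participants; with
  very small cohorts and large between-participant slope variance they are
  anticonservative (the type-I simulations use a zero-variance null
  precisely to isolate the selection machinery).
* The generator's white measurement noise makes neighbouring 10-ms bins
  independent; real pupil noise is strongly autocorrelated, which would
  smooth the selection profiles but not change the leakage logic.
* The au→mm conversion is an affine stand-in for the unpublished
  recorder-specific formula; absolute mm values are therefore only as good
  as the configured coefficients.
* The JZS Bayes factor requires balanced complete cells; with the designs
  generated here that is guaranteed, and other data fall back to the BIC
  approximation.
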
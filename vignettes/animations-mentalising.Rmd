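---
title: "Bi-directional mentalising in the animations task: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-directional mentalising in the animations task: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In the animations (moving-triangles) task, participants first *generate*
short animations of two triangles depicting a word — three mental-state
words (arguing, surprising, teasing), in which one agent intends to act on
the other's mental state, and three non-mental-state words (following,
searching, dancing) — and later *observe and rate* animations generated by
their fellow participants. Because every participant is both a generator
and an observer, the design can ask a question that one-sided designs
cannot: is mentalising difficulty between autistic and non-autistic people
a one-way deficit, or a bi-directional mismatch between neurotypes (the
"double empathy" question)? Crossing the design over two cultures (UK and
Japan) additionally asks whether any such mismatch is culturally
invariant, and whether kinematic similarity between observer and
generator — how close the observer's own movement style is to the
movements in the animation — carries part of the effect.

`animent` implements this entire analysis as a tested pipeline:

1. a synthetic-study generator with the crossed 2 (culture) x 2 (group)
   generator/observer design, 60 Hz two-triangle trajectories, balanced
   144-animation rating sessions and a controllable generative model for
   ratings;
2. kinematic feature extraction (mean jerk, word-matched observer-animation
   jerk differences, per-cell jerk variability);
3. the trial accuracy statistic;
4. a declarative catalogue of seventeen Bayesian crossed random-effects
   models with posterior summaries, Savage-Dickey density ratios,
   PSIS-LOO model comparison and posterior cell-mean contrasts.

## The accuracy statistic

After each animation, an observer rates all six words on 0–100
visual-analogue scales. Trial accuracy is

$$A = r_{\text{target}} - \tfrac{1}{5}\sum_{w \ne \text{target}} r_w
\in [-100, 100],$$

positive when the intended word is discriminated from the five
distractors. The statistic is applied to raw ratings — no per-trial
re-normalisation and no winsorising — because anything beyond the formula
would be invention. Adding a constant to all six ratings leaves it
unchanged, which the tests assert.

## Movement kinematics

**Mean jerk.** Jerk is the third time derivative of position. Positions
are differentiated by repeated central differences (each pass drops one
sample at each end, so an order-3 derivative loses six samples per
triangle). The per-sample jerk magnitude is the Euclidean norm of the
(x, y) jerk vector; magnitudes are averaged over interior samples and then
over the two triangles, giving one non-negative intensity per animation.
Magnitudes rather than signed components are used because a signed mean
would cancel to zero for any oscillatory movement and could not serve as a
smoothness index. An optional second-order Butterworth low-pass filter
(zero-phase, default cutoff 10 Hz when enabled) can be applied to position
before differentiating, since third derivatives amplify high-frequency
noise; it is off by default and off in all tests, so the finite-difference
oracles (zero jerk for sub-cubic polynomials, jerk 6 for $x(t) = t^3$) are
exact to truncation error.

**Jerk difference.** For every rated trial, the observer's own mean jerk
for the target word (from the animation they themselves generated for that
word) is compared with the rated animation's mean jerk:
$\Delta J = |J_{\text{own}} - J_{\text{animation}}|$, an inverse index of
observer–agent movement similarity. $\Delta J$ is z-standardised *within
the dataset entering each model* (e.g. within the UK-only subset for a
UK-only model), because standardising on the full table and then filtering
would leave a covariate that is neither centred nor unit-scaled in the
data the sampler actually sees; the transform parameters are retained on
the design object.

**Jerk variability.** The coefficient of variation (sample SD / mean) of
generators' mean-jerk values within each culture x group cell, per word —
six CV values per cell, modelled with a random intercept for word.

## The synthetic-study generator

The generator's defaults are the study conditions the analysis targets:
15 participants per culture x group cell, six words (three per condition),
sessions of exactly 144 rated animations per observer (6 per word x
generator group x generator culture), trajectories sampled at 60 Hz, and
observers never rating their own animations.

**Trajectories** are chains of minimum-jerk submovements: within each
segment the position follows the quintic profile
$10\tau^3 - 15\tau^4 + 6\tau^5$, the classic smoothness-optimal primitive
of human point-to-point movement. Jerk intensity is controlled by how many
submovements are packed into a fixed duration (peak jerk of a segment
scales as amplitude/T³), which gives a monotone, easily testable handle on
per-generator jerk level. Default animations last 8 s with around 12
submovements per triangle and amplitude SD 0.15 screen units — values
chosen once as plausible for finger-drawn tablet animations; the real
instrument's pixel geometry is abstracted to the unit square, since the
analysis is invariant to it (mean jerk scales linearly with spatial scale,
and all group comparisons are within one simulated instrument).

**Between-generator jerk variability** is controlled per cell: a
generator's personal submovement count is
$\text{round}(\bar n \cdot e^{\epsilon})$, $\epsilon \sim N(0, d_c)$ with
cell dispersion $d_c$. The default dispersions (0.25 everywhere, 0.4 for
the UK-autistic cell) reproduce the qualitative condition the analysis is
designed to detect — elevated inter-subject jerk variability among UK
autistic generators only — at a realistic magnitude: cell-average CVs of
roughly 0.6 with an elevation of roughly +0.4 in the UK-autistic cell.
Because jerk responds super-linearly to submovement count, dispersion on
the count scale is deliberately smaller than the target dispersion on the
jerk scale.

**Ratings** are built from a latent trial accuracy

$$A = \beta_0 + \beta_{\text{gen}}\,[\text{gen = aut}]
 + \beta_{\text{obs}}\,[\text{obs = aut}]
 + \beta_{\text{int}}\,[\text{both}]
 + \beta_{\text{cond}}\,[\text{non-mental}]
 + \beta_{\Delta J}\, z(\Delta J)
 + u_{\text{obs}} + u_{\text{anim}}
 + s_{\text{obs}}[\text{gen = aut}] + \varepsilon,$$

with independent Gaussian random effects and residual. The six ratings are
then constructed so the accuracy statistic recovers $A$ exactly before
clipping: the target word gets $50 + A/2$ and every non-target $50 - A/2$.
This symmetric construction was chosen over asymmetric alternatives
because it is the simplest scheme for which scoring is an exact inverse of
generation in the noise-free case — the property the scoring tests rely
on. Clipping to [0, 100] only bites when $|A| > 100$ (rare at the default
effect sizes), and those trials are exactly the ones excluded from the
exactness test.

Default effect sizes ($\beta_0 = 20$, $\beta_{\text{gen}} = -8$,
$\beta_{\text{obs}} = -3$, $\beta_{\text{int}} = 3$,
$\beta_{\text{cond}} = -5$, $\beta_{\Delta J} = -2$; SDs 8 (subject), 6
(animation), 3 (subject slope), 15 (residual)) are of the magnitude the
analysis is designed to detect: a clear own-group advantage of
non-autistic observers for non-autistic-generated animations and a
negative movement-dissimilarity slope, against realistic trial-level
noise.

Each pipeline phase (design, trajectories, sessions, ratings) draws from
its own RNG stream derived deterministically from the study seed, so a
stage can be re-run in isolation and identical seeds yield byte-identical
studies.

**What the generator does not emulate.** Semantic content of animations
(words differ only in labels, not kinematics, unless word-level profiles
are supplied), touchscreen digitisation artefacts, session order effects
(ordering is treated as irrelevant to all statistics, consistent with
pseudo-random selection), and rating-scale behaviours such as anchoring or
digit preference. Passing tests therefore demonstrate that the *analysis
machinery* is correct and calibrated under the assumed generative
structure — not that real data satisfy that structure.

## The model catalogue

Seventeen models are declared, named for the sample they address:

- **UK.1–UK.5 / JP.1–JP.5** (within-culture, both observer and generator
  of that culture): accuracy regressed on dummy-coded generator group and
  observer group (reference: non-autistic), mental-state trials only
  (x.1) or with the dummy-coded condition factor (x.2, reference: mental);
  and on the z-scored jerk difference with condition (x.3), plus observer
  group (x.4) or generator group (x.5).
- **JPUK.1–JPUK.3** (cross-culture accuracy models): jerk difference x
  condition x observer culture (JPUK.1), plus observer group (JPUK.2); and
  condition x observer culture x generator culture within autistic
  observers and generators only (JPUK.3).
- **JPUK.4–JPUK.6** (mean-jerk models): per-animation mean jerk
  (z-standardised, so effects are unit-free) on generator group, plus the
  word factor under a deviation contrast (each word against the grand
  mean), plus culture.
- **JPUK.7** (jerk variability): the per-cell-per-word CV on group x
  culture with a random intercept for word.

Group-comparison accuracy models carry random intercepts and random
slopes by both subject and animation; jerk-difference models carry random
intercepts for subject and animation with slopes varying by subject only.
"Slopes for each predictor term" is ambiguous for interaction terms, so
the catalogue defaults to slopes for main-effect terms with a `slopes =
"full"` switch; slope terms that are constant within a grouping factor's
data are retained (they are weakly identified and prior-dominated rather
than harmful, and dropping them silently would misreport the declared
structure).

## Priors, sampling and reporting

Priors are zero-centred normals on the intercept and coefficients and
half-Cauchy on every SD (random-effect and residual). Defaults on the
accuracy scale are normal(0, 10) for coefficients, normal(0, 50) for the
intercept — a scale-10 prior on the intercept would be informative against
cell means near 30–40, which defeats the purpose of a weakly informative
choice — and half-Cauchy(0, 5) for SDs; unit-scale responses (z jerk, CV)
use scale 2.5 throughout. One exception is informative by design: the
jerk-difference slope prior is centred on the negative
movement-similarity effect established in earlier work with this task,
normal(mean = −2.5, sd = 1.5) score units per SD by default. Both numbers
are configuration parameters recorded on every fit, not estimates.

Random intercepts and slopes within a grouping factor are modelled as
independent Gaussians. Modelling their correlations (the default of
formula-interface fitters) was considered and set aside: the available
sampler has no prior family that combines a correlation structure with
the stated half-Cauchy margins, and a scaled-Wishart replacement would
silently change the prior the analysis declares. Independence is the
conservative reading; with the catalogue's balanced designs the fixed
effects it reports are insensitive to this choice.

Models are sampled with Gibbs-type MCMC (JAGS), by protocol four chains
of 4000 iterations with 1000 warm-up; chain seeds derive from the
settings seed, so refits are bit-identical. Convergence is gated on
split-chain Rhat (threshold 1.01) for every monitored parameter; any
exceedance raises a warning that propagates into the report, never a
silent discard. Divergent transitions are a Hamiltonian-sampler
diagnostic and do not exist for this sampler; the diagnostic slot reports
`NA` rather than a fabricated zero. Reduced settings used by the analysis
drivers and the test suite (2 chains x 2000–2500 iterations; studies of
4–8 participants per cell for fitting) are the package's own desk-scale
choices — summaries at those sizes are noisier but the quantities checked
(coverage, oracle agreement, sign patterns) are calibrated for them.

Reported per term: the posterior mean Eμ, the equal-tailed 95% credible
interval (2.5%/97.5% quantiles of the pooled post-warmup draws — chosen
over HPD intervals to match standard mixed-model reporting), and the
directional posterior probabilities P(Eμ < 0), P(Eμ > 0).

**Contrasts.** Post-hoc contrasts are linear combinations of fixed-effect
cell means evaluated draw by draw: a cell is a named set of factor
levels, unmentioned factors are averaged with equal cell weights, and
continuous covariates are held at 0 on the z scale (the dataset mean) —
the conventional reference-grid defaults. The contrast machinery is
validated against brute-force per-draw computation from the coefficient
draws.

**Savage-Dickey.** Evidence for point nulls is the ratio of posterior to
prior density at zero. The posterior density is a Gaussian kernel
estimate (Silverman bandwidth) over pooled draws; the tests establish the
estimator is accurate within 10% when the null lies within about two
posterior SDs of the posterior mean, which is exactly the regime where a
density ratio is informative. When the posterior has essentially no mass
at zero the ratio is reported at a floor of 1e-4 and flagged rather than
extrapolated — a kernel estimate five SDs into a tail is noise, and a
flagged floor is more honest than a fabricated small number.

**LOO.** Model comparison uses Pareto-smoothed importance-sampling LOO
implemented in-package: per observation, importance ratios
$1/p(y_i \mid \theta_s)$ have their largest 20% tail replaced by expected
order statistics of a generalised Pareto fit (Zhang–Stephens profile
posterior), truncated at the raw maximum. Pointwise elpds, their total
and SE, pairwise differences with SEs, and the Pareto-k diagnostics are
reported. The implementation is validated against exact brute-force
leave-one-out refits (n = 30), agreement within 2 SE, and by its
preference for a model containing a real covariate effect in 9 of 10
seeded replicates.

## Numerical and degenerate-input choices

- Differentiation requires at least `order + 2` samples per triangle and
  uniform spacing within 1e-6 relative tolerance; violations are errors,
  not warnings.
- CV computation refuses cells with fewer than two generators or
  non-positive mean jerk.
- Session assembly fails eagerly, naming the word x generator-cell pool
  that cannot supply enough animations (an observer's own animations are
  excluded from their pools, so each pool needs at least
  `animations_per_cell + 1` generators when the observer belongs to it).
- Fixed seeds everywhere: study phases, chain initialisation, replicate
  batches. All reported quantities are pure functions of the stored
  draws; re-summarising reproduces reports bit-identically.

## Parameter recovery and calibration

`recovery_experiment()` repeatedly simulates a reduced study (default 8
participants per cell), refits the mental-state generator x observer
group model whose structure mirrors the generative model, and records CrI
coverage and bias. Under the default conditions with an injected
generator-group effect of −8, 95% CrIs cover the true value at a rate
consistent with nominal coverage (18–20 of 20 seeded replicates in the
acceptance runs) and the mean posterior mean lands within about half a
score unit of −8.

## Known limitations

- The within-culture models interpret "UK data" / "Japanese data" as
  observer *and* generator of that culture; sessions always contain
  cross-culture animations, which only the JPUK models use.
- Jerk-response models are fit to z-standardised mean jerk; effects are
  unit-free and not directly comparable to analyses on raw jerk units.
- The real-data ingestion path is mapping-driven and validated on
  synthetic stand-ins; deposited files' layouts must be described in a
  mapping config at ingestion time.
- KDE-based Savage-Dickey ratios are only trustworthy when the null is
  not far in the posterior tail (the flagged floor marks the rest).
- The independent-random-effects structure and the main-effect-slope
  default are documented deviations from fuller structures a
  formula-interface fitter would build; both are switchable where
  identifiable.
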
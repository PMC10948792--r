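---
title: "Modeling cue integration in emotion inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cue integration in emotion inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emocue)
```

## The inference problem

When we judge what another person feels, two broad sources of information
are available: the *situation* the person is in and their *facial
expression*. A long-standing question in affective science is whether
perceivers combine these cues, and if so, how. `emocue` implements the
standard computational treatment of this question: perceivers are assumed to
hold a causal lay theory in which situational outcomes cause emotions and
emotions cause expressions. Under that directed acyclic graph the two cues
are conditionally independent given the emotion, and a Bayesian observer's
posterior over emotion categories $e$ given situation $s$ and face $f$ is

$$
P(e \mid s, f) \;\propto\; \frac{P(e \mid s)\, P(e \mid f)}{P(e)},
$$

renormalized over categories within each stimulus. Three candidate accounts
of joint-cue judgments are compared: **Situation-only** ($P(e\mid s)$),
**Face-only** ($P(e\mid f)$), and **Bayesian cue integration** (the formula
above). A **flat-prior** variant replaces $P(e)$ with the uniform
distribution to ask whether measured priors carry information.

## From ratings to probabilities

The raw data are presence/intensity Likert ratings: for each stimulus and
each of 13 emotion categories (amusement, anger, awe, contempt, disgust,
embarrassment, fear, happiness, interest, pride, sadness, shame, surprise) a
rater answers yes/no and, if yes, rates intensity *slightly* --
*intensely*. `encode_rating()` maps this to a 0--4 ordinal score with
absence coded 0.

The conversion of ratings to probabilities rests on a probability-matching
assumption: across raters, the distribution of intensity mass over
categories tracks the subjective probability of each category.
`condition_probability_table()` therefore averages the 0--4 scores across
raters per (stimulus, emotion) cell and divides each stimulus row by its
sum. Two conventions here are genuine design choices rather than forced
moves:

* **Absence enters the mean as 0.** The alternative (averaging over
  present-only trials) would decouple the cell mean from how *often* a
  category is perceived; zero-coding makes the mean a frequency-weighted
  intensity, which is what the probability-matching rationale needs.
* **Missing cells contribute no rater** (mean over available raters), and
  are never imputed.

A stimulus row whose raters judged every category absent has no defined
distribution; it falls back to the uniform row and is flagged in
`degenerate_rows()` so downstream correlations stay defined while the
anomaly remains auditable.

Priors come from a separate task in which each participant rates, on a
1--7 scale, how likely they are to perceive each category in everyday life.
`prior_vector()` averages per category and normalizes. A floor
($\varepsilon = 10^{-6}$) keeps every entry strictly positive so the
division in the integration rule is always defined; on the 1--7 scale true
zeros cannot arise from data, so the floor only guards synthetic or
truncated inputs.

### Data cleaning

The rating platform could not undo an intensity rating, so raters were
instructed to mark *slight* intensity for an accidental rating of an absent
emotion. `infer_quality()` encodes this: absent + intensity 1 is
*accidental* (corrected to absent), absent + intensity above 1 is
*incorrect* (dropped trial-wise), and missing responses are dropped and
counted. `exclude_participants()` removes participants whose fraction of
accidental + incorrect + missing trials *strictly* exceeds 10%; a
participant at exactly 10% is retained (the rule is "more than 10%").

## Scoring models

`fit_model()` scores a model table against the empirical joint-cue table
over all stimulus-by-emotion cells (7852 pairs for 604 stimuli; 572 for the
44-stimulus subset): Pearson $r$, RMSE, and 95% percentile bootstrap
intervals obtained by resampling observation pairs (the resampling unit per
the design's "pairs of observations"; whole-stimulus resampling is exposed
as an option). The bootstrap default is $B = 10{,}000$ with a mandatory
seed; percentile rather than BCa intervals are used, the simplest method
consistent with an unqualified "bootstrapped 95% CI".

Two models' fits to the *same* empirical vector are dependent, overlapping
correlations; `dependent_correlation_test()` implements the
Hotelling--Williams statistic. Its conventional degrees of freedom are
$n-3$; the reported `df` follows the $n-2$ convention used when such
comparisons are quoted alongside the correlations themselves, and both are
stored. Per-category contrasts (`per_emotion_bootstrap_difference()`)
bootstrap stimuli within one emotion column and call a difference
significant when the 95% percentile interval of $\Delta r$ excludes zero.

## Individual differences

`participant_probability_table()` is the single-rater analogue of the group
aggregation, and `reliance_estimates()` correlates one participant's
joint-cue table with fixed group-level model tables, yielding face-reliance,
situation-reliance and cue-integration estimates (Fisher-$z$ transformed
for all downstream statistics, clamped at $|r| = 1 - 10^{-7}$ so perfect
fits stay finite). The group-level tables are supplied as fixed inputs, not
re-estimated from the individual-level sample, mirroring the cross-study
design this machinery comes from. `classify_best_model()` takes the argmax
of the three correlations; exact ties resolve by the documented precedence
situation > integration > face, favouring the simpler single-cue account.

Covariate analyses (`covariate_association()`) use two-tailed Pearson
correlations with Bonferroni adjustment (raw $p$ times the family size,
capped at 1); the family size is supplied explicitly by the caller and
echoed in the result. Multivariate outlier screening
(`mahalanobis_outliers()`) uses classical Mahalanobis distances with a
chi-square cutoff at $\alpha = 0.001$; a robust-covariance variant was
considered and left out because the classical method is the stated one and
the robust choice would change flagged sets silently.

Test--retest stability (`icc_consistency()`) uses the two-way,
single-measure, *consistency* intraclass correlation ICC(C,1), whose $F$
statistic has df $(n-1, n-1)$ for two sessions — the form matching the
printed degrees of freedom this statistic is conventionally reported with.
The 95% interval is the F-based interval, which can extend below zero for
weak reliability; absolute-agreement ICC(A,1) is available as an option.

## The synthetic world

Because the archival rating data are not redistributable, the package ships
a generative counterpart of the lay theory so every stage is testable with
known ground truth (`simulate_stimulus_space()`, `simulate_raters()`,
`simulate_retest()`).

* **Stimulus space.** Each stimulus's situation distribution is a Dirichlet
  draw (concentration 0.7: sparse, peaked rows resembling consensus
  stimuli). The face distribution is a mixture of the situation row (weight
  `face_informativeness`, default 0.9) and an independent Dirichlet draw, so
  faces mostly echo the situation plus an independent component. The prior
  is one global Dirichlet draw. Defaults are sized to the
  individual-difference design: 44 stimuli, 13 categories.
* **Raters.** A rater's joint-cue target is the situation row, the face
  row, or their Bayesian combination depending on `rater_type`. Integrators
  additionally take an `integration_weight` $g$: the target is
  $\propto P(e\mid s)\,(P(e\mid f)/P(e))^{g}$, so $g = 1$ is full Bayesian
  integration and $g = 0$ collapses to situation reliance. Expected
  intensity is $4 \times$ the target probability, perturbed by truncated
  Gaussian noise on the 0--4 scale and rounded to the grid (presence =
  intensity > 0). A multinomial probability-matching mode (the 4-point
  intensity budget allocated by a multinomial draw) is provided as an
  alternative noise process; the response-noise process is a modeling
  decision, not an empirical fact.
* **Study conditions.** `simulate_study()` draws independent cohorts of 40
  raters per condition (roughly the per-stimulus rating depth of the
  archival design). Situation descriptions are rated cleanly (noise SD
  0.5); facial portrayals are ambiguous and rated noisily (1.25); the joint
  condition, where two cues must be reconciled, is noisiest (1.75), and its
  default raters are conservative partial integrators ($g = 0.5$). These
  values were fixed once, from the package's own oracle calibration runs,
  to place the synthetic world in the empirically observed regime: the
  situation-only and integration accounts fit group data about equally
  well (Williams $t \approx 1$ at 572 pairs) while face-only falls clearly
  behind, and the recovered ordering of fit correlations
  ($\approx 0.80 / 0.79 / 0.67$) matches the published ordering of the
  three accounts.
* **Category boost.** `category_boost` adds an independent, high-variance
  Gamma component to one category's face values — a category whose facial
  expressions carry information perceivers actually use (the happiness
  analogue). Demonstrating its per-category consequence needs the power of
  the full 604-stimulus scale at which per-category contrasts are run.
* **Retest.** `simulate_retest()` draws a heterogeneous cohort (type mix
  0.55 situation / 0.2 face / 0.25 integrator, echoing observed best-model
  shares; per-rater noise uniform on 0.3--1.2 and reliance weight on
  0.6--1) and blends session-2 parameters with fresh draws by `stability`;
  at stability 1 the session-1 response seeds are reused, so session 2
  reproduces session 1 exactly and the ICC is 1 by construction.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes — peaked
consensus distributions, partially informative faces, heterogeneous rater
strategies, ordinal discretization, correlated sessions. It does not model
stimulus content, actor behaviour, facial action units, per-category
differences in rater reliability, or any dependence of the prior on the
stimulus set. Tests passing on this world show the *machinery* recovers
known structure; they do not certify conclusions about real raters.

### Identifiability and the recovery world

Parameter-recovery tests use `face_informativeness = 0.5` rather than the
default 0.9. At 0.9 the face and situation tables correlate at about 0.99,
so face-reliant and situation-reliant raters produce nearly identical
ratings and no classifier could separate them — the types are unidentifiable
in principle, not merely hard to estimate. Recovery claims are only
meaningful in a world where the cues genuinely differ.

## Numerical choices

* Probability rows are validated to sum to 1 within $10^{-9}$; degenerate
  rows fall back to uniform and are flagged, never silently repaired.
* Bootstrap replicates with degenerate variance are redrawn and counted
  (`n_redrawn`) rather than propagating `NA`.
* Fisher-$z$ clamps at $|r| = 1 - 10^{-7}$; the ICC returns exactly 1 with
  a degenerate $F$ when the within-rater mean square is numerically zero.
* All simulation entry points require an explicit seed; nothing is seeded
  silently.
* Bootstrap index matrices are generated in chunks of 500 replicates so
  memory stays flat at large $n \times B$.

## Known limitations

* The Williams test at hundreds of pairs is sensitive enough to detect the
  small, world-specific differences between the situation-only and
  integration accounts that any *fixed* generative configuration produces;
  across repeated synthetic worlds the two accounts are statistically
  indistinguishable in roughly 70% of runs under the default conditions,
  not in all of them. This mirrors the empirical situation: at the full
  archival scale the situation-only account fit *significantly* (if
  slightly) better, and indistinguishability appears at the 572-pair
  scale.
* RMSE orderings in the synthetic world need not match correlation
  orderings: heavy response noise flattens estimated tables, which can
  lower a poorly correlated model's absolute error. Correlation is the
  primary fit metric here.
* The package compares correlations and RMSE only; no likelihood-based
  model selection (AIC/BIC, hierarchical Bayes) is attempted, and no
  alternative causal graphs (e.g., a direct situation-to-expression link)
  are implemented.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
group comparisons at 44 stimuli x 13 categories x 40 raters per condition
(with the per-category boost demonstration at 604 stimuli), recovery at 90
raters per run, bootstrap coverage at 500 replicates of $n = 200$ with
$B = 1000$, and retest reliability at 110--200 raters. These sizes were
chosen to estimate each quantity stably while keeping a full run fast on a
single CPU.
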
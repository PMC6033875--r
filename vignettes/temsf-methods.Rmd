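---
title: "Models and methods behind temsf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind temsf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, estimators, and design choices in
`temsf`: what the synthetic observer generates, how each analysis stage
estimates its quantities, which knobs matter, and where the genuinely open
decisions were made.

## The task and the data model

Each trial is a sequence of 11 brief events (100 ms stimulus, 100 ms gap)
containing exactly one target, at sequence position 3 (onset 400 ms) or 9
(1600 ms). The observer judges whether the target's frequency is higher or
lower than the distractors — a 2AFC discrimination. Temporal expectation
(TE) is manipulated block-wise: "expect early" blocks draw early targets
with probability 0.86, "expect late" blocks with probability 0.43. Three
target modalities (A, V, AV) appear equally often (56 trials each per
168-trial block; six main blocks, 1008 main trials). Two between-subject
factors span four experiments: spatial uncertainty (sounds co-located with
the display vs over headphones) and target uncertainty (whether the
sequence modality predicts the target modality). Trial records are tidy
rows: subject, design labels, target, response, RT, correctness.

## The generative observer

`simulate_cohort()` drives an equal-variance Gaussian signal-detection
observer. For a trial with internal sensitivity $\delta$, evidence is
$e \sim \mathcal N(s\,\delta/2,\,1)$ with $s=+1$ for "higher" targets and
$-1$ for "lower"; the response is "higher" iff $e > c$ (criterion $c$),
replaced by a fair coin flip with probability `lapse_rate`. The yes/no
sensitivity of this model is exactly $\delta$, so the analysis-side 2AFC
estimator $(z(H)-z(F))/\sqrt2$ converges to $\delta/\sqrt2$ — a property
the test suite checks at 10,000 trials per cell (tolerance 0.05).

Condition sensitivity composes additively, floored at zero:

$$\delta = \mathrm{base}(mod) + g_{TE}\,[expected]
 - p_{uni}\, n_{high}\,[mod \ne AV]
 + [mod = AV]\big(g_{AV} + g_{unc}\, n_{high}
 + s_{pref}\,|\delta_A-\delta_V| + g_{seq}\,[prev.\ TP\ match]\big)$$

with $\mathrm{base}(AV) = (\delta_A+\delta_V)/2$ and $n_{high}$ the number
of high-uncertainty factors. The terms mirror the phenomena the analyses
are meant to detect: a TE benefit; an AV benefit that grows under
uncertainty while unisensory sensitivity degrades; an AV benefit that
*shrinks* as one modality dominates ($s_{pref}<0$); and a phasic AV boost
when the previous trial's target position matches. Real studies of this
paradigm analyse human observers, who come with no known generative
model — the additive form here is this package's own synthetic stand-in,
chosen for transparency (every injected effect has one parameter, and the
null observer with all gains zero makes every cell equal, which the
type-I tests exploit).

Population defaults (`sample_observers()`) were set once from the group
means the analysis stack should reproduce at study scale: a TE gain of
0.26 on the $\delta$ scale ($\approx 0.18$ in d′, matching expected vs
unexpected group d′ of roughly 1.27 vs 1.09), an AV gain of 0.17
($\approx 0.12$ in d′), a unisensory uncertainty penalty of 0.25 per high
factor, preference spread 0.35, slope $s_{pref} = -0.5$, sequential gain
0.3, and shifted-lognormal RTs (shift 600 ms, $\mu=\log 1000$,
$\sigma=0.4$) with mean reductions of 111 ms for expected and 59 ms for AV
targets, matching group mean RTs near 1524/1635 ms. These are configuration
defaults, not ground truth; every recovery test samples fresh observers
around them.

Response times do not depend on $\delta$ (mean shifts only); accordingly
the RT side of the analyses is exercised structurally (sign conventions,
LOOCV machinery) but carries no injected perceptual effect beyond the two
mean shifts. Omitted responses are off by default (`miss_rate = 0`); the
data being emulated report no omission rate.

### Threshold calibration

The experiment calibrates each modality's target frequency to 75% accuracy
before the main blocks, with equal early/late targets and no TE
manipulation. `calibrate_threshold()` emulates this with a 72-trial
weighted up–down staircase per modality (step $1.2/t^{0.45}$, start at the
closed-form unbiased threshold $2\Phi^{-1}(0.75) \approx 1.349$). The
readout averages two standard estimators whose finite-run biases have
opposite sign: the post-burn-in staircase mean (last 60% of the track) and
a one-parameter probit maximum-likelihood fit to the staircase history. A
200–400-trial internal validation batch aborts with a calibration error
when the result is grossly off target (deviation above 0.22, e.g. an
observer whose response bias puts 75% out of reach), while leaving room
for ordinary staircase noise (SD of a single 72-trial staircase is about
0.3 in $\delta$, i.e. about 0.05 in accuracy).

The subject's signed modality preference is applied *after* calibration
(half added to A, half subtracted from V). This emulates the situation the
calibrated experiment still produced: both modalities start at 75%, but
attention allocation in the main session re-introduces imbalance. The
calibrated values double as the per-subject "target frequency" covariates,
normalised by their grand mean per modality, so they enter the regression
as unitless values near 1.

### Randomness and reproducibility

A master seed expands into per-subject seeds (drawn once up front), so
identical `(config, master_seed)` yield byte-identical trial tables and
any subject's session can be regenerated in isolation. Target positions
are independent Bernoulli draws with the block-type probability — not
exact quotas, since 86% of 56 is not an integer — so proportion checks are
formulated within binomial standard errors. Block types strictly
alternate; the starting type is counterbalanced by subject-index parity.

## Filtering and n−1 annotation

The analysis keeps early targets only (late targets are always expected by
the time they occur, so they carry no expectation contrast), responses
inside a closed 150–3000 ms window after target onset, and main blocks.
Exclusion reasons are tallied once per row under the fixed precedence
window > position > block > response. The n−1 annotation
(`annotate_previous_trial()`) is computed *before* filtering, within
subject and within block — block breaks change the expectation context, so
sequential relations do not cross them. Whether mean RT uses correct
trials only is not fixed by convention; the default uses all surviving
responses, with a documented `correct_only` switch.

## Scoring and the max-criterion

d′ uses the 2AFC convention $(z(H)-z(F))/\sqrt2$ with a log-linear
correction (add 0.5 to each count, 1 to each denominator) by default;
`1/(2N)` clamping and no correction are selectable. Cells below four
analysed trials are flagged rather than dropped; cells with only one
target direction are unusable for d′ and are dropped.

The best unisensory modality per subject is chosen in at most two steps:
the modality better in *both* expectation cells wins; on split dominance,
the better unweighted mean of the two cells wins. The selection runs
separately for d′ (maximise) and RT (minimise), and may disagree between
measures — that disagreement defines the "mixed" preference label. An
exact tie after step 2 is broken deterministically (more analysed trials,
then A) and flagged; it essentially never occurs on continuous data.

MSF outcomes are signed so that positive always means facilitation:
$d'(AV) - d'(\mathrm{best}[A,V])$ and
$RT(\mathrm{best}[A,V]) - RT(AV)$, evaluated per expectation cell at the
subject-level best modality. The unisensory difference predictor uses the
per-cell spread $\max[A,V]-\min[A,V]$, which is non-negative by
construction even when dominance is split across cells.

## The mixed ANOVA

`mixed_anova()` performs a direct sum-of-squares decomposition for
balanced designs with crossed within factors and subjects nested in
between cells, via Möbius inclusion–exclusion over marginal cell totals.
This is exact for balanced data, auditable term by term, and reduces to
the paired $t^2$ with one within factor — both properties are asserted
against `aov()` and `t.test()` oracles in the tests. Sphericity is moot:
all within factors have two levels.

Effect sizes: generalized η² divides by the effect SS plus *all*
subject-level error strata (the `ez`-style definition), and η² is reported
in its partial form (the labelling common to mixed-design software
output); the object records `eta2_type = "partial"`. Note a consequence
of the generalized definition: per-subject mean shifts move the subject
stratum and therefore *do* change ges; the quantities genuinely invariant
to such shifts are the within-effect SS, F, and partial η², and those are
what the tests assert.

Post-hoc paired comparisons report Cohen's
$d = \bar{d}/s_d$ and Bonferroni-corrected p (family size = the simple
effects actually compared, default 2 per interaction). For non-significant
results a Jeffreys–Zellner–Siow Bayes factor for the null is attached
(Cauchy prior scale $\sqrt2/2$, one-dimensional quadrature); it is an
approximation to common software defaults and is labelled as such.
Unbalanced between groups are refused by default; `allow_unbalanced`
switches to a flagged unweighted-means (harmonic cell size) analysis,
which the pipeline uses for the history stage when subject drops unbalance
the groups.

## All-subsets LOOCV model comparison

The 8 predictors are: spatial uncertainty, target uncertainty, TE
(coded 1 = unexpected), normalized A and V target frequencies, two
preference indicators (PrefA, PrefV; both 0 for mixed — the only coding
that yields exactly 8 predictors and $2^8-1 = 255$ candidate subsets), and
the measure-matched unisensory difference. The outcome has
$N = 2 \times n_{subjects}$ rows (one per subject × expectation cell; 240
at study scale).

Every non-empty subset is fit by OLS with intercept; leave-one-out
predictions use the exact hat-matrix identity
$\hat e_{(i)} = e_i/(1-h_{ii})$, verified against naive per-fold refits to
1e-8 on random matrices. Models are ranked by LOOCV RMSE; ties (possible
only on degenerate data) break by smaller subset, then canonical mask
order. Spearman correlations between held-out predictions and
observations use average ranks with the t-approximation for p, Bonferroni
over the five reported models (best, physical, individual,
unisensory-performance, full; configurable). For the best model,
per-predictor PRE refits the model with that single predictor removed
(intercept retained) on the full data: PRE is a full-fit quantity, not a
cross-validated one. Rank-deficient subsets (e.g. a preference indicator
constant in a small cohort) raise an error by default;
`on_singular = "drop"` ranks them last with infinite RMSE, which the
pipeline uses so small simulated cohorts degrade gracefully.

## Trial-history analysis

History cells condition the current trial's d′ on the previous trial's
modality match and target-position (TP) match, restricted to trials whose
previous answer was correct (avoiding post-error effects), for the current
modalities AV and best[A,V]. Two decisions the data convention leaves
open: TP match is defined on the physical position (early/late), which
within a block is equivalent to matching expectation status (sequential
relations never cross blocks); and an AV trial at n−1 counts as a modality
*mismatch* for a current unisensory trial (match requires identity). Other
n−1 properties are controlled by marginalising rather than stratifying.
The resulting 2×2×2 within structure feeds the same mixed ANOVA with the
two uncertainty factors between subjects; subjects with any empty cell are
dropped with a message.

## Simulation-study sizes

The stochastic verification suites were sized once, from pilot power
considerations, and are stated here as the package's own simulation-study
design:

* **Directional recovery** (TE main effect significant; best-model
  UniDiff slope negative; AV TP-match advantage exceeding the unisensory
  one): 100 cohorts of 36 subjects (9 per experiment), four 96-trial
  blocks each, full calibration. At these sizes the pilot detection rates
  were ~0.90, ~1.00, and ~0.90 respectively, comfortably above the 0.80 /
  0.95 / 0.80 acceptance rates.
* **Type-I control**: 200 null-observer cohorts (all gains zero; 16
  subjects, two 96-trial blocks, both target positions analysed), with
  per-effect rejection counts required to fall in the central 99%
  binomial band around 5%. One effect is knowingly excepted from a
  nominal rate: the *modality* main effect. Because the max-criterion
  selects best[A,V] from the same noisy data it is then compared on, the
  selected unisensory d′ is inflated by roughly
  $\mathbb E[\max(X_1,X_2)] - \mu = \sigma_{\hat d'}/\sqrt{\pi}$ under the
  null, and the resulting test statistic grows with the number of
  subjects regardless of trials per cell — so no cohort size makes the
  modality effect's null rejection rate 5%. The suite demonstrates the
  attribution directly: with an a-priori (selection-free) comparison
  modality the same ANOVA is nominal. Note the direction of this bias
  favours best[A,V] over AV, i.e. it works *against* detecting
  multisensory facilitation, which makes max-criterion MSF findings
  conservative.
* **Calibration check**: 100 observers × 100 validation trials (10,000
  total), pooled accuracy within three binomial standard errors of 75%.

## What passing tests do and do not show

The generator emulates the design's structure and the direction and rough
size of the population effects, with additive condition sensitivities,
independent trials (beyond the one-trial TP gain), Gaussian evidence, and
lognormal RTs unrelated to accuracy. Real observers drift, fatigue, show
RT–accuracy coupling and richer sequential dependencies. Green tests
therefore certify the *estimators and pipeline* — that the scoring,
selection rule, ANOVA, cross-validated model comparison, and history
conditioning compute what they claim and recover known effects injected
under the stated assumptions — not that any particular empirical finding
about human observers is true.

## Known limitations

* Bias measures (criterion c, β), psychometric-function fits, and
  RT-distribution modelling are out of scope.
* The JZS Bayes factor covers paired contrasts only; no ANOVA-level Bayes
  factors.
* The unweighted-means fallback for unbalanced groups is an approximation
  and is flagged in the fitted object.
* Race-model inequality tests for redundant-target RTs are not included.
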
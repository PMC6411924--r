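---
title: "Models and methods behind metaconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaconf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

metaconf simulates and analyses staircase-controlled two-interval
forced-choice (2IFC) confidence experiments in three sensory modalities —
visual contrast, innocuous warmth and noxious heat — and asks how
metacognition (the evaluation of one's own perceptual decisions) covaries
across them. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic data do and do not establish.

## The type-1 model

Each trial presents a fixed *reference* stimulus and a more intense *test*
stimulus in random order; the observer reports which interval was more
intense and rates confidence on a 1–4 scale. We code the trial as a
two-class signal detection problem: stimulus class S1/S2 is the interval
containing the test, the response R1/R2 is the chosen interval. Under the
equal-variance Gaussian model, with hit rate H = P(R1|S1) and false-alarm
rate F = P(R1|S2),

$$d' = z(H) - z(F), \qquad c = -\tfrac{1}{2}\,(z(H) + z(F)),$$

where $z$ is the standard normal quantile. No $\sqrt{2}$ 2IFC correction is
applied: the downstream quantity of interest, meta-d′/d′, is invariant to
any shared rescaling of the axis, and omitting the correction matches the
convention of the standard meta-d′ estimators. Rates are computed after
adding $1/(2K)$ to every confidence cell ($K = 4$), the usual log-linear
correction that keeps empty cells from producing infinite z-scores.

## The type-2 (meta-d′) model

Confidence is modelled with the Maniscalco–Lau meta-d′ observer: a second,
meta-level observer with sensitivity meta-d′ whose type-1 criterion sits at
the same *relative* position $c' = c/d'$ (the standard identifiability
constraint), and $K-1$ ordered type-2 criteria on each response side.
Conditional on stimulus and response, the confidence distribution is the
truncated-normal mass between consecutive criteria, renormalised within the
response region. meta-d′ is the d′ a signal-detection-ideal observer would
need to produce the observed confidence data; metacognitive efficiency is
the ratio meta-d′/d′ (1 = all first-order evidence reaches the confidence
judgement) or the difference meta-d′ − d′, which avoids ratio blow-up when
d′ is small. Metacognitive bias is simply the mean confidence rating,
irrespective of accuracy.

**Maximum-likelihood fit.** `fit_meta_d_mle()` maximises the multinomial
log-likelihood of confidence counts conditional on (stimulus, response),
with (d′, c) fixed at their observed-rate values. Criterion ordering is
enforced by optimising log-spaced increments away from the meta-level
criterion; the search is bounded L-BFGS-B from meta-d′ = d′ and increments
set from the empirical marginal confidence quantiles, followed by a
Nelder-Mead polish (relative tolerance 1e-12). Degenerate tables (a single
used confidence level) are returned flagged rather than as errors.

**Single-subject Bayesian fit.** `fit_meta_d_bayes()` samples the same
likelihood with JAGS, with a Normal(0, 1) prior on log(meta-d′/d′) and
half-Normal(1) priors on the criterion increments. The log-scale prior keeps
meta-d′ positive and is centred on efficiency 1; it is weakly informative
(95% prior mass for the ratio between 0.14 and 7.1). When the data carry no
type-2 information (e.g. every rating identical), the posterior simply
returns this prior — wide, centred near 1 — which is the correct behaviour
for an uninformative likelihood. Convergence is diagnosed with the
split-chain $\hat{R}$ (flagged above 1.05); defaults are 3 chains with 1000
warm-up and 1000 kept draws.

## The adaptive staircase

First-order difficulty is controlled by a continuous 2-down/1-up staircase:
one step up after every error, one step down after two consecutive correct
responses, with the counter resetting after any intensity change (standard
Levitt semantics; the reset rule is a package choice, as transformed
up-down descriptions usually leave it implicit). The rule equilibrates where
$p^2 = 1/2$, i.e. 70.7% correct. Intensities are stored as integer step
offsets from the start value so long trajectories cannot drift off the step
lattice, and are clamped to the configured caps: the warmth track never
exceeds 43.0 °C (to stay below the noxious range), the heat-pain track never
exceeds 50.0 °C (skin-safety limit), and the lower cap defaults to one step
above the reference so test and reference never coincide. The staircase
defaults (reference/start/step: vision 50%/70%/3% contrast, warmth
38.0/40.0/0.5 °C, pain 45.0/47.0/0.5 °C) reproduce the reference design.

A caveat for convergence diagnostics: the 70.7% figure is an asymptotic
result that assumes steps small relative to the psychometric slope. With
study-scale steps (about a quarter of d′ per step) the skewed stationary
distribution sits slightly above equilibrium, and session accuracy lands
near 71–72%; with a step of a tenth of that, accuracy at the mean converged
intensity is within half a point of 70.7%. The convergence tests therefore
use a fine-step configuration, while session-level checks use the
experiment-scale configurations.

## The synthetic cohort

`simulate_cohort()` is the generative stand-in for the human dataset:
36 subjects × 3 tasks × 180 trials (the first 20 are practice and excluded
from analysis), one staircase-controlled session per subject-task, plus a
20-trial painfulness-rating manipulation check (10 ratings each of the
warmest innocuous and the lowest noxious stimulus).

Per-subject parameters are drawn once per cohort: log-efficiency and
confidence-bias vectors from multivariate normals with configurable 3×3
cross-task correlation matrices, psychometric slopes log-normally and
criteria normally around task defaults. The defaults encode the structure
the analysis is designed to detect: efficiency correlated between vision
and warmth (0.7) but not vision and pain (0), bias positively correlated
across all tasks (0.6–0.8), task-mean efficiencies near 0.9–1.0, and d′
near 1.0–1.3 at the staircase equilibrium. The warmth slope is set low
enough that a minority of simulated subjects reach the 43.0 °C cap, which
reproduces the small warmth accuracy deficit of the reference design. The
manipulation-check ratings use a subject-level noxious-minus-warm gap of
0.59 rating points (between-subject SD 0.5), which also implies that a few
subjects per cohort do not rate noxious above warm — the case the optional
manipulation-check exclusion rule is for.

**Confidence generation.** Trial outcomes are sampled directly from the
type-2 model itself: the response from the type-1 probabilities at the
trial's staircase-controlled d′, and confidence from the meta-level
conditional distribution with meta-d′ = efficiency × d′. An earlier design
added Gaussian noise to a copy of the decision variable and binned that;
it was abandoned because confidence conditioned on a response made from a
*different* variable systematically undershoots the intended efficiency
(a target of 0.7 fitted near 0.5), and no closed-form noise map repairs
this. Sampling from the model makes the calibration exact for any
efficiency — including values above 1, which the reference data contain and
which no additive-noise mechanism can produce — and guarantees the
generator and the fitted likelihood agree cell by cell (verified by
chi-square goodness of fit in the test suite). The cost is that the
generator inherits the model's assumptions rather than stress-testing them.

Confidence bias shifts all cutpoint distances by a subject-specific
constant (floored at a small positive spacing, so extreme bias saturates
the scale rather than inverting it). Reproducibility: subject-level draws
use one stream seeded by the cohort seed, and each session re-seeds with a
documented hash of (seed, subject, task), so datasets are byte-identical
across runs.

## Group inference

**Correlation Bayes factors.** `bf_correlation()` integrates the exact
sampling density of the Pearson coefficient (Fisher's 1915 distribution,
with the hypergeometric term summed as a forward Gauss series in a regime
where it is provably stable) against a stretched beta prior of width
κ (κ = 1 is uniform on (−1, 1)), divided by the density at ρ = 0. One-sided
versions restrict and renormalise the prior. Quadrature is adaptive with
relative tolerance 1e-8, and each result carries its estimated integration
error (reported results require < 1e-3).

**Paired t-test Bayes factors.** `bf_ttest_paired()` computes the JZS Bayes
factor with Cauchy prior scale 0.707 by one-dimensional quadrature over the
g-representation, with the integrand evaluated in log space to avoid
overflow at large t.

**Steiger's Z.** `steiger_overlapping()` compares two dependent correlations
sharing a variable via Fisher z-transforms and the pooled-r̄ covariance
(Steiger 1980) — the variant implemented in the standard comparison
software, which reproduces published statistics from printed two-decimal
correlations to within ±0.05. Two-tailed p-values are reported. Null
calibration (Z standard normal under equal true correlations) is verified
by Monte Carlo in the test suite.

**Hierarchical model.** `fit_hierarchical_efficiency()` places a trivariate
normal on subject-level log(meta-d′/d′) across tasks and feeds each
subject-task's confidence counts through the meta-d′ likelihood (type-1
parameters fixed per subject-task), so single-subject uncertainty
propagates into the posterior of the cross-task correlation matrix. The
covariance prior is a *scaled* inverse Wishart: Wishart(I, 4) on the
precision of unit-scale latent effects (implied marginal prior on each
pairwise correlation uniform on (−1, 1)) with separate half-Normal(1) task
scales and Normal(0, 1) task means. A plain inverse-Wishart prior was tried
first and rejected: at the small between-subject scales typical here
(log-efficiency SD ≈ 0.35) it exhibits its known bias of correlations
toward zero — in one check the posterior mean was 0.14 when the sample
correlation of the generating subject effects was 0.59. JAGS has no LKJ
distribution, and the scaled inverse Wishart is the standard JAGS-native
alternative with essentially the same marginals. A pair is flagged
"significant" when its 95% credible interval excludes zero.

Two properties of this analysis are worth keeping in mind. First,
single-subject point estimates of efficiency from 160 trials are noisy
(SE ≈ 0.3 on the log scale), so *observed* cross-task correlations are
attenuated by roughly 40% relative to the generating ones — a cohort built
with ρ = 0.7 yields point correlations near 0.4. The hierarchical model
widens its intervals accordingly rather than de-attenuating to a sharp
estimate; its posterior intervals cover the generating values, but a
frequentist test on the attenuated point correlations has modest power at
n = 36, so contrasts between correlations are only borderline-detectable at
this scale. Second, the stopping-rule machinery (`sequential_stopping()`)
monitors whatever Bayes factors the caller supplies; the pipeline uses the
three pairwise t-test BFs, since omnibus Bayesian repeated-measures ANOVA
is deliberately out of scope.

## Pipeline and exclusion rules

`run_full_analysis()` chains: exclusions → per-subject measures → pairwise
modality comparisons (paired JZS BFs on all six measures) → cross-task
correlations with positive-sided BFs (d′, meta-d′, efficiency, mean
confidence) → Steiger comparisons among the three efficiency correlations →
the hierarchical model → the manipulation check, and returns everything
with its prior and sampler settings plus the seed (each number is traceable
to configuration). The chance-level rule operationalises "performed at
chance" as a one-sided exact binomial test of analysed accuracy against 0.5
at α = 0.05; failing it in *any* task removes the subject everywhere. The
manipulation-check rule (off by default, as a sensitivity analysis) removes
subjects whose mean noxious rating does not exceed their mean warm rating.
The per-subject fit method defaults to MLE; the single-subject Bayesian
fit is available via `analysis_config(fit_method = "bayes")` and is the
better choice when trial counts are low, at roughly two orders of magnitude
more computation per cohort.

## Problem sizes and numerical tolerances

Simulation-based tests use sizes chosen to keep Monte-Carlo error well
inside the asserted tolerances: 20,000 staircase trials (2,000 burn-in) for
convergence; 10⁴ trials for ideal-observer recovery (±0.05); 120–150
subjects for generator-level correlation recovery; 5,000 replicates for
Steiger null calibration; 20 replicates of 16-subject cohorts for
hierarchical false-positive calibration, with one full 36-subject cohort
for coverage. Grid oracles refine 21-point grids six times (final
resolution below 1e-5); trapezoid oracles for the Bayes factors use
2,000–40,000 nodes after removing the endpoint singularity of the
hypergeometric integrand by substitution.

## Limitations

The generator samples from the same model family the estimators fit, so
recovery tests validate the estimation machinery, not the model's fidelity
to human confidence data; it also omits habituation, sensitisation,
reaction times, sequential dependencies and skin-temperature dynamics.
Response-specific meta-d′ and unequal-variance models are out of scope.
The hierarchical prior is JAGS-native scaled inverse Wishart, not LKJ;
at n = 36 the posterior for cross-task correlations is prior-sensitive in
the tails, which is why recovery is asserted as interval coverage rather
than point accuracy.
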
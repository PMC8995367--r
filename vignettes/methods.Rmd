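---
title: "Models and methods behind metaconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaconf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metaconf` analyses dual-task confidence forced-choice data: per trial, two
contrast discriminations followed by a forced choice of which decision the
observer trusts more. This vignette documents the statistical models, the
generative observer used for simulation, the numerical choices, and the
limits of what the simulations can establish.

## The analysis chain

### Confidence sets

Each trial contributes both decisions to the *unsorted* set and exactly the
decision selected as more confident to the *chosen* set. Confidence is
coded 1 (selected) / 0 (not selected), so the session-wide mean confidence
is 0.5 by construction — only the *allocation* of the codes across
difficulty and accuracy is informative.

### Psychometric model

Proportions of "test higher" reports per signed contrast difference
$\Delta$ (in % contrast) are modelled as

$$p(\Delta) = \frac{\lambda}{2} + (1 - \lambda)\,
  \Phi\!\left(\frac{\Delta - \mu}{\sigma}\right)$$

with equal guess/lapse asymptotes $\lambda/2$, appropriate for a binary
judgement recoded against the standard. $\mu$ is the PSE and $1/\sigma$ the
contrast sensitivity. Parameters maximize the binomial likelihood with a
beta(1.5, 20) penalty on $\lambda$; bounds are $\lambda \in [0, 0.1]$ and
$\sigma \in [0.1, 100]$ % contrast. The penalty regularizes the
lapse/slope trade-off in sessions without asymptotic errors while leaving
well-constrained fits essentially untouched.

Numerical scheme: the objective is optimized in $(\mu, \log\sigma,
\lambda)$ by `nlminb` from a fixed grid of starting values spanning the
stimulus range (3 PSE locations × 3 slope scales × 2 lapse levels); the
grid is screened by objective value and the best four starts are polished.
The procedure is deterministic given the counts, and tests verify it
against an exhaustive dense grid search over the same objective. Degenerate
data are reported, not repaired: responses with no slope information push
$\sigma$ to its upper bound, perfectly separated responses to its lower
bound, and both raise warnings and set a flag. Deviance
$D = 2\sum_j [k_j \ln\frac{k_j}{n_j \hat p_j} + (n_j - k_j)
\ln\frac{n_j - k_j}{n_j (1 - \hat p_j)}]$ (with $0 \ln 0 = 0$) summarizes
goodness of fit; a fitted probability of exactly 0/1 against a discordant
count yields $D = \infty$.

This is a deliberate re-implementation choice: Bayesian psychometric
toolboxes report posterior summaries under explicit priors, whereas here a
penalized maximum-likelihood point estimate keeps the fit deterministic and
dependency-free. For well-behaved data the point estimates agree closely;
for sparse chosen sets the estimates here are somewhat noisier than
posterior means would be (see *Limitations*).

### Confidence Modulation Index

$\mathrm{CMI} = 100 (S_c - S_u)/S_u$ with $S = 1/\sigma$ per set. Because
empirical CMIs can fall marginally below zero while the
arcsine-square-root transform is only defined on $[0, 100]$, the transform
is extended as the odd function
$\mathrm{sign}(c)\,\arcsin\!\sqrt{|c|/100}$ — strictly monotone,
rank-preserving, and identical to the plain transform on positives.
Outliers are screened once, on raw CMIs over the pooled sample, with
1.5·IQR Tukey fences (type-7 quartiles); flagged participants are dropped
from group statistics but retained, flagged, in the per-participant table.

### Response-time model

Decisions with RT < 100 ms or > 3000 ms are treated as anticipatory or
delayed and excluded from RT analyses only — psychometric and confidence
analyses keep every decision, since the bounds are an RT-quality rule and
exclusion rates are far below 1% under the generative defaults. Median RTs
are computed per confidence set × signed stimulus level, with the
normalized intensity $S = (\Delta - \mathrm{PSE})/\sigma$ taken from the
**unsorted-set** fit for both sets: the unsorted fit uses all data, and a
shared normalization keeps the two sets on one intensity axis. The
three-parameter model

$$RT(S) = \alpha - \beta e^{-S^2/2} - \gamma C$$

is fitted by least squares jointly over the (up to) 14 cells of both sets.
The joint fit is what identifies $\gamma$: within the chosen set $C$ is
constant at 1, so a per-set fit would leave the confidence term
unidentifiable. Since the regressors are fixed, the model is linear in
$(\alpha, \beta, \gamma)$ and the global optimum is computed exactly
(verified against a 50³ grid in the tests); identifiability checks demand
≥ 4 cells, ≥ 2 distinct values of $e^{-S^2/2}$ and of $C$, and full column
rank. Cells are unweighted — cell sizes are near-balanced by design, and
the model is a descriptive decomposition rather than a likelihood.

A note on signs: in this minus convention, responses that *slow down*
towards the PSE (the standard difficulty effect) correspond to $\beta < 0$,
which also places the generic RT $\alpha$ *below* the overall median RT.
The generator's defaults therefore draw negative $\beta$; the fit itself is
sign-agnostic, and predicted-RT monotonicity in $|S|$ and $C$ follows the
signs of the fitted coefficients.

### Group statistics

* **Mixed ANOVA** (between: age group; within: confidence set): classical
  univariate sums-of-squares decomposition, $F$, dfs, $p$, and partial
  $\eta^2 = SS_e/(SS_e + SS_{err})$. With two within levels, sphericity is
  vacuous. Verified against `aov()` error strata, a hand-worked
  decomposition, and (single-group case) the $F = t^2$ identity.
* **t-tests**: Levene's test (mean-centred, α = 0.05) gates Student vs
  Welch for independent comparisons. Cohen's d uses the pooled SD
  (independent) or the SD of differences (paired). 95% percentile
  bootstrap CIs use 2000 resamples with participants as the resampling
  unit, each group resampled independently.
* **Correlations**: Pearson $r$ with $t$-based two-sided $p$; first-order
  partial correlation (df = n − 3) for the age-controlled analysis;
  bootstrap CIs resample complete observation tuples.
* p-values are reported unadjusted; no multiple-testing correction is
  applied anywhere in the chain.

## The generative observer

Per decision, evidence $e \sim N((\Delta - b)/\sigma_s, 1)$; the report is
$\mathrm{sign}(e)$, replaced by a fair coin with probability `lapse`.
Confidence evidence is $|e| + N(0, \sigma_c)$ — distance from criterion,
the standard SDT confidence rule — and the decision with the larger value
is selected (ties broken by coin). $\sigma_c = 0$ gives the ideal
confidence observer; $\sigma_c \to \infty$ decouples confidence from
accuracy and drives the expected CMI to zero. RTs follow the exponential
model with the realized confidence code plus Gaussian noise, clamped at the
100 ms filter bound so generated RTs are never flagged as anticipatory.

`expected_choice_map()` computes choice probabilities exactly (no
sampling) by integrating the bivariate evidence density over sign
half-planes. With $\sigma_c > 0$ the integrand is smooth on each half-plane
and 2-D adaptive quadrature (`pracma::integral2`, tolerance $10^{-6}$) is
used; with $\sigma_c = 0$ the indicator $|e_1| > |e_2|$ would be
discontinuous, so the inner integral is evaluated in closed form with
normal CDFs and only a 1-D quadrature remains. Lapses redistribute
decision labels but cancel in the aggregate map.

### Cohort defaults (the reference study conditions)

One session is 420 trials in 6 blocks of 70; 7 test contrasts 13–31% in 3%
steps around a 22% standard, each level 60× per task position,
counterbalanced independently and shuffled uniformly (no further ordering
constraints). Trial laterality is generated and stored but not analysed.

Group parameter distributions (chosen once as a realistic older/younger
contrast cohort, then frozen):

| parameter | older | younger | unit |
|---|---|---|---|
| sensory noise $\sigma_s$ | N(7.0, 1.3) | N(4.6, 0.8) | % contrast |
| confidence noise $\sigma_c$ | logN(log 1.0, 0.45) | logN(log 0.66, 0.40) | evidence SD |
| generic RT $\alpha$ | N(524, 120) | N(438, 100) | ms |
| intensity effect $\beta$ | N(−100, 35) | N(−90, 30) | ms |
| confidence effect $\gamma$ | N(50, 22) | N(55, 22) | ms |
| trial RT noise | 150 | 150 | ms |

The $\sigma_c$ medians were calibrated in a one-off simulation so the
pipeline's group-mean CMIs land near the canonical ≈31% (younger) and ≈23%
(older) efficiency levels for this paradigm; $\sigma_s$ levels produce the
expected sensitivity gap between groups, and cognitive-battery marginals
are Gaussian with group-typical means/SDs (completion times negated before
compositing).

### The EF–efficiency link

The battery's four EF measures load (λ = 0.7) on a shared factor coupled
to the latent efficiency trait (the pooled-standardized $-\sigma_c$)
through a Gaussian-factor construction; backward digit span is generated
independently of efficiency. The within-group coupling is solved in closed
form from population moments so that the target pooled correlation is met
exactly, accounting for the between-group alignment contributed by the
group differences in both $\sigma_c$ and battery means; infeasible targets
raise an error before any simulation.

`ef_link` targets the correlation **the pipeline recovers** between
estimated CMIs and EF scores, not the latent correlation. The distinction
matters: at 420 trials per session, estimated CMIs carry substantial
estimation noise, which attenuates the recovered correlation to roughly
half the latent one. Since empirical reports of a CMI–EF association are
necessarily measured-CMI correlations, a generator that emulates such a
study must compensate: the latent copula strength is
`ef_link / ef_attenuation`, with `ef_attenuation = 0.5` determined once by
a calibration simulation at the default cohort and exposed as an argument
(`ef_attenuation = 1` recovers the uncompensated latent-target behaviour).
The compensation is exact at the default conditions and approximate away
from them.

## What the simulations do and do not show

The generator reproduces the design structure, SDT-consistent psychometric
and confidence behaviour, realistic RT structure, and the group/EF
covariance structure. It does **not** emulate: sequential effects or
learning/fatigue across blocks, criterion drift, lateral biases,
evidence-accumulation RT dynamics (RT noise is additive Gaussian, not a
process model), confidence lapses distinct from additive confidence noise,
or non-Gaussian cognitive-score distributions. Passing tests therefore
establish that the pipeline is correct and well-calibrated *under the SDT
observer*, not that real data satisfy those assumptions.

Known limitations:

* Estimated CMIs are noisier than Bayesian posterior summaries would be on
  the same sessions (the chosen set has only 420 decisions); between-
  participant CMI spreads from this pipeline are correspondingly wider
  than the generative spread alone.
* The arcsine transform's signed extension is a pragmatic device for the
  occasional marginally negative CMI; strongly negative CMIs (|CMI| near
  100) would deserve a different treatment, and magnitudes above 100 are
  clipped with a warning.
* Group statistics assume one session per participant and complete
  within-cells; incomplete designs error out rather than impute.

## Problem sizes used by the test-suite

Tests run the psychometric grid oracle at ~0.04–0.05 resolution, the RT
grid oracle at 50³, parameter recovery at 100–200 simulated sessions or
datasets, the map convergence check at 500 sessions, the EF-link
calibration at 200 cohort replicates of 30 + 30 participants, and type-I
calibration of the gated t-test at 1000 null replicates — sizes chosen so
each Monte-Carlo check has comfortable resolution for the tolerance it
asserts while the whole suite stays desk-scale.
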
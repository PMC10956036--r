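---
title: "Modelling metacognition and its psychiatric correlates with metacogr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metacognition and its psychiatric correlates with metacogr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacogr)
```

## The problem

When people make two-alternative forced-choice (2-AFC) decisions and rate
their confidence, two distinct metacognitive quantities are in play:
*metacognitive sensitivity* (do confidence ratings discriminate correct from
incorrect decisions?) and *metacognitive bias* (is confidence high or low
overall, regardless of accuracy?). Both have been linked to dimensions of
psychopathology in general-population samples: compulsivity-related symptoms
with inflated confidence despite reduced accuracy, anxious-depressive symptoms
with depressed confidence despite intact accuracy. metacogr implements the
full computational chain needed to study such relationships: signal-detection
modelling of decisions and confidence, hierarchical Bayesian estimation of
metacognitive efficiency, transdiagnostic factor scoring of questionnaire
batteries, data-quality exclusion rules, standardized regression and power
analysis — together with a synthetic-cohort generator with planted effects so
that every stage is testable without access to human data.

## The observer model

Classical equal-variance signal detection describes the type-1 decision:
evidence $x \sim \mathcal N(\pm d'/2, 1)$, response "right" when $x > c$.
From hit and false-alarm rates, $d' = z(\mathrm{HR}) - z(\mathrm{FAR})$ and
$c = -\tfrac12\,[z(\mathrm{HR}) + z(\mathrm{FAR})]$, with the relative
criterion $c' = c/d'$. By convention, the stimulus "right" is the signal, so
a bias toward "left" responses appears as $c > 0$.

The meta-d' model asks what type-1 sensitivity a *metacognitively ideal*
observer with the same relative criterion would have needed to produce the
observed confidence data. On the meta level, evidence is again unit-variance
normal at $\pm \text{meta-}d'/2$; the meta-level criterion is pinned at
$\text{meta-}c = c' \cdot \text{meta-}d'$, and $K-1$ type-2 criteria per
response side partition the axis into confidence bands. For "right" responses
with boundaries $\text{meta-}c = b_0 < b_1 \le \dots < b_K = \infty$,

$$P(y \mid s, \text{right}) \;=\;
\frac{\Phi(b_y - \mu_s) - \Phi(b_{y-1} - \mu_s)}{1 - \Phi(\text{meta-}c - \mu_s)},
\qquad \mu_s = \pm \text{meta-}d'/2,$$

mirrored through the lower tail for "left" responses. Fitting maximises the
multinomial likelihood of the confidence counts conditional on (stimulus,
response). Efficiency is the ratio $M = \text{meta-}d'/d'$, analysed as
$\log M$; $M = 1$ is ideal insight and the ratio (rather than the difference
$\text{meta-}d' - d'$) is used because it better isolates metacognition from
first-order performance.

Metacognitive *bias* is quantified by the confidence criterion: the absolute
distances $\lvert \text{type-2 } c' - \text{type-1 } c' \rvert$ averaged over
the $K-1$ rating levels within each response side, then over the two sides.
Small values mean the type-2 criteria hug the decision criterion — a bias
toward high confidence — so the statistic is inversely related to mean
confidence. The type-1 reference is the model's own meta-level criterion by
default (`reference = "meta_c"`); the raw criterion can be requested instead,
since the published definition fixes the framework but not the axis.

### Numerical choices

* Every rating cell is padded with $1/(2K)$ pseudo-counts before rates or
  likelihoods are formed (the classic +0.5 correction after collapsing),
  exposed as `padding` everywhere and applied identically in the type-1 and
  type-2 fits.
* Probabilities are clipped to $[10^{-6}, 1-10^{-6}]$ before quantile
  transforms, keeping estimates finite for extreme observers; conditional
  rating probabilities are floored at $10^{-12}$ inside log-likelihoods.
* Criterion ordering is enforced by construction: both criteria vectors are
  parameterised as positive increments on a log scale away from the
  meta-level criterion, so any unconstrained parameter vector maps to a valid
  observer. The MLE uses BFGS with an analytic gradient (a safety-net second
  start is consulted if the first fails), and meta-d' is allowed to go
  negative at the MLE so that the negative-efficiency exclusion rule has
  something to screen.
* Trials from the identical condition (zero evidence, no objectively correct
  answer) are kept in the rating tables under their labelled side but
  excluded from every accuracy denominator, and their count is flagged.
* Degenerate confidence data (a single rating level used throughout) yield a
  fit flagged `degenerate` rather than an error; such participants are the
  business of the exclusion rules.

## Bayesian estimation

Single-subject MCMC fits sample $\log M$ (so meta-d' stays positive under the
prior) and the log criteria increments by adaptive random-walk Metropolis.
Priors are weakly informative: $\log M \sim \mathcal N(0, 1)$ and
$\mathcal N(0, 2)$ on each log increment. The reference workflow delegates
these priors to an external toolbox without reproducing them, so they are
package choices, exposed as arguments; the published sampler settings
(3 chains, 1000 burn-in, 10000 samples, no thinning) are the defaults of
`mcmc_params()`. One note: a location prior for a *log-scale* increment
cannot meaningfully be centred on an evidence-axis criterion value, so the
increment prior is centred at zero.

The hierarchical model shares information across subjects:
$\log M_s \sim \mathcal N(\mu + X_s\beta,\ \sigma)$, with
$\mu \sim \mathcal N(0,1)$, $\beta_k \sim \mathcal N(0,1)$,
$\sigma \sim \text{half-}\mathcal N(1)$, and subject-level type-2 criteria as
above. Because no MCMC engine is available as a dependency, the sampler is
implemented in the package: Metropolis-within-Gibbs with vectorised
independent random-walk updates across subjects (one block for $\log M$, one
per criteria side), a conjugate Gibbs draw for $(\mu, \beta)$, and a
log-scale random walk for $\sigma$; proposal scales adapt during burn-in
toward ~30% acceptance. Split-chain R-hat and an autocorrelation-based
effective sample size are reported for every top-level parameter, and R-hat
above 1.1 raises a warning that is also recorded in the diagnostics table.

Inference follows the highest-density-interval rule: an effect (group
difference of paired posterior draws, or a regression coefficient) is called
significant exactly when its 95% HDI excludes zero. The HDI is the narrowest
window containing $\lceil 0.95\,n \rceil$ sorted draws, leftmost on ties.
Group splits for the high/low comparison use `median_split()`, which sends
exact-median subjects to the low group. Covariates are standardized before
entering the hierarchical regression (the source procedure does not state
this either way; standardizing keeps the coefficient scale interpretable and
is recorded here as the package default).

## The synthetic world

The generator states one world and keeps it fixed:

* **Designs.** Perception: a 272-dot reference against comparisons differing
  by $-64..+64$ dots in steps of 8 (17 conditions including the identical
  condition), 8 trials each, 136 trials in 2 blocks, reference side
  counterbalanced within condition. Knowledge: 8 log10 population-ratio bins
  of width 0.225 (edges 0–1.8) times two sides, 9 trials per signed bin,
  144 trials in 2 blocks; country pairs are opaque labels, and trials can
  time out.
* **Observer.** Evidence $x \sim \mathcal N(k\,\Delta/2, 1)$, so task-level
  $d'$ is linear in $|\Delta|$ (the published group curves are monotone but
  their functional form is not stated; linearity is the simplest choice).
  Confidence cuts a noisy copy $x + \varepsilon$,
  $\varepsilon \sim \mathcal N(0, \sigma_m)$, with equal-width type-2
  criteria (spacing 0.25) shifted by a confidence-bias parameter. With
  $\sigma_m = 0$ and zero shift the observer is metacognitively ideal.
* **Calibration.** The default sensitivity slopes (0.060 per dot, 0.315 per
  bin) were fixed once so that the collapsed fits land near the reported
  task averages ($d' \approx 1.7$ perception, $\approx 1.3$ knowledge); the
  criterion distribution ($\mathcal N(0.10, 0.15)$) reproduces the small
  leftward bias; the criteria spacing puts the mean confidence criterion
  near 0.75. Population Mratio targets are drawn
  $\mathcal N(0.8, 0.2)$, clipped to $[0.3, 1]$, and realised through
  $\sigma_m = \sqrt{1/M^2 - 1}$.
* **Cohorts.** Three symptom factors (AD, CIT, SW) are multivariate normal
  with correlations 0.45/0.58/0.42 — the moderate inter-factor correlations
  typical of large transdiagnostic samples. 209 items across nine instruments
  (depression 20, trait anxiety 20, apathy 18, impulsivity 30, OCD 18, eating
  attitudes 26, alcohol use 10, schizotypy 43, social anxiety 24 with
  fear/avoidance sub-answers) load chiefly on their instrument's dominant
  factor, with small zero-centred, sign-mixed cross-loadings (uniformly
  positive cross-loadings would manufacture a general factor and
  near-collinear scores); responses are the probability-integral transform of
  the noisy item latent onto each instrument's ordinal range.
* **Planted effects.** Standardized effects default to +0.33 (AD) and −0.17
  (CIT) on the confidence criterion and −0.16 (CIT) on $d'$ — the replication
  targets the simulation is built to exercise. Each behavioural latent is
  built to unit variance (linear factor part plus shared and task-specific
  residuals). Confidence bias is expressed *multiplicatively* on the type-2
  criterion spacing (log-normal across subjects): spacing
  $0.25\,e^{0.42 u}$, always positive, right-skewed, no floor truncation
  (an additive shift clamps at zero for low-bias subjects, which compresses
  one tail and attenuates planted effects asymmetrically). Offsets are stated
  on the meta axis and divided by the subject's meta-noise attenuation
  $1/\sqrt{1+\sigma_m^2}$ so that the *fitted* criteria carry the intended
  spacing. Because the published coefficients are themselves estimates on the
  measured scale — the z-scored confidence criterion at 136 trials, whose SD
  includes trial-level measurement noise — the latent plant is scaled by the
  inverse of the measurement chain's gain (calibrated once for the default
  world: 0.83 for AD, 0.74 for CIT, 0.78 for SW), so that the standardized
  regression on measured outcomes is centred on the planted values. Big-5
  latents are tied to the factors with the signs observed in large
  questionnaire studies. Requested rule violators are injected at the end of
  the cohort, one rule each.

What the generator does **not** emulate: response times, reverse-keyed item
semantics (items are generated already keyed), age/gender relationships with
symptoms (planted at zero by default), item-level measurement models beyond a
linear factor structure, and Mratio values above 1. A green end-to-end test
therefore establishes that the pipeline recovers what was planted under this
stated world — not that the world captures every property of human data.

Two subtleties are worth knowing. First, the process observer's realised
Mratio under metacognitive noise is close to, but below,
$1/\sqrt{1+\sigma_m^2}$, because decision and confidence can disagree near
the criterion; recovery tests that need an exactly known Mratio use
`simulate_metad_counts()`, which draws ratings from the meta-d' model's own
conditional distributions. Second, when an ideal observer is simulated across
*mixed* difficulty levels and fitted collapsed, the Gaussian assumption is
mildly violated and fitted Mratio exceeds 1 by a few percent; the
ideal-observer calibration therefore uses a fixed-evidence design, where the
model is exact.

## Scoring, exclusion, regression, power

Factor scores follow the published recipe exactly: z-score each item across
participants, weight, sum within factor, z-score the sums. The weight matrix
is user-supplied (`read_factor_weights()`); a synthetic stand-in with the
same shape ships for testing. Questionnaire log-totals use
$\log(\text{total}+1)$ — the offset guards instruments whose minimum total is
zero and is configurable, since the source states only "log-transformed".

Exclusions implement the ten published rules with their exact thresholds
(accuracy strictly below 55% on responded, non-identical-condition trials;
under 18; missing gender; failed catch item; constant confidence; Mratio
below 0 from the *non-hierarchical* fit, matching the workflow order; and,
for the two-task design, the knowledge-task analogues plus more than 4
non-responses out of 144). A participant violating several rules is excluded
once but counted under every rule.

Regression families mirror the published models: separate per-questionnaire
models, the three-factor model, and the personality-plus-factors model, each
controlling for age and gender, all variables z-scored (gender as a z-scored
binary contrast), p-values from the t distribution, VIF per predictor, and
Bonferroni correction over the *dependent variables* of each family
(`bonferroni_alpha()`), never over predictors.

Power planning uses the noncentral-F formulation with noncentrality
$\lambda = f^2 n$, `df1` the number of tested coefficients and
`df2` $= n - p - 1$. The defaults (five predictors, one tested) reproduce the
published plan — 395 participants for 80% power at $f^2 = 0.02$, 86% power at
$n = 473$ — to the printed precision; both counts remain explicit parameters
because the original calculator settings are not fully stated.

## A worked example

```{r example, eval = FALSE}
co <- simulate_cohort(cohort_spec(n = 60, tasks = "perception", seed = 1))
cf <- fit_cohort_metad(co)          # per-participant MLE fits
sc <- participant_scores(co)        # factor scores + totals + demographics
m  <- cf$measures
cc <- m$value[m$measure == "confidence_criterion"]
dat <- data.frame(sc, outcome = cc[match(sc$participant_id,
                                         m$participant_id[m$measure == "confidence_criterion"])])
standardized_ols(dat, "outcome", c("AD", "CIT", "SW", "age", "gender"))
```

## Known limitations

* The hierarchical sampler is plain Metropolis-within-Gibbs; at the reference
  settings it is slower than a compiled engine, and the group-spread
  parameter mixes most slowly (watch its effective sample size).
* Unequal-variance type-1 models, type-2 ROC measures and response-time
  models are out of scope.
* The exploratory factor analysis that produced the item weights is not
  reimplemented; scores are computed from a supplied weight matrix only.
* The knowledge task is abstracted to binned evidence; no country-population
  database is bundled.
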
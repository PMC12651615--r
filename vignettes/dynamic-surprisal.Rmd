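---
title: "Dynamic Bayesian surprisal for daily-diary exposures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic Bayesian surprisal for daily-diary exposures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsurprisal)
```

## Overview

Surprisal — the negative log predictive probability of an observation —
is only as good as the expectation it is scored against. In daily-diary
data, a new participant has no personal history, so expectations must be
built sequentially: a prior, updated one day at a time. This package
implements that prequential machinery for three measurement types
(binary, integer-heaped continuous, and zero-inflated skewed
non-negative), under two prior regimes, together with the hindsight
benchmark that a fully observed record would provide.

Each variable is modelled separately for each person; the joint
distribution across variables is deliberately ignored. This scales to
settings where different people track different (possibly many)
variables, at the cost of missing cross-variable structure.

## The three sequential models

**Binary exposure (exercise).** Bernoulli likelihood with a conjugate
Beta(α, β) prior. After `k` exposures in `t` observed days the posterior
is Beta(α + k, β + t − k) and the posterior predictive probability of an
exposure tomorrow is (α + k)/(α + β + t). The state stores (α, β) and
(k, t) separately, so the prior remains inspectable after any amount of
updating.

**Heaped continuous (sleep hours).** Reports heap at whole hours, so a
continuous Normal model is discretised at scoring time. The likelihood
is Normal with *known* observation variance σ²ʸ and a conjugate Normal
prior on the mean μ; the posterior on μ has precision 1/σ²₀ + n/σ²ʸ.
The one-step-ahead predictive is Normal with variance σ²ʸ + Var(μ |
data); the probability of an integer report `z` is the predictive mass
between z − 0.5 and z + 0.5, renormalised over the integer support
[0, 24] (zero is the hard physical floor, 24 h the cap). Observations
are rounded half-up before lookup, matching the half-integer bins.

Treating σ²ʸ as known preserves exact conjugacy. Its default is 2.25 h²
(SD 1.5 h), a typical night-to-night spread; under the empirical prior
condition it is replaced by the pooled within-person variance of the
leave-one-out sample, so the amount of smoothing reflects the cohort at
hand. Placing a prior on the variance as well (Normal–Inverse-Gamma)
would be a natural extension but is out of scope.

Two defensible treatments exist for mass falling below the truncation
point: folding it into the boundary bin, or renormalising it away. We
renormalise, which keeps the support an honest probability distribution
and treats the lower and upper truncation symmetrically. With a 7 h
centre the choice is numerically negligible except under extremely
diffuse predictives.

**Zero-inflated skewed (stress).** A hurdle-Gamma: a Bernoulli hurdle
for the probability `p_zero` of a zero-stress day, and a Gamma(shape,
rate) for the magnitude of nonzero days. The hurdle is conjugate
(Beta); the two-parameter Gamma is not, so the (shape, rate) posterior
is refit by sampling at each day on all accumulated observations, with
independent Gamma hyperpriors on shape and rate. The expected daily
stress is E[x] = (1 − p_zero) × shape/rate, averaged over posterior
draws.

### The stress sampler

Any correct posterior sampler satisfies the model contract; we use the
simplest one that is verifiable against closed forms:

* `p_zero` is drawn *exactly* from its conjugate
  Beta(a + n₀, b + n₊) — no Monte-Carlo error beyond sampling, and a
  closed form the tests compare against;
* (log shape, log rate) are sampled by adaptive random-walk Metropolis
  using the sufficient statistics (n₊, Σy, Σ log y), with the proposal
  scale adapted during warmup toward an acceptance rate of 0.3 and then
  frozen. Defaults: 2000 post-warmup draws, 1000 warmup. With no
  positive observations the (shape, rate) posterior *is* the hyperprior
  and is drawn directly.

Acceptance rates outside [0.1, 0.9] after adaptation attach a
diagnostic warning. Every refit is seeded deterministically from a base
seed and the number of accumulated observations, so a fixed seed gives
bit-identical draws and a day-`t` posterior depends only on the
observations it was fit to.

Because surprisal requires a probability (not a density), the stress
predictive is discretised like sleep: a point mass at zero (posterior
mean of `p_zero`) plus unit-width bins centred at 1, 2, … (intensity
scores are sums of integer ratings, so unit bins are the natural
resolution; the width is configurable). The first bin absorbs the
sliver (0, 0.5], the last absorbs the upper tail beyond `support_max`
(default 60), so the masses always sum to one. Density-based scoring
was considered and rejected as the default: densities are not
probabilities, and mixing a point mass with densities would put the
zero and nonzero scores on different scales.

## Prior conditions

**Uninformative.** Beta(1, 1) for the binary exposure (predictive 0.5
before any data); Normal(7, 100) on mean sleep hours (SD 10 h around a
7 h centre — broad enough to be dominated by a few nights of data);
Gamma(2, 0.1) hyperpriors (mean 20, SD ≈ 14) on both the stress shape
and rate; Beta(1, 1) on the hurdle.

**Empirical (leave-one-out).** For each participant, built from everyone
else:

* *exercise*: Beta moment-matched to the mean and variance of the
  leave-one-out per-person exposure proportions. If the variance is
  infeasible (zero, or ≥ m(1 − m)), a mean-matched Beta with
  concentration 2 is used, with a warning.
* *sleep*: prior mean = mean of person-level sleep means; prior
  variance = between-person variance of those means (floored at
  0.25 h² so a homogeneous cohort cannot produce a delta-function
  prior); observation variance = pooled within-person variance.
* *stress*: Gamma maximum-likelihood fit to the pooled nonzero values
  (Newton iteration on the shape score log α − ψ(α) = log x̄ − mean(log x),
  moment-estimator start, tolerance 1e−8, at most 100 iterations; the
  rate is α̂/x̄ so the fitted mean equals the sample mean), then the
  hyperpriors are re-centred so their means equal the MLEs with a
  coefficient of variation of 0.5; the hurdle Beta is moment-matched to
  the per-person zero rates.

The *strength* of an empirical prior is nowhere pinned down by first
principles; we encode it through quantities the construction already
names — between-person dispersion for the conjugate models, and a
configurable CV (default 0.5, i.e. a hyperprior effective sample size
of 4) for the stress hyperpriors. Re-centring hyperpriors rather than
plugging in point MLEs keeps the model form identical across the two
prior conditions, so the conditions differ only in information, not in
structure. Individually elicited baseline priors are future work.

## Scoring convention

`run_prequential()` scores day `t` under the predictive formed from
days 1..t−1 and then updates — strict one-step-ahead scoring, with day
1 scored under the prior predictive. This is the default because it is
the honestly prospective quantity: the surprisal emitted on day `t`
cannot depend on day `t` or anything later, and a complete 28-day
record yields exactly 28 values.

For the dynamic-vs-static *benchmark comparison*, however, the
comparable dynamic quantity conditions on the current day
(`include_current = TRUE`): the static benchmark is fitted to the full
record *including* the scored day, and a like-for-like comparison gives
the dynamic side the same privilege. The distinction is not cosmetic.
Under strict one-step-ahead scoring the per-person total of (dynamic −
static) surprisal is mathematically non-negative — the prequential
total equals the negative log marginal likelihood, which can never beat
the maximised likelihood the static fit attains — so early dynamic
surprisal necessarily sits *above* the hindsight benchmark on average.
Conditioning on the current day lets the sparse early posteriors absorb
the scored observation (a larger relative gain early, when the
posterior is dominated by few observations), producing the
characteristic pattern the benchmark comparison is designed to expose:
dynamic surprisal *below* the static reference early, more so under the
uninformative prior, converging within about four weeks. The
acceptance-level directional test asserts exactly that pattern on a
200-participant synthetic cohort.

## The static benchmark

The hindsight reference fits, to each participant's complete record,
the *same family* as the dynamic model — Bernoulli MLE for exercise,
Normal MLE (mean and MLE variance) discretised to integer hours for
sleep, empirical zero rate plus Gamma MLE on nonzero values binned
identically for stress — so dynamic-minus-static differences isolate
the learning dynamics rather than a change of family. Raw empirical
frequencies were the alternative; they cannot score unseen values and
would conflate family mismatch with learning.

Guards for degenerate records: the Bernoulli MLE is clipped to
[1/(2T), 1 − 1/(2T)] so an always- or never-exposed record still yields
finite surprisal; the sleep MLE variance is floored at 0.25 h² for
constant records; stress requires at least two nonzero values.

Per-day cohort summaries (mean, SE, 1.96 × SE intervals) are
frequentist across participants and deliberately ignore each person's
posterior uncertainty; days contributed by a single participant are
reported with an `NA` standard error rather than dropped.

## The synthetic cohort generator

`simulate_cohort()` draws per-person latent parameters from population
distributions and then daily observations from the three model
families. Defaults describe the cohort the models are designed for:
100 participants × 28 days; per-person exercise probabilities from
Beta(2, 6) (group-level exposure on 25% of days); per-person mean sleep
Normal(7, 1) h with 1 h within-person SD, truncated at zero and rounded
half-up to whole hours; per-person zero-stress probability from
Beta(3, 7) (mean 0.3) with Gamma magnitudes centred at shape 2, rate
0.1 (mean 20 intensity units, matching the centre of the weakly
informative hyperpriors) and lognormal between-person dispersion
(SD 0.3 on the log scale). Missingness is optional and
missing-completely-at-random.

The generator emulates exactly the structure the models assume —
which is what makes it the right instrument for testing the machinery,
and the wrong instrument for validating the models. Passing tests on
simulated cohorts show that updating, scoring, priors and benchmarks
behave correctly *when the model family is true*; they cannot show that
real diaries follow these families. Real data features the generator
does not produce: day-to-day autocorrelation (weekend structure,
stress spillover), reporting heaping beyond integer rounding (an excess
of exactly-8-hour sleep reports), informative missingness, and
cross-variable dependence.

## Numerical choices

* Rounding is half-up (`floor(x + 0.5)`), matching the half-integer
  bins; banker's rounding would split ties inconsistently with them.
* Predictive masses below 1e−300 (possible for far-tail observations
  under tight predictives) score as the surprisal of 1e−300 with a
  warning, rather than returning infinity.
* Surprisal of a non-positive "probability" is an error, not a large
  value: a zero mass reaching the scoring function indicates an
  unclipped empirical estimate upstream.
* The Gamma MLE Newton iteration keeps its iterate positive by step
  halving; an all-equal sample (zero log-spread) is a hard error, since
  the likelihood is unbounded there.
* Logs default to base e (nats); base 2 (bits) is available everywhere
  through `log_base`.

## Problem sizes in the shipped tests

The test suite exercises the directional and recovery properties at
sizes chosen to keep Monte-Carlo error well inside the asserted
margins while running in seconds: 200 participants for
convergence/directionality checks, 50 replicates of n = 500 for
hurdle-Gamma recovery (posterior means within 15% relative error),
n = 5000 for Gamma MLE recovery (within 5%), 1000 random parameter
draws for predictive normalisation, and reduced sampler sizes
(hundreds of draws) where a model is refit 28 times per trajectory.
All are the package's own choices and can be scaled up freely.

## Limitations

Per-person, per-variable independence is a modelling *choice*, not a
finding; joint surprisal across variables and partial pooling across
people ("hierarchical" in the population sense) are not implemented.
The sleep observation variance is fixed, not learned. The stress
refits are O(T) posterior fits per participant; for very long records
a sequential Monte Carlo scheme would be cheaper. And all validation is
against synthetic cohorts drawn from the assumed families — the
strongest statements the tests support are about the correctness of
the machinery, not about any real population.
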
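# dsurprisal

Prospective, day-by-day Bayesian surprisal estimation for daily-diary
exposure variables.

## The problem

In daily-diary (ecological momentary assessment) studies, the
*surprisal* of an observation — its self-information,

&nbsp;&nbsp;&nbsp;&nbsp;*S(x<sub>t</sub>) = −log P(x<sub>t</sub> | θ<sub>t</sub>)*

— quantifies how unexpected the day's exposure was given what had been
learned about that person so far. Retrospective surprisal, scored
against a distribution fitted to a person's complete record, requires
weeks of data before it can be computed. This package estimates
surprisal *prospectively*: expectations are formed by Bayesian sequential
updating from the first diary day onward, so each observation is scored
against a predictive distribution that existed before (or on) the day it
arrived.

Three measurement types common in diary data are covered, each with its
own sequential model:

| Variable | Measurement type | Model |
|---|---|---|
| exercise | binary (0/1) | Bernoulli likelihood, conjugate Beta prior; posterior predictive *(α+k)/(α+β+t)* after *k* exposures in *t* days |
| sleep | continuous hours, heaped at integers | Normal likelihood with known variance, conjugate Normal prior on the mean; predictive discretised between half-integer bounds, truncated to [0, 24] h |
| stress | non-negative, zero-inflated, right-skewed | hurdle-Gamma: conjugate Beta hurdle for zero days, Gamma magnitude with Gamma hyperpriors on shape and rate, refit by posterior sampling at each day |

Two prior conditions are supported: **uninformative** (flat Beta(1, 1);
Normal(7, 100) on mean sleep; Gamma(2, 0.1) hyperpriors on the stress
shape and rate) and **empirical** leave-one-out priors built, for each
participant, from the data of everyone else in the cohort
(moment-matched Beta, between/within variance decomposition for sleep,
Gamma maximum-likelihood fits for stress). A static full-record
benchmark (the hindsight distribution fitted to each complete record)
and per-day cohort summaries of expectations and dynamic-minus-static
surprisal differences complete the analysis. A synthetic-cohort
generator provides diary datasets with the statistical structure the
models assume.

## Worked example

```r
library(dsurprisal)

# a 100-participant, 28-day synthetic diary cohort
diary <- simulate_cohort(cohort_config(n_participants = 100, seed = 42))

# one participant's prospective exercise surprisal under the flat prior
p1 <- diary[diary$participant_id == "P001", ]
traj <- run_prequential(p1$exercise, beta_bernoulli_state(1, 1))
head(traj, 3)
#>   day observed pred_mass surprisal expectation
#> 1   1        0 0.5000000 0.6931472   0.5000000
#> 2   2        0 0.6666667 0.4054651   0.3333333
#> 3   3        0 0.7500000 0.2876821   0.2500000
```

Day 1 is scored under the prior predictive (0.5 under the flat prior, so
every first observation costs log 2 ≈ 0.693 nats); as no-exercise days
accumulate, the predictive probability of another no-exercise day rises
and its surprisal falls. The `expectation` column is the predictive
probability of exercising *before* seeing the day's report — 0.5 on day
1 for every participant, the signature of the flat prior.

```r
# dynamic vs static exercise surprisal across the cohort, both priors
dyn <- dynamic_surprisal(diary, variables = "exercise",
                         conditions = c("uninformative", "empirical"),
                         include_current = TRUE, base_seed = 42)
sta <- static_surprisal(diary, variables = "exercise")
diff <- compare(dyn, sta)
subset(diff, day %in% c(1, 28))
#>    variable prior_condition day     estimate          se
#> 1  exercise       empirical   1 -0.011739837 0.025691534
#> 28 exercise       empirical  28  0.003956853 0.008368507
#> 29 exercise   uninformative   1 -0.066414883 0.046271747
#> 56 exercise   uninformative  28  0.002072551 0.005524405
```

On day 1 the dynamic surprisal sits below the hindsight benchmark —
much further below under the uninformative prior (−0.066 nats) than
under the empirical prior (−0.012) — and by day 28 both conditions have
converged to the benchmark (estimates within a few thousandths of a
nat, confidence intervals covering zero). Early expectations are where
prior choice matters; individual learning erases the difference within
about four weeks.

The full pipeline (all three variables, both priors, static references,
per-day summary tables, JSON run manifest) runs from a YAML config:

```r
run_pipeline(list(simulate = list(n_participants = 20, seed = 1),
                  variables = c("exercise", "sleep", "stress"),
                  seed = 1), out_dir = "results/demo")
```

or from the shell via `inst/scripts/dsurprisal-cli`
(`simulate` / `run` / `compare` verbs).

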
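# Shared fixtures: sampler settings small enough for fast tests but large
# enough that Monte-Carlo error stays well below the tolerances asserted.
fast_sampler <- list(n_draws = 400L, n_warmup = 200L)

# A degenerate hurdle-Gamma posterior with fixed parameter values, for
# testing predictive/expectation arithmetic independently of the sampler.
degenerate_posterior <- function(p_zero, shape, rate, n_draws = 1L) {
  structure(list(draws = data.frame(p_zero = rep(p_zero, n_draws),
                                    shape = rep(shape, n_draws),
                                    rate = rep(rate, n_draws)),
                 n_draws = n_draws, n_obs = 0L, n_zero = 0L,
                 prior = hurdle_gamma_prior(),
                 diagnostics = list(accept_rate = NA_real_)),
            class = "hurdle_gamma_posterior")
}

small_cohort <- function(n = 6L, days = 28L, seed = 11L, ...) {
  simulate_cohort(cohort_config(n_participants = n, n_days = days,
                                seed = seed, ...))
}
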
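#' Prior specifications for the three diary variables
#'
#' Two prior conditions are supported. Uninformative priors express
#' minimal baseline knowledge: a flat Beta(1, 1) on the exercise
#' probability, a diffuse Normal(7, 100) on mean sleep hours (prior SD 10
#' h around a 7 h centre), and weakly informative Gamma(2, 0.1)
#' hyperpriors on the stress Gamma shape and rate. Empirical priors are
#' built per participant from the leave-one-out sample (all other
#' participants): moment-matched Beta for exercise, between/within
#' variance decomposition for sleep, and Gamma maximum-likelihood fits
#' for stress.
#'
#' @param variable One of `"exercise"`, `"sleep"`, `"stress"`.
#' @return An object of class `prior_spec`: a list with `condition`,
#'   `variable`, and `parameters` (a model state or prior object ready to
#'   initialise the corresponding sequential model).
#' @examples
#' uninformative_prior("exercise")   # flat Beta(1, 1)
#' @export
uninformative_prior <- function(variable = c("exercise", "sleep", "stress")) {
  variable <- match.arg(variable)
  params <- switch(variable,
    exercise = beta_bernoulli_state(1, 1),
    sleep = normal_mean_state(mu_prior = 7, var_prior = 100, obs_var = 2.25),
    stress = hurdle_gamma_prior(hurdle_alpha = 1, hurdle_beta = 1,
                                shape_prior = c(2, 0.1),
                                rate_prior = c(2, 0.1)))
  new_prior_spec("uninformative", variable, params)
}

new_prior_spec <- function(condition, variable, parameters, notes = NULL) {
  structure(list(condition = condition, variable = variable,
                 parameters = parameters, notes = notes),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Prior spec: %s prior for %s\n", x$condition, x$variable))
  print(x$parameters)
  if (!is.null(x$notes)) cat("note:", x$notes, "\n")
  invisible(x)
}

# Moment-matched Beta(alpha, beta) from a mean m and variance v. When the
# variance is infeasible (v = 0 or v >= m(1-m)) falls back to a
# mean-matched Beta with concentration 2, with a warning.
beta_moment_match <- function(m, v, fallback_concentration = 2) {
  stopifnot(is_scalar_prob(m))
  if (m <= 0 || m >= 1)
    m <- clip(m, 1e-6, 1 - 1e-6)
  if (!is.finite(v) || v <= 0 || v >= m * (1 - m)) {
    warning(sprintf("moment matching infeasible (mean %.4g, variance %.4g); using mean-matched Beta with concentration %g",
                    m, v, fallback_concentration), call. = FALSE)
    return(list(alpha = m * fallback_concentration,
                beta = (1 - m) * fallback_concentration, fallback = TRUE))
  }
  c0 <- m * (1 - m) / v - 1
  list(alpha = m * c0, beta = (1 - m) * c0, fallback = FALSE)
}

#' Leave-one-out empirical prior for a binary exposure
#'
#' Builds a Beta prior whose mean and variance match the distribution of
#' per-person exposure proportions in the leave-one-out sample.
#'
#' @param loo_person_rates Per-person exposure proportions in `[0, 1]`
#'   for the sample excluding the target participant; at least 2 persons.
#' @return A `prior_spec` whose `parameters` is a
#'   [beta_bernoulli_state()] with the matched Beta prior and zero
#'   counts. If moment matching is infeasible (zero or too-large
#'   variance), a mean-matched Beta with concentration 2 is used and a
#'   warning emitted.
#' @export
empirical_prior_exercise <- function(loo_person_rates) {
  r <- as.numeric(loo_person_rates)
  if (length(r) < 2L)
    stop("need at least 2 leave-one-out participants", call. = FALSE)
  if (anyNA(r) || any(r < 0) || any(r > 1))
    stop("person rates must lie in [0, 1]", call. = FALSE)
  mm <- beta_moment_match(mean(r), stats::var(r))
  new_prior_spec("empirical", "exercise",
                 beta_bernoulli_state(mm$alpha, mm$beta),
                 notes = if (mm$fallback) "moment-matching fallback" else NULL)
}

#' Leave-one-out empirical prior for sleep duration
#'
#' The Normal prior on the sleep mean is centred at the mean of the
#' leave-one-out person-level sleep means with variance equal to the
#' between-person variance of those means (floored to avoid a
#' delta-function prior for homogeneous cohorts). The known observation
#' variance is set to the pooled within-person variance of the
#' leave-one-out sample.
#'
#' @param loo_records Data frame with columns `participant_id` and
#'   `sleep_hours` for the sample excluding the target participant
#'   (missing values dropped); at least 2 persons.
#' @param var_floor Minimum prior variance on the mean, hours squared
#'   (default 0.25).
#' @param obs_var_fallback Observation variance used when no person has 2
#'   or more reports (default 2.25 h²).
#' @return A `prior_spec` whose `parameters` is a [normal_mean_state()].
#' @export
empirical_prior_sleep <- function(loo_records, var_floor = 0.25,
                                  obs_var_fallback = 2.25) {
  stopifnot(is.data.frame(loo_records),
            all(c("participant_id", "sleep_hours") %in% names(loo_records)))
  rec <- loo_records[!is.na(loo_records$sleep_hours), , drop = FALSE]
  if (nrow(rec) == 0L) stop("leave-one-out sample is empty", call. = FALSE)
  by_p <- split(rec$sleep_hours, rec$participant_id, drop = TRUE)
  if (length(by_p) < 2L)
    stop("between-person variance undefined: need at least 2 leave-one-out participants",
         call. = FALSE)
  means <- vapply(by_p, mean, numeric(1))
  prior_mean <- mean(means)
  prior_var <- stats::var(means)
  floored <- prior_var < var_floor
  prior_var <- max(prior_var, var_floor)

  ns <- lengths(by_p)
  with_rep <- ns >= 2L
  if (any(with_rep)) {
    ssw <- sum(vapply(by_p[with_rep],
                      function(v) (length(v) - 1) * stats::var(v), numeric(1)))
    obs_var <- ssw / sum(ns[with_rep] - 1L)
    if (obs_var <= 0) obs_var <- obs_var_fallback
  } else {
    warning("no participant has repeated sleep reports; using fallback observation variance",
            call. = FALSE)
    obs_var <- obs_var_fallback
  }
  new_prior_spec("empirical", "sleep",
                 normal_mean_state(prior_mean, prior_var, obs_var = obs_var),
                 notes = if (floored) "prior variance floored" else NULL)
}

#' Gamma maximum-likelihood fit via Newton iteration on the shape
#'
#' Solves the Gamma MLE first-order condition
#' \eqn{\log\alpha - \psi(\alpha) = \log\bar{x} - \overline{\log x}} by
#' Newton iteration with moment-estimator initialisation; the rate is
#' then \eqn{\hat\alpha / \bar{x}} (so the fitted mean equals the sample
#' mean).
#'
#' @param x Strictly positive values, at least 2 distinct.
#' @param tol Convergence tolerance on the score (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return A list with `shape`, `rate`, `iterations`, `loglik`.
#' @export
gamma_mle <- function(x, tol = 1e-8, max_iter = 100L) {
  x <- as.numeric(x)
  if (length(x) < 2L || anyNA(x) || any(x <= 0))
    stop("need at least 2 strictly positive values", call. = FALSE)
  m <- mean(x)
  s <- log(m) - mean(log(x))
  if (s < 1e-12)
    stop("degenerate sample (all values equal): Gamma MLE undefined",
         call. = FALSE)
  a <- m^2 / max(stats::var(x), 1e-12)  # moment-estimator start
  a <- clip(a, 1e-8, 1e8)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    while (a_new <= 0) {  # keep the iterate in the domain
      step <- step / 2
      a_new <- a - step
    }
    a <- a_new
    if (abs(f) < tol) { converged <- TRUE; break }
  }
  if (!converged && abs(log(a) - digamma(a) - s) >= tol)
    stop("Gamma MLE Newton iteration did not converge after ", max_iter,
         " iterations", call. = FALSE)
  rate <- a / m
  list(shape = a, rate = rate, iterations = it,
       loglik = sum(stats::dgamma(x, shape = a, rate = rate, log = TRUE)))
}

#' Leave-one-out empirical prior for stress
#'
#' Fits the Gamma parameters by maximum likelihood to the pooled nonzero
#' stress values of the leave-one-out sample, then re-centres the Gamma
#' hyperpriors so their means equal the MLEs with a configurable relative
#' dispersion (coefficient of variation). The hurdle Beta prior is
#' moment-matched to the per-person zero rates.
#'
#' @param loo_nonzero_values Pooled strictly positive stress values from
#'   the leave-one-out sample; at least 10.
#' @param loo_zero_rates Per-person proportions of zero-stress days in
#'   the leave-one-out sample.
#' @param cv Coefficient of variation of the re-centred hyperpriors
#'   (default 0.5).
#' @param ... Passed to [gamma_mle()].
#' @return A `prior_spec` whose `parameters` is a
#'   [hurdle_gamma_prior()].
#' @export
empirical_prior_stress <- function(loo_nonzero_values, loo_zero_rates,
                                   cv = 0.5, ...) {
  v <- as.numeric(loo_nonzero_values)
  if (length(v) < 10L)
    stop("need at least 10 nonzero stress values for the empirical prior",
         call. = FALSE)
  if (any(v <= 0)) stop("nonzero stress values must be strictly positive",
                        call. = FALSE)
  stopifnot(is.numeric(cv), cv > 0)
  mle <- gamma_mle(v, ...)
  a_hyp <- 1 / cv^2  # Gamma(a, b) has CV 1/sqrt(a)
  r <- as.numeric(loo_zero_rates)
  if (length(r) < 2L)
    stop("need per-person zero rates for at least 2 participants",
         call. = FALSE)
  mm <- beta_moment_match(mean(r), stats::var(r))
  new_prior_spec("empirical", "stress",
                 hurdle_gamma_prior(hurdle_alpha = mm$alpha,
                                    hurdle_beta = mm$beta,
                                    shape_prior = c(a_hyp, a_hyp / mle$shape),
                                    rate_prior = c(a_hyp, a_hyp / mle$rate)),
                 notes = sprintf("Gamma MLE shape %.4g rate %.4g (n = %d)",
                                 mle$shape, mle$rate, length(v)))
}

#' Initial sequential state from a prior specification
#'
#' @param spec A `prior_spec`.
#' @param sampler Optional list of hurdle-Gamma sampler settings
#'   (`n_draws`, `n_warmup`, `base_seed`, `bin_width`, `support_max`),
#'   used only for stress.
#' @return A predictive state ready for [run_prequential()].
#' @export
initial_state <- function(spec, sampler = list()) {
  stopifnot(inherits(spec, "prior_spec"))
  if (spec$variable %in% c("exercise", "sleep")) return(spec$parameters)
  hurdle_gamma_state(spec$parameters,
                     n_draws = sampler$n_draws %||% 2000L,
                     n_warmup = sampler$n_warmup %||% 1000L,
                     base_seed = sampler$base_seed %||% 1L,
                     bin_width = sampler$bin_width %||% 1,
                     support_max = sampler$support_max %||% 60)
}
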
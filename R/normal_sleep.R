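#' Known-variance Normal mean state for heaped sleep duration
#'
#' Sleep duration is reported in hours and heaps at whole numbers. It is
#' modelled as Normal with known observation variance `obs_var` and a
#' conjugate Normal prior on the mean \eqn{\mu}. After `n` observations
#' with sum `sum_obs`, the posterior on \eqn{\mu} has
#' precision \eqn{1/\sigma_0^2 + n/\sigma_y^2} and mean equal to the
#' precision-weighted combination of the prior mean and the running
#' sample mean. The one-step-ahead predictive for the next (continuous)
#' report is Normal with that mean and variance
#' \eqn{\sigma_y^2 + \mathrm{Var}(\mu \mid data)}; it is then discretised
#' to integer hours between half-integer bounds and truncated to
#' \eqn{[0, 24]} (see [discretize_predictive()]).
#'
#' @param mu_prior Prior mean of \eqn{\mu}, in hours.
#' @param var_prior Prior variance of \eqn{\mu}, in hours squared.
#' @param obs_var Known observation (within-person) variance, hours
#'   squared. Default 2.25 (SD 1.5 h).
#' @param n Number of observations absorbed (default 0).
#' @param sum_obs Running sum of absorbed observations, hours.
#' @param z_min,z_max Integer support bounds for the discretised
#'   predictive; defaults 0 and 24 h (the physical cap).
#' @return An object of class `normal_mean_state`.
#' @export
normal_mean_state <- function(mu_prior, var_prior, obs_var = 2.25,
                              n = 0L, sum_obs = 0, z_min = 0L, z_max = 24L) {
  stopifnot(is.numeric(mu_prior), length(mu_prior) == 1L, is.finite(mu_prior),
            is.numeric(var_prior), length(var_prior) == 1L, var_prior > 0,
            is.numeric(obs_var), length(obs_var) == 1L, obs_var > 0,
            is_count(n), is.numeric(sum_obs), length(sum_obs) == 1L,
            is_count(z_min), is_count(z_max))
  if (z_min > z_max) stop("`z_min` must not exceed `z_max`", call. = FALSE)
  structure(list(mu_prior = mu_prior, var_prior = var_prior,
                 obs_var = obs_var, n = as.integer(n), sum_obs = sum_obs,
                 z_min = as.integer(z_min), z_max = as.integer(z_max)),
            class = "normal_mean_state")
}

# Posterior over mu and the continuous one-step-ahead predictive.
normal_posterior <- function(state) {
  prec0 <- 1 / state$var_prior
  prec <- prec0 + state$n / state$obs_var
  mu_t <- (state$mu_prior * prec0 + state$sum_obs / state$obs_var) / prec
  var_mu <- 1 / prec
  list(mu = mu_t, var_mu = var_mu, pred_var = state$obs_var + var_mu)
}

#' Absorb one sleep observation
#'
#' Standard known-variance conjugate update: posterior precision grows by
#' one unit of observation precision per report.
#'
#' @param state A [normal_mean_state()].
#' @param obs Hours slept; must be non-negative.
#' @return The updated state.
#' @export
update_normal_mean <- function(state, obs) {
  stopifnot(inherits(state, "normal_mean_state"))
  if (!(is.numeric(obs) && length(obs) == 1L && is.finite(obs) && obs >= 0))
    stop("sleep observation must be a non-negative number of hours",
         call. = FALSE)
  normal_mean_state(state$mu_prior, state$var_prior, state$obs_var,
                    state$n + 1L, state$sum_obs + obs,
                    state$z_min, state$z_max)
}

#' Discretised (integer-hour) predictive distribution
#'
#' Converts a continuous Normal predictive into probability masses on
#' integer hours: the mass at integer `z` is the Normal probability
#' between the half-integer bounds \eqn{z - 0.5} and \eqn{z + 0.5},
#' renormalised over the truncated support `[z_min, z_max]`.
#'
#' @param mu_t Predictive mean, hours.
#' @param sigma_t Predictive standard deviation, hours; must be positive.
#' @param z_min,z_max Integer support bounds (default 0 and 24).
#' @return An object of class `discretized_predictive`: a list with
#'   integer `support` and `mass` summing to 1.
#' @examples
#' d <- discretize_predictive(7, 1)
#' sum(d$mass)   # 1
#' @export
discretize_predictive <- function(mu_t, sigma_t, z_min = 0L, z_max = 24L) {
  stopifnot(is.numeric(mu_t), length(mu_t) == 1L, is.finite(mu_t),
            is.numeric(sigma_t), length(sigma_t) == 1L, sigma_t > 0)
  if (z_min > z_max) stop("`z_min` must not exceed `z_max`", call. = FALSE)
  support <- seq.int(z_min, z_max)
  raw <- stats::pnorm((support + 0.5 - mu_t) / sigma_t) -
         stats::pnorm((support - 0.5 - mu_t) / sigma_t)
  tot <- sum(raw)
  if (tot < .MIN_MASS)
    stop("discretised predictive has no mass on the support; check mu/sigma",
         call. = FALSE)
  structure(list(support = support, mass = raw / tot,
                 mu = mu_t, sigma = sigma_t),
            class = "discretized_predictive")
}

# Current discretised predictive of a sleep state.
sleep_predictive <- function(state) {
  post <- normal_posterior(state)
  discretize_predictive(post$mu, sqrt(post$pred_var), state$z_min, state$z_max)
}

#' Surprisal of a sleep report under the current predictive
#'
#' The report is rounded half-up to the nearest integer hour (matching
#' the half-integer discretisation bins) and scored as the negative log
#' of the discretised predictive mass at that integer.
#'
#' @param obs_hours Reported hours slept (non-negative).
#' @param state A [normal_mean_state()].
#' @param log_base `"e"` (nats) or `"2"` (bits).
#' @return Surprisal of the rounded report.
#' @export
sleep_surprisal <- function(obs_hours, state, log_base = c("e", "2")) {
  log_base <- match.arg(log_base)
  surprisal_guarded(predictive_mass(state, obs_hours), log_base,
                    context = "sleep report")
}

# Mass of the discretised bin containing a (rounded) sleep report.
mass_at_hour <- function(dpred, obs_hours) {
  z <- round_half_up(obs_hours)
  i <- match(z, dpred$support)
  if (is.na(i)) 0 else dpred$mass[i]
}

#' @export
predictive_mass.normal_mean_state <- function(state, x, ...) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0))
    stop("sleep observation must be a non-negative number of hours",
         call. = FALSE)
  mass_at_hour(sleep_predictive(state), x)
}

#' @export
update_state.normal_mean_state <- function(state, x, ...) {
  update_normal_mean(state, x)
}

#' @export
expected_value.normal_mean_state <- function(state, ...) {
  d <- sleep_predictive(state)
  sum(d$support * d$mass)
}

#' @export
n_observed.normal_mean_state <- function(state) state$n

#' @export
print.normal_mean_state <- function(x, ...) {
  post <- normal_posterior(x)
  cat(sprintf("Normal mean state: mu ~ N(%.3f, %.3f) after n = %d obs; obs_var = %.3f; predictive N(%.3f, %.3f) on [%d, %d] h\n",
              post$mu, post$var_mu, x$n, x$obs_var, post$mu, post$pred_var,
              x$z_min, x$z_max))
  invisible(x)
}
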
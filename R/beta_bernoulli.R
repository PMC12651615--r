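#' Beta-Bernoulli state for a binary daily exposure
#'
#' Conjugate model for a daily 0/1 exposure (e.g. whether a formal
#' exercise session took place). With prior \eqn{Beta(\alpha, \beta)} and
#' `k` exposures observed over `t` days, the posterior is
#' \eqn{Beta(\alpha + k, \beta + t - k)} and the posterior predictive
#' probability of exposure on the next day is
#' \eqn{(\alpha + k) / (\alpha + \beta + t)}. The prior hyperparameters
#' and the accumulated counts are carried separately.
#'
#' @param alpha,beta Positive Beta prior hyperparameters.
#' @param k Number of exposure days observed so far (default 0).
#' @param t Number of days observed so far (default 0); `k <= t`.
#' @return An object of class `beta_bernoulli_state`.
#' @examples
#' st <- beta_bernoulli_state(1, 1)   # flat prior
#' bernoulli_predictive(st)           # 0.5 before any data
#' @export
beta_bernoulli_state <- function(alpha, beta, k = 0L, t = 0L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha > 0,
            is.numeric(beta), length(beta) == 1L, is.finite(beta), beta > 0,
            is_count(k), is_count(t))
  if (k > t) stop("`k` (exposures) cannot exceed `t` (days observed)",
                  call. = FALSE)
  structure(list(alpha = alpha, beta = beta, k = as.integer(k),
                 t = as.integer(t)),
            class = "beta_bernoulli_state")
}

#' Posterior predictive probability of a binary exposure
#'
#' @param state A [beta_bernoulli_state()].
#' @return The probability \eqn{(\alpha + k) / (\alpha + \beta + t)} that
#'   the next day is an exposure day.
#' @export
bernoulli_predictive <- function(state) {
  stopifnot(inherits(state, "beta_bernoulli_state"))
  (state$alpha + state$k) / (state$alpha + state$beta + state$t)
}

#' Absorb one binary observation
#'
#' @param state A [beta_bernoulli_state()].
#' @param obs 0 or 1.
#' @return The updated state: `k` incremented by `obs`, `t` by one; the
#'   prior hyperparameters are unchanged.
#' @export
update_bernoulli <- function(state, obs) {
  stopifnot(inherits(state, "beta_bernoulli_state"))
  if (!(is.numeric(obs) && length(obs) == 1L && !is.na(obs) && obs %in% c(0, 1)))
    stop("binary observation must be 0 or 1, got ", deparse(obs), call. = FALSE)
  beta_bernoulli_state(state$alpha, state$beta, state$k + as.integer(obs),
                       state$t + 1L)
}

#' @export
predictive_mass.beta_bernoulli_state <- function(state, x, ...) {
  if (!(is.numeric(x) && length(x) == 1L && !is.na(x) && x %in% c(0, 1)))
    stop("binary observation must be 0 or 1, got ", deparse(x), call. = FALSE)
  p <- bernoulli_predictive(state)
  if (x == 1) p else 1 - p
}

#' @export
update_state.beta_bernoulli_state <- function(state, x, ...) {
  update_bernoulli(state, x)
}

#' @export
expected_value.beta_bernoulli_state <- function(state, ...) {
  bernoulli_predictive(state)
}

#' @export
n_observed.beta_bernoulli_state <- function(state) state$t

#' @export
print.beta_bernoulli_state <- function(x, ...) {
  cat(sprintf("Beta-Bernoulli state: Beta(%.4g, %.4g), k = %d of t = %d days; predictive P(x = 1) = %.4f\n",
              x$alpha, x$beta, x$k, x$t, bernoulli_predictive(x)))
  invisible(x)
}
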
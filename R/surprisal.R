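#' Surprisal (self-information) of a predictive probability
#'
#' Surprisal quantifies how unexpected an observed event is under a
#' predictive distribution: \eqn{S(x) = -\log P(x)}. An event that was
#' certain (\eqn{P = 1}) carries no information; rarer events carry more.
#'
#' @param p Predictive probability mass of the observed event. Must lie in
#'   \eqn{(0, 1]}; a zero or negative value signals an invalid probability
#'   mass (for example an unclipped empirical zero) and is an error.
#' @param log_base Logarithm base: `"e"` for nats (default) or `"2"` for
#'   bits.
#' @return Non-negative numeric vector of surprisal values, in nats or
#'   bits.
#' @examples
#' surprisal(1)            # 0: certainty carries no information
#' surprisal(0.5)          # log(2) nats
#' surprisal(0.25, "2")    # 2 bits
#' @export
surprisal <- function(p, log_base = c("e", "2")) {
  log_base <- match.arg(log_base)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("`p` must be a probability mass in (0, 1]; got ",
         paste(utils::head(p[!is.finite(p) | p <= 0 | p > 1], 3), collapse = ", "),
         call. = FALSE)
  }
  s <- -log(p)
  if (log_base == "2") s <- s / log(2)
  s
}

# Overflow-guarded surprisal for model-internal use: probability masses can
# underflow to (numerical) zero for far-tail observations even though the
# model assigns them positive mass. Those are mapped to the surprisal of
# the smallest representable mass, with a warning, rather than Inf.
.MIN_MASS <- 1e-300

surprisal_guarded <- function(p, log_base = "e", context = "observation") {
  if (any(p < .MIN_MASS)) {
    warning("predictive mass underflow for ", context,
            "; reporting surprisal of mass 1e-300", call. = FALSE)
    p <- pmax(p, .MIN_MASS)
  }
  surprisal(p, log_base)
}

#' Predictive-state contract
#'
#' Every sequential model in the package (Beta-Bernoulli for binary
#' exposures, known-variance Normal mean updating for sleep, hurdle-Gamma
#' for stress) implements three generics: the probability mass the current
#' predictive distribution assigns to an observation, the expectation of
#' the next observation, and the state obtained by absorbing one
#' observation. [run_prequential()] drives any state obeying this
#' contract.
#'
#' @param state A predictive state object.
#' @param x A single observation on the variable's scale.
#' @param ... Passed to methods.
#' @return `predictive_mass()`: a probability in \eqn{[0, 1]};
#'   `expected_value()`: the predictive mean; `update_state()`: a state of
#'   the same class with one more observation absorbed; `n_observed()`:
#'   the number of observations absorbed so far.
#' @name predictive-state
NULL

#' @rdname predictive-state
#' @export
predictive_mass <- function(state, x, ...) UseMethod("predictive_mass")

#' @rdname predictive-state
#' @export
update_state <- function(state, x, ...) UseMethod("update_state")

#' @rdname predictive-state
#' @export
expected_value <- function(state, ...) UseMethod("expected_value")

#' @rdname predictive-state
#' @export
n_observed <- function(state) UseMethod("n_observed")

#' Prequential (day-by-day) surprisal trajectory
#'
#' Runs a predictive state through an ordered record of daily
#' observations. By default each non-missing day `t` is scored under the
#' predictive distribution formed from days `1..t-1` (day 1 is scored
#' under the prior predictive) and the state is then updated with the
#' day's observation — strict one-step-ahead scoring. With
#' `include_current = TRUE` the state is updated first, so day `t` is
#' scored under the posterior through day `t`; this is the conditioning
#' used when comparing against the full-record hindsight benchmark, which
#' itself conditions on the scored day (see [static_reference()]).
#'
#' Missing observations (`NA`) emit no surprisal and trigger no update. A
#' complete 28-day record therefore yields exactly 28 surprisal values.
#'
#' @param observations Numeric vector of daily observations in day order;
#'   `NA` marks a missing day.
#' @param state Initial predictive state (a valid prior state with no
#'   observations absorbed).
#' @param log_base Logarithm base for surprisal, `"e"` (nats) or `"2"`.
#' @param include_current Score day `t` under the posterior through day
#'   `t` instead of `t - 1`. Default `FALSE`.
#' @param days Optional integer day indices (strictly increasing, no
#'   duplicates); defaults to `seq_along(observations)`.
#' @return An object of class `surprisal_trajectory`: a data frame with
#'   one row per non-missing day and columns `day`, `observed`,
#'   `pred_mass`, `surprisal`, `expectation`. The final state is attached
#'   as attribute `"state"`.
#' @examples
#' st <- beta_bernoulli_state(1, 1)
#' run_prequential(c(1, NA, 0), st)
#' @export
run_prequential <- function(observations, state, log_base = c("e", "2"),
                            include_current = FALSE,
                            days = seq_along(observations)) {
  log_base <- match.arg(log_base)
  if (length(days) != length(observations))
    stop("`days` must have one entry per observation", call. = FALSE)
  if (length(days) > 1L && any(diff(days) <= 0))
    stop("day indices must be strictly increasing with no duplicates",
         call. = FALSE)

  keep <- which(!is.na(observations))
  out <- data.frame(day = integer(0), observed = numeric(0),
                    pred_mass = numeric(0), surprisal = numeric(0),
                    expectation = numeric(0))
  rows <- vector("list", length(keep))
  for (idx in seq_along(keep)) {
    j <- keep[idx]
    x <- observations[j]
    if (include_current) {
      state <- update_state(state, x)
      p <- predictive_mass(state, x)
      e <- expected_value(state)
    } else {
      p <- predictive_mass(state, x)
      e <- expected_value(state)
      state <- update_state(state, x)
    }
    rows[[idx]] <- data.frame(day = as.integer(days[j]), observed = x,
                              pred_mass = p,
                              surprisal = surprisal_guarded(
                                p, log_base,
                                context = paste0("day ", days[j])),
                              expectation = e)
  }
  if (length(rows)) out <- do.call(rbind, rows)
  class(out) <- c("surprisal_trajectory", "data.frame")
  attr(out, "state") <- state
  attr(out, "log_base") <- log_base
  out
}
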
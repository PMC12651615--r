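#' Configuration for a synthetic diary cohort
#'
#' Describes the population a synthetic daily-diary cohort is drawn from.
#' Defaults emulate the study conditions the models assume: roughly 100
#' participants observed for 28 days; per-person exercise probabilities
#' drawn from a Beta with mean 0.25 (exercise on a quarter of days at the
#' group level); per-person mean sleep centred at 7 h with 1 h
#' between-person SD and integer-heaped reports with 1 h within-person
#' SD; and per-person hurdle-Gamma stress with a mean zero-day
#' probability of 0.3 and Gamma magnitude centred at shape 2, rate 0.1
#' (mean 20 intensity units) with lognormal between-person dispersion.
#'
#' @param n_participants Number of participants (default 100).
#' @param n_days Diary length in days (default 28).
#' @param seed Integer seed; the generator is fully deterministic given
#'   the config.
#' @param exercise_alpha,exercise_beta Population Beta for per-person
#'   exercise probabilities (default Beta(2, 6), mean 0.25).
#' @param sleep_mean Population mean sleep, hours (default 7).
#' @param sleep_between_sd Between-person SD of mean sleep, hours
#'   (default 1).
#' @param sleep_within_sd Within-person (night-to-night) SD, hours
#'   (default 1).
#' @param stress_zero_alpha,stress_zero_beta Population Beta for
#'   per-person zero-stress-day probabilities (default Beta(3, 7), mean
#'   0.3).
#' @param stress_shape,stress_rate Population centres of the per-person
#'   Gamma shape and rate (default 2 and 0.1).
#' @param stress_log_sd Between-person SD of log shape and log rate
#'   (default 0.3).
#' @param missing_rate Probability each cell is missing, independently
#'   (default 0; missing-completely-at-random only).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 100L, n_days = 28L, seed = 1L,
                          exercise_alpha = 2, exercise_beta = 6,
                          sleep_mean = 7, sleep_between_sd = 1,
                          sleep_within_sd = 1,
                          stress_zero_alpha = 3, stress_zero_beta = 7,
                          stress_shape = 2, stress_rate = 0.1,
                          stress_log_sd = 0.3,
                          missing_rate = 0) {
  stopifnot(is_count(n_participants), is_count(n_days), n_days >= 1,
            is.numeric(seed), length(seed) == 1L,
            exercise_alpha > 0, exercise_beta > 0,
            is.finite(sleep_mean), sleep_between_sd >= 0, sleep_within_sd > 0,
            stress_zero_alpha > 0, stress_zero_beta > 0,
            stress_shape > 0, stress_rate > 0, stress_log_sd >= 0,
            is_scalar_prob(missing_rate))
  structure(list(n_participants = as.integer(n_participants),
                 n_days = as.integer(n_days), seed = as.integer(seed),
                 exercise_alpha = exercise_alpha,
                 exercise_beta = exercise_beta,
                 sleep_mean = sleep_mean,
                 sleep_between_sd = sleep_between_sd,
                 sleep_within_sd = sleep_within_sd,
                 stress_zero_alpha = stress_zero_alpha,
                 stress_zero_beta = stress_zero_beta,
                 stress_shape = stress_shape, stress_rate = stress_rate,
                 stress_log_sd = stress_log_sd,
                 missing_rate = missing_rate),
            class = "cohort_config")
}

#' Simulate a synthetic daily-diary cohort
#'
#' Draws per-person latent parameters from the population distributions
#' in the config, then daily observations: exercise ~ Bernoulli(p_i),
#' sleep ~ Normal(mu_i, sd_w) truncated at 0 and rounded half-up to
#' integer hours, stress ~ hurdle-Gamma (zero with probability p0_i, else
#' Gamma(shape_i, rate_i)). Missingness, if configured, is applied
#' independently per cell. The per-person latent parameters are attached
#' as attribute `"latent"` for parameter-recovery studies.
#'
#' @param config A [cohort_config()].
#' @return A long-format data frame of class `diary_dataset` with columns
#'   `participant_id`, `day`, `stress`, `sleep_hours`, `exercise`
#'   (missing cells are `NA`).
#' @examples
#' d <- simulate_cohort(cohort_config(n_participants = 3, n_days = 5))
#' head(d)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  np <- config$n_participants
  nd <- config$n_days
  empty <- data.frame(participant_id = character(0), day = integer(0),
                      stress = numeric(0), sleep_hours = numeric(0),
                      exercise = numeric(0))
  if (np == 0L) {
    class(empty) <- c("diary_dataset", "data.frame")
    return(empty)
  }
  set.seed(config$seed)
  ids <- sprintf("P%03d", seq_len(np))
  latent <- data.frame(
    participant_id = ids,
    p_exercise = stats::rbeta(np, config$exercise_alpha, config$exercise_beta),
    mu_sleep = stats::rnorm(np, config$sleep_mean, config$sleep_between_sd),
    p_zero = stats::rbeta(np, config$stress_zero_alpha, config$stress_zero_beta),
    shape = config$stress_shape * exp(stats::rnorm(np, 0, config$stress_log_sd)),
    rate = config$stress_rate * exp(stats::rnorm(np, 0, config$stress_log_sd)))

  rows <- lapply(seq_len(np), function(i) {
    exercise <- stats::rbinom(nd, 1, latent$p_exercise[i])
    sleep <- round_half_up(pmax(0, stats::rnorm(nd, latent$mu_sleep[i],
                                                config$sleep_within_sd)))
    zero <- stats::rbinom(nd, 1, latent$p_zero[i]) == 1
    stress <- ifelse(zero, 0,
                     stats::rgamma(nd, shape = latent$shape[i],
                                   rate = latent$rate[i]))
    data.frame(participant_id = ids[i], day = seq_len(nd),
               stress = stress, sleep_hours = as.numeric(sleep),
               exercise = as.numeric(exercise))
  })
  out <- do.call(rbind, rows)
  if (config$missing_rate > 0) {
    for (col in c("stress", "sleep_hours", "exercise")) {
      out[[col]][stats::runif(nrow(out)) < config$missing_rate] <- NA
    }
  }
  rownames(out) <- NULL
  attr(out, "latent") <- latent
  class(out) <- c("diary_dataset", "data.frame")
  out
}
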
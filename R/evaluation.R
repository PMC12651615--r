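#' Static full-record empirical surprisal benchmark
#'
#' Fits a distribution of the same family as the dynamic model to a
#' participant's complete record (hindsight) and scores every observation
#' against it. Exercise uses the Bernoulli MLE \eqn{\hat{p} = k/T},
#' clipped to \eqn{[1/(2T), 1 - 1/(2T)]} so that all-zero or all-one
#' records still yield finite surprisal. Sleep uses the Normal MLE (mean
#' and variance, variance floored) discretised to integer hours. Stress
#' uses the empirical zero rate (clipped likewise) with a Gamma MLE on
#' the nonzero values, binned exactly as the dynamic stress predictive.
#'
#' @param record Numeric vector of a participant's daily observations in
#'   day order; `NA` marks missing days (they receive no surprisal).
#' @param variable One of `"exercise"`, `"sleep"`, `"stress"`.
#' @param log_base `"e"` (nats) or `"2"` (bits).
#' @param var_floor Variance floor for constant sleep records (default
#'   0.25 h²).
#' @param bin_width,support_max Stress binning (see
#'   [stress_predictive()]).
#' @param days Optional day indices, as in [run_prequential()].
#' @return An object of class `static_reference`: list with `variable`,
#'   `fit` (the fitted parameters), and `surprisal` (data frame `day`,
#'   `observed`, `surprisal`).
#' @export
static_reference <- function(record, variable = c("exercise", "sleep", "stress"),
                             log_base = c("e", "2"), var_floor = 0.25,
                             bin_width = 1, support_max = 60,
                             days = seq_along(record)) {
  variable <- match.arg(variable)
  log_base <- match.arg(log_base)
  if (length(days) != length(record))
    stop("`days` must have one entry per observation", call. = FALSE)
  keep <- !is.na(record)
  obs <- record[keep]
  d <- as.integer(days[keep])
  n <- length(obs)
  if (n == 0L) stop("record has no non-missing observations", call. = FALSE)

  if (variable == "exercise") {
    if (!all(obs %in% c(0, 1)))
      stop("exercise record must be binary", call. = FALSE)
    p_hat <- clip(sum(obs) / n, 1 / (2 * n), 1 - 1 / (2 * n))
    fit <- list(p_hat = p_hat, k = sum(obs), t = n)
    s <- surprisal(ifelse(obs == 1, p_hat, 1 - p_hat), log_base)
  } else if (variable == "sleep") {
    if (any(obs < 0)) stop("sleep record must be non-negative", call. = FALSE)
    m <- mean(obs)
    v <- if (n > 1) stats::var(obs) * (n - 1) / n else 0  # MLE variance
    v <- max(v, var_floor)
    dpred <- discretize_predictive(m, sqrt(v))
    fit <- list(mean = m, var = v, predictive = dpred)
    s <- surprisal_guarded(vapply(obs, function(x) mass_at_hour(dpred, x),
                                  numeric(1)),
                           log_base, context = "static sleep reference")
  } else {
    if (any(obs < 0)) stop("stress record must be non-negative", call. = FALSE)
    pos <- obs[obs > 0]
    if (length(pos) < 2L)
      stop("stress static reference needs at least 2 nonzero values",
           call. = FALSE)
    p0_hat <- clip(sum(obs == 0) / n, 1 / (2 * n), 1 - 1 / (2 * n))
    gm <- gamma_mle(pos)
    n_bins <- max(1L, floor(support_max / bin_width))
    pred <- structure(list(zero_mass = p0_hat, bin_width = bin_width,
                           centers = bin_width * seq_len(n_bins),
                           masses = (1 - p0_hat) *
                             gamma_bin_masses(gm$shape, gm$rate, bin_width,
                                              n_bins)),
                      class = "stress_predictive")
    fit <- list(p_zero = p0_hat, shape = gm$shape, rate = gm$rate,
                predictive = pred)
    s <- vapply(obs, function(x) stress_surprisal(x, pred, log_base),
                numeric(1))
  }
  structure(list(variable = variable, fit = fit,
                 surprisal = data.frame(day = d, observed = obs,
                                        surprisal = s)),
            class = "static_reference")
}

#' @export
print.static_reference <- function(x, ...) {
  cat(sprintf("Static %s reference over %d days; mean surprisal %.3f\n",
              x$variable, nrow(x$surprisal), mean(x$surprisal$surprisal)))
  invisible(x)
}

# Per-day mean, SE and normal-approximation 95% CI of `value` within
# groups; n = 1 days are reported with NA SE/CI (flagged), not dropped.
summarize_by_day <- function(df, value = "value",
                             by = intersect(c("variable", "prior_condition"),
                                            names(df))) {
  stopifnot(is.data.frame(df), "day" %in% names(df), value %in% names(df))
  if (nrow(df) == 0L) stop("nothing to summarize: empty input", call. = FALSE)
  keys <- c(by, "day")
  groups <- split(df, df[keys], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- g[[value]]
    n <- length(v)
    se <- if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_
    row <- g[1, keys, drop = FALSE]
    row$estimate <- mean(v)
    row$se <- se
    row$ci_lo <- row$estimate - 1.96 * se
    row$ci_hi <- row$estimate + 1.96 * se
    row$n <- n
    row
  }))
  out <- out[order(interaction(out[rev(keys)], drop = TRUE)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-day dynamic-minus-static surprisal differences
#'
#' Joins dynamic and static surprisal values on participant, day and any
#' shared grouping columns, and summarises the per-day mean difference
#' across participants with its standard error and normal-approximation
#' 95% confidence interval (half-width 1.96 SE). Days contributed by a
#' single participant are reported with `NA` standard error rather than
#' dropped.
#'
#' @param dynamic,static Data frames with columns `participant_id`,
#'   `day`, `surprisal`, plus optional grouping columns `variable` and
#'   `prior_condition` (grouping columns present in `dynamic` but not
#'   `static` are carried from `dynamic`).
#' @return A data frame of class `difference_trajectory` with columns
#'   (grouping columns,) `day`, `estimate`, `se`, `ci_lo`, `ci_hi`, `n`.
#' @examples
#' dyn <- data.frame(participant_id = c("a", "b", "c"), day = 1,
#'                   surprisal = c(1, 2, 3))
#' sta <- data.frame(participant_id = c("a", "b", "c"), day = 1,
#'                   surprisal = c(2, 4, 6))
#' compare(dyn, sta)
#' @export
compare <- function(dynamic, static) {
  stopifnot(is.data.frame(dynamic), is.data.frame(static))
  need <- c("participant_id", "day", "surprisal")
  if (!all(need %in% names(dynamic)) || !all(need %in% names(static)))
    stop("dynamic and static tables need columns participant_id, day, surprisal",
         call. = FALSE)
  join_keys <- c("participant_id", "day",
                 intersect(intersect(c("variable"), names(dynamic)),
                           names(static)))
  m <- merge(dynamic, static, by = join_keys, suffixes = c("_dyn", "_stat"))
  if (nrow(m) == 0L)
    stop("no matching participant/day keys between dynamic and static tables",
         call. = FALSE)
  m$value <- m$surprisal_dyn - m$surprisal_stat
  carry <- intersect(c("variable", "prior_condition"), names(m))
  out <- summarize_by_day(m[, c(carry, "participant_id", "day", "value")],
                          value = "value", by = carry)
  class(out) <- c("difference_trajectory", "data.frame")
  out
}

#' Per-day cohort summaries of expected values
#'
#' Aggregates per-participant daily expectations (the predictive mean of
#' each model before the day's observation) into a per-day group mean
#' with a normal-approximation 95% confidence interval across
#' participants. These intervals ignore each participant's own posterior
#' uncertainty.
#'
#' @param expectations Data frame with columns `participant_id`, `day`,
#'   `expectation`, plus optional grouping columns `variable` and
#'   `prior_condition`.
#' @return Data frame with per-group, per-day `estimate`, `se`, `ci_lo`,
#'   `ci_hi`, `n`.
#' @export
summarize_expectations <- function(expectations) {
  stopifnot(is.data.frame(expectations))
  if (!all(c("participant_id", "day", "expectation") %in% names(expectations)))
    stop("need columns participant_id, day, expectation", call. = FALSE)
  if (nrow(expectations) == 0L) stop("empty input", call. = FALSE)
  df <- expectations
  df$value <- df$expectation
  summarize_by_day(df, value = "value")
}
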
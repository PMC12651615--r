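variable_column <- c(exercise = "exercise", sleep = "sleep_hours",
                     stress = "stress")

#' Build a prior for one participant and variable
#'
#' For the uninformative condition this is just [uninformative_prior()].
#' For the empirical condition the prior is built from the leave-one-out
#' sample: every participant except the target.
#'
#' @param data A diary dataset (see [read_diary()]).
#' @param variable One of `"exercise"`, `"sleep"`, `"stress"`.
#' @param condition `"uninformative"` or `"empirical"`.
#' @param target_id Participant whose prior is requested (required for
#'   the empirical condition).
#' @return A `prior_spec`.
#' @export
prior_for <- function(data, variable, condition = c("uninformative", "empirical"),
                      target_id = NULL) {
  condition <- match.arg(condition)
  if (condition == "uninformative") return(uninformative_prior(variable))
  if (is.null(target_id))
    stop("empirical priors are leave-one-out: `target_id` is required",
         call. = FALSE)
  loo <- data[data$participant_id != target_id, , drop = FALSE]
  if (nrow(loo) == 0L)
    stop("leave-one-out sample is empty for participant ", target_id,
         call. = FALSE)
  switch(variable,
    exercise = {
      ex <- loo[!is.na(loo$exercise), , drop = FALSE]
      rates <- tapply(ex$exercise, ex$participant_id, mean)
      empirical_prior_exercise(as.numeric(rates))
    },
    sleep = empirical_prior_sleep(loo),
    stress = {
      st <- loo[!is.na(loo$stress), , drop = FALSE]
      zero_rates <- tapply(st$stress, st$participant_id,
                           function(v) mean(v == 0))
      empirical_prior_stress(st$stress[st$stress > 0],
                             as.numeric(zero_rates))
    },
    stop("unknown variable: ", variable, call. = FALSE))
}

#' Dynamic surprisal trajectories for a cohort
#'
#' Runs the prequential engine for every participant, requested variable
#' and prior condition, and returns one tidy table of per-day predictive
#' masses, surprisal values and expectations.
#'
#' @param data A diary dataset.
#' @param variables Subset of `c("exercise", "sleep", "stress")`.
#' @param conditions Subset of `c("uninformative", "empirical")`.
#' @param log_base `"e"` or `"2"`.
#' @param include_current Scoring convention (see [run_prequential()]).
#' @param base_seed Base seed for the stress sampler.
#' @param sampler Stress sampler settings (`n_draws`, `n_warmup`,
#'   `bin_width`, `support_max`).
#' @return Data frame with columns `participant_id`, `variable`,
#'   `prior_condition`, `day`, `observed`, `pred_mass`, `surprisal`,
#'   `expectation`.
#' @export
dynamic_surprisal <- function(data, variables = c("exercise", "sleep", "stress"),
                              conditions = c("uninformative", "empirical"),
                              log_base = "e", include_current = FALSE,
                              base_seed = 1L, sampler = list()) {
  data <- validate_diary(as.data.frame(data))
  ids <- unique(data$participant_id)
  out <- list()
  for (variable in variables) {
    col <- variable_column[[variable]]
    for (condition in conditions) {
      for (i in seq_along(ids)) {
        id <- ids[i]
        rec <- data[data$participant_id == id, , drop = FALSE]
        spec <- withCallingHandlers(
          prior_for(data, variable, condition, target_id = id),
          warning = function(w) {
            message(sprintf("[%s/%s/%s] %s", id, variable, condition,
                            conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
        st <- initial_state(spec, sampler = c(
          sampler, list(base_seed = derive_seed(base_seed, i))))
        traj <- run_prequential(rec[[col]], st, log_base = log_base,
                                include_current = include_current,
                                days = rec$day)
        if (nrow(traj)) {
          traj <- as.data.frame(traj)
          traj$participant_id <- id
          traj$variable <- variable
          traj$prior_condition <- condition
          out[[length(out) + 1L]] <- traj
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(participant_id = character(0), variable = character(0),
                      prior_condition = character(0), day = integer(0),
                      observed = numeric(0), pred_mass = numeric(0),
                      surprisal = numeric(0), expectation = numeric(0)))
  res <- do.call(rbind, out)
  res[, c("participant_id", "variable", "prior_condition", "day",
          "observed", "pred_mass", "surprisal", "expectation")]
}

#' Static full-record surprisal for a cohort
#'
#' @inheritParams dynamic_surprisal
#' @param ... Passed to [static_reference()].
#' @return Data frame with columns `participant_id`, `variable`, `day`,
#'   `observed`, `surprisal`.
#' @export
static_surprisal <- function(data, variables = c("exercise", "sleep", "stress"),
                             log_base = "e", ...) {
  data <- validate_diary(as.data.frame(data))
  out <- list()
  for (variable in variables) {
    col <- variable_column[[variable]]
    for (id in unique(data$participant_id)) {
      rec <- data[data$participant_id == id, , drop = FALSE]
      ref <- static_reference(rec[[col]], variable, log_base = log_base,
                              days = rec$day, ...)
      s <- ref$surprisal
      s$participant_id <- id
      s$variable <- variable
      out[[length(out) + 1L]] <- s
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("participant_id", "variable", "day", "observed", "surprisal")]
}

#' Run the full analysis pipeline
#'
#' Loads or simulates a diary cohort, computes dynamic surprisal and
#' expectation trajectories for every participant, variable and prior
#' condition, fits the static full-record references, and writes tidy
#' result tables plus a JSON run manifest to `out_dir`:
#' `diary.csv`, `trajectories.csv`, `static.csv`,
#' `expectations_by_day.csv`, `surprisal_by_day.csv`,
#' `difference_by_day.csv`, `manifest.json`. Output is bit-identical for
#' a fixed (config, seed) pair.
#'
#' The dynamic-minus-static difference table conditions the dynamic
#' trajectory on the current day (see [run_prequential()]), matching the
#' full-record benchmark, unless `include_current` is set explicitly in
#' the config, in which case that setting is used for both the
#' trajectories table and the difference table.
#'
#' @param config A `run_config` (see [read_run_config()]) or a list
#'   coercible with [as_run_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of the result tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  data <- if (!is.null(config$input)) read_diary(config$input)
          else simulate_cohort(config$simulate)
  write_diary(data, file.path(out_dir, "diary.csv"))

  dyn <- dynamic_surprisal(data, variables = config$variables,
                           conditions = config$priors,
                           log_base = config$log_base,
                           include_current = config$include_current,
                           base_seed = config$seed,
                           sampler = config$sampler)
  sta <- static_surprisal(data, variables = config$variables,
                          log_base = config$log_base,
                          bin_width = config$sampler$bin_width,
                          support_max = config$sampler$support_max)

  expectations <- summarize_expectations(dyn)
  surprisal_by_day <- summarize_by_day(
    transform(dyn, value = surprisal), value = "value")
  difference <- compare(dyn, sta)

  tables <- list(trajectories = dyn, static = sta,
                 expectations_by_day = expectations,
                 surprisal_by_day = surprisal_by_day,
                 difference_by_day = difference)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")

  manifest <- list(
    package = "dsurprisal",
    version = as.character(utils::packageVersion("dsurprisal")),
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    config_hash = config_hash(config),
    n_participants = length(unique(data$participant_id)),
    n_rows = nrow(data))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(tables)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
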
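#' Read and validate a diary CSV
#'
#' The interchange format is one row per participant-day, wide across the
#' three modelled variables: columns `participant_id`, `day`, `stress`,
#' `sleep_hours`, `exercise`. Empty cells are missing. Validation rejects
#' out-of-range values with row-level messages.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame of class `diary_dataset`.
#' @export
read_diary <- function(path) {
  if (!file.exists(path)) stop("diary file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_diary(df)
}

#' @rdname read_diary
#' @param data A diary data frame to validate or write.
#' @export
validate_diary <- function(data) {
  need <- c("participant_id", "day", "stress", "sleep_hours", "exercise")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("diary is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop(what, " in row(s) ", paste(utils::head(idx, 5), collapse = ", "),
           call. = FALSE)
  }
  bad_row(is.na(data$participant_id) | data$participant_id == "",
          "missing participant_id")
  bad_row(!is.na(data$day) & (data$day < 1 | data$day != floor(data$day)),
          "day must be a positive integer")
  bad_row(is.na(data$day), "missing day index")
  key <- paste(data$participant_id, data$day)
  bad_row(duplicated(key), "duplicate (participant, day)")
  bad_row(!is.na(data$exercise) & !(data$exercise %in% c(0, 1)),
          "exercise must be 0, 1, or empty")
  bad_row(!is.na(data$stress) & data$stress < 0, "negative stress value")
  bad_row(!is.na(data$sleep_hours) & data$sleep_hours < 0,
          "negative sleep value")
  data <- data[order(data$participant_id, data$day), , drop = FALSE]
  rownames(data) <- NULL
  class(data) <- unique(c("diary_dataset", class(data)))
  data
}

#' @rdname read_diary
#' @export
write_diary <- function(data, path) {
  data <- validate_diary(as.data.frame(data))
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a run configuration
#'
#' A run configuration is a YAML file declaring either an `input` diary
#' CSV path or a `simulate` block ([cohort_config()] fields) — exactly
#' one of the two — plus the variables to analyse, the prior
#' condition(s), the log base, the base seed, and sampler settings for
#' the stress model.
#'
#' @param path Path to a YAML file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  as_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A list of configuration fields (as from YAML).
#' @export
as_run_config <- function(config) {
  stopifnot(is.list(config))
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim)
    stop("config must declare exactly one of `input` (diary CSV path) or `simulate` (cohort block)",
         call. = FALSE)
  variables <- config$variables %||% c("exercise", "sleep", "stress")
  bad <- setdiff(variables, c("exercise", "sleep", "stress"))
  if (length(bad))
    stop("unknown variable(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  priors <- config$priors %||% c("uninformative", "empirical")
  bad <- setdiff(priors, c("uninformative", "empirical"))
  if (length(bad))
    stop("unknown prior condition(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  log_base <- as.character(config$log_base %||% "e")
  if (!log_base %in% c("e", "2"))
    stop("log_base must be \"e\" or \"2\"", call. = FALSE)
  sampler <- config$sampler %||% list()
  stopifnot(is.list(sampler))
  structure(list(
    input = config$input,
    simulate = if (has_sim) do.call(cohort_config, config$simulate),
    variables = variables,
    priors = priors,
    log_base = log_base,
    include_current = isTRUE(config$include_current),
    seed = as.integer(config$seed %||% 1L),
    sampler = list(n_draws = as.integer(sampler$n_draws %||% 2000L),
                   n_warmup = as.integer(sampler$n_warmup %||% 1000L),
                   bin_width = sampler$bin_width %||% 1,
                   support_max = sampler$support_max %||% 60)),
    class = "run_config")
}
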
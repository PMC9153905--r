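trial_log_columns <- c("session_id", "condition", "trial_index", "block",
                       "trial_type", "go_stimulus", "ssd_programmed_ms",
                       "ssd_meta_ms", "responded", "response_key", "rt_ms",
                       "outcome")

#' Write a trial log to CSV
#'
#' One row per trial with a mandatory header; absent fields (go-trial SSDs,
#' RTs of withheld responses) are written as empty strings. Timing fields
#' are serialized at microsecond (3-decimal) precision — far below any
#' physically meaningful resolution — which keeps write/read/write cycles
#' byte-stable.
#'
#' @param log A trial log from [run_session()]. If it lacks `session_id` /
#'   `condition` columns they are supplied from the arguments.
#' @param path Output CSV path.
#' @param session_id,condition Identifiers used when the log carries none.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path, session_id = "S1", condition = "lab") {
  if (!"session_id" %in% names(log)) log$session_id <- session_id
  if (!"condition" %in% names(log)) log$condition <- condition
  log <- dplyr::select(log, dplyr::all_of(trial_log_columns))
  for (col in c("ssd_programmed_ms", "ssd_meta_ms", "rt_ms")) {
    log[[col]] <- round(log[[col]], 3)
  }
  readr::write_csv(log, path, na = "")
  invisible(path)
}

#' Read and validate a trial log CSV
#'
#' Reads a log written by [write_trial_log()] (round-tripping it
#' byte-identically up to line endings) and enforces the cross-field rules
#' of the schema. Malformed rows are reported with their file line numbers.
#'
#' Validated rules: known `block`/`trial_type`/`outcome` values; `rt_ms`
#' present iff `responded`; `response_key` present iff `responded`; SSD
#' fields present iff the trial is a stop trial; outcome consistent with the
#' trial type; and key accord — a failed stop labelled `correct_key`
#' (respectively `incorrect_key`) must have a response key that does
#' (does not) match the go stimulus, and likewise `go_correct` / `go_error`.
#'
#' @param path CSV path.
#' @return A validated trial-log tibble including `session_id` and
#'   `condition`.
#' @export
read_trial_log <- function(path) {
  log <- readr::read_csv(
    path,
    col_types = readr::cols(
      session_id = readr::col_character(),
      condition = readr::col_character(),
      trial_index = readr::col_integer(),
      block = readr::col_character(),
      trial_type = readr::col_character(),
      go_stimulus = readr::col_character(),
      ssd_programmed_ms = readr::col_double(),
      ssd_meta_ms = readr::col_double(),
      responded = readr::col_logical(),
      response_key = readr::col_character(),
      rt_ms = readr::col_double(),
      outcome = readr::col_character()
    ),
    na = c("", "NA"),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(trial_log_columns, names(log))
  if (length(missing)) {
    stop("Trial log ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_trial_log(log, source = path)
  log
}

#' Validate the cross-field consistency of a trial log
#'
#' @param log A trial-log tibble (see [read_trial_log()] for the rules).
#' @param source Label used in error messages.
#' @return `log`, invisibly, when valid; otherwise an error listing every
#'   offending row (line numbers count the CSV header as line 1).
#' @export
validate_trial_log <- function(log, source = "trial log") {
  go_outcomes <- c("go_correct", "go_error", "go_omission")
  stop_outcomes <- c("stop_inhibited", "stop_failed_correct_key",
                     "stop_failed_incorrect_key")
  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad, na.rm = TRUE)) {
      lines <- which(bad) + 1L # header is line 1
      problems <<- c(problems,
                     paste0(msg, " (line", if (length(lines) > 1) "s" else "",
                            " ", paste(lines, collapse = ", "), ")"))
    }
  }
  is_stop <- log$trial_type == "stop"
  flag(!log$trial_type %in% c("go", "stop"), "unknown trial_type")
  flag(!log$outcome %in% c(go_outcomes, stop_outcomes), "unknown outcome")
  flag(!log$go_stimulus %in% c("X", "O"), "unknown go_stimulus")
  flag(log$responded & is.na(log$rt_ms), "responded without rt_ms")
  flag(!log$responded & !is.na(log$rt_ms), "rt_ms present but responded is FALSE")
  flag(log$responded & is.na(log$response_key),
       "responded without response_key")
  flag(!log$responded & !is.na(log$response_key),
       "response_key present but responded is FALSE")
  flag(is_stop & (is.na(log$ssd_programmed_ms) | is.na(log$ssd_meta_ms)),
       "stop trial without SSD fields")
  flag(!is_stop & (!is.na(log$ssd_programmed_ms) | !is.na(log$ssd_meta_ms)),
       "go trial with SSD fields")
  flag(!is_stop & log$outcome %in% stop_outcomes,
       "stop outcome on a go trial")
  flag(is_stop & log$outcome %in% go_outcomes, "go outcome on a stop trial")
  flag(log$outcome %in% c("go_omission", "stop_inhibited") & log$responded,
       "withheld outcome with responded = TRUE")
  flag(log$outcome %in% c("go_correct", "go_error", "stop_failed_correct_key",
                          "stop_failed_incorrect_key") & !log$responded,
       "response outcome with responded = FALSE")
  flag(log$outcome %in% c("go_correct", "stop_failed_correct_key") &
         log$responded & log$response_key != log$go_stimulus,
       "correct-key outcome but response_key differs from go_stimulus")
  flag(log$outcome %in% c("go_error", "stop_failed_incorrect_key") &
         log$responded & log$response_key == log$go_stimulus,
       "incorrect-key outcome but response_key matches go_stimulus")
  if (length(problems)) {
    stop("Invalid ", source, ":\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(log)
}
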
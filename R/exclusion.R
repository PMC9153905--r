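#' Apply session-level exclusion rules
#'
#' Evaluates the standard participant-level validity rules on scored
#' sessions. A session is excluded when any of the following holds, each
#' inequality strict (boundary values retain):
#' \itemize{
#'   \item race-model violation: mean RT of correct-key (or, separately,
#'     incorrect-key) failed stops greater than the mean go RT;
#'   \item stop accuracy below 25\% or above 75\%;
#'   \item go errors above 10\% of go trials;
#'   \item SSRT below 50 ms.
#' }
#' A failed-stop stratum with no trials (RT mean `NA`) skips its race rule.
#'
#' @param metrics A metrics tibble from [score_session()] or
#'   [score_sessions()]; extra identifying columns are carried through.
#' @return The identifying columns plus `excluded` (logical) and `reasons`
#'   (comma-separated rule identifiers, empty when retained).
#' @examples
#' m <- tibble::tibble(go_rt_mean = 500, go_errors = 2, stop_accuracy = 24,
#'                     ssrt = 240, failed_stop_correct_key_rt_mean = 450,
#'                     failed_stop_incorrect_key_rt_mean = NA_real_)
#' apply_exclusion(m)
#' @export
apply_exclusion <- function(metrics) {
  needed <- c("go_rt_mean", "go_errors", "stop_accuracy", "ssrt",
              "failed_stop_correct_key_rt_mean",
              "failed_stop_incorrect_key_rt_mean")
  missing <- setdiff(needed, names(metrics))
  if (length(missing)) {
    stop("Metrics are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rule <- function(cond) !is.na(cond) & cond
  flags <- tibble::tibble(
    race_violation_correct_key =
      rule(metrics$failed_stop_correct_key_rt_mean > metrics$go_rt_mean),
    race_violation_incorrect_key =
      rule(metrics$failed_stop_incorrect_key_rt_mean > metrics$go_rt_mean),
    stop_accuracy_low = rule(metrics$stop_accuracy < 25),
    stop_accuracy_high = rule(metrics$stop_accuracy > 75),
    go_errors_high = rule(metrics$go_errors > 10),
    ssrt_low = rule(metrics$ssrt < 50)
  )
  reasons <- apply(flags, 1, function(row) {
    paste(names(flags)[row], collapse = ",")
  })
  keys <- setdiff(names(metrics), c(needed, "go_accuracy", "go_omissions",
                                    "go_error_rt_mean", "intraindividual_sd",
                                    "ssd_programmed_mean", "ssd_meta_mean",
                                    "n_go", "n_stop"))
  out <- dplyr::bind_cols(
    metrics[keys],
    tibble::tibble(excluded = reasons != "", reasons = reasons)
  )
  tibble::as_tibble(out)
}

#' Keep only participants with two clean sessions
#'
#' Study-level filter for the two-condition within-subject design:
#' a participant is retained iff both sessions are present and neither was
#' excluded. Participants with a single session are reported with reason
#' `incomplete_pair`.
#'
#' @param reports An exclusion report from [apply_exclusion()] carrying
#'   `participant_id` and `condition` columns.
#' @return A tibble with one row per participant: `participant_id`,
#'   `retained`, and `reasons` (the union of session-level reasons, plus
#'   `incomplete_pair` where applicable).
#' @examples
#' r <- tibble::tibble(participant_id = c("a", "a", "b"),
#'                     condition = c("lab", "independent", "lab"),
#'                     excluded = c(FALSE, FALSE, FALSE),
#'                     reasons = c("", "", ""))
#' pair_filter(r)
#' @export
pair_filter <- function(reports) {
  needed <- c("participant_id", "condition", "excluded", "reasons")
  missing <- setdiff(needed, names(reports))
  if (length(missing)) {
    stop("Reports are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(reports[c("participant_id", "condition")])
  if (any(dup)) {
    stop("Duplicate (participant_id, condition) rows: ",
         paste(unique(reports$participant_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  reports |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      any_excluded = any(excluded),
      reasons = {
        rs <- unlist(strsplit(reasons[reasons != ""], ","))
        if (dplyr::n() < 2) rs <- c(rs, "incomplete_pair")
        paste(unique(rs), collapse = ",")
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(retained = n_sessions == 2 & !any_excluded) |>
    dplyr::select(participant_id, retained, reasons)
}
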
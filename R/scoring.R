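#' Mean-method stop-signal reaction time
#'
#' The mean method estimates the latency of the inhibitory process as the
#' mean go RT minus the mean stop-signal delay. The difference may be
#' negative for degenerate sessions; the exclusion rules handle that
#' downstream rather than this function.
#'
#' @param go_rt_mean Mean go RT in ms.
#' @param ssd_mean Mean SSD in ms.
#' @return SSRT in ms.
#' @examples
#' compute_ssrt(485.56, 223.11) # 262.45
#' @export
compute_ssrt <- function(go_rt_mean, ssd_mean) {
  if (!all(is.finite(go_rt_mean)) || !all(is.finite(ssd_mean))) {
    stop("`go_rt_mean` and `ssd_mean` must be finite.", call. = FALSE)
  }
  go_rt_mean - ssd_mean
}

#' Score one session into the standard variable battery
#'
#' Reduces an experimental trial log to the session-level variables used to
#' characterise stop-signal performance: go accuracy / omissions / errors
#' (percent of go trials), mean correct-go RT and its within-session SD
#' (intraindividual SD, n-1 denominator), mean wrong-key go RT, stop
#' accuracy (percent of stop trials), mean programmed and meta (clock-
#' measured) SSD, failed-stop RT means split by whether the pressed key
#' matched the stimulus, and the mean-method SSRT.
#'
#' Practice trials are dropped before scoring. Omissions contribute no RT to
#' any mean. RT means over empty strata (e.g. no wrong-key failed stops)
#' are `NA`, meaning "no such trials", never 0.
#'
#' @param results A trial log from [run_session()] or [read_trial_log()].
#' @param ssd_source Which SSD mean enters the SSRT: the clock-measured
#'   `"meta"` value (default) or the `"programmed"` staircase value.
#' @param include_error_rts If `TRUE` wrong-key go RTs are pooled into
#'   `go_rt_mean` (and its SD); by default the main mean uses correct
#'   responses only and wrong-key RTs are reported separately.
#' @return A one-row tibble with the fields above plus `n_go` and `n_stop`.
#'   `go_accuracy + go_omissions + go_errors` is 100 up to rounding, and
#'   `ssrt = go_rt_mean - ssd_mean` exactly.
#' @examples
#' cfg <- session_config()
#' log <- run_session(generate_schedule(cfg, seed = 1),
#'                    participant_params(), config = cfg, seed = 1)
#' score_session(log)
#' @export
score_session <- function(results, ssd_source = c("meta", "programmed"),
                          include_error_rts = FALSE) {
  ssd_source <- match.arg(ssd_source)
  needed <- c("block", "trial_type", "ssd_programmed_ms", "ssd_meta_ms",
              "rt_ms", "outcome")
  missing <- setdiff(needed, names(results))
  if (length(missing)) {
    stop("Trial log is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  exp_rows <- results[as.character(results$block) != "practice", ]
  go <- exp_rows[exp_rows$trial_type == "go", ]
  stop_rows <- exp_rows[exp_rows$trial_type == "stop", ]
  if (nrow(go) == 0) {
    stop("Cannot score: no experimental go trials in the log.", call. = FALSE)
  }
  if (nrow(stop_rows) == 0) {
    stop("Cannot score: no experimental stop trials in the log.", call. = FALSE)
  }

  n_go <- nrow(go)
  n_stop <- nrow(stop_rows)
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  sd_or_na <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_

  correct_rt <- go$rt_ms[go$outcome == "go_correct"]
  error_rt <- go$rt_ms[go$outcome == "go_error"]
  main_rt <- if (include_error_rts) c(correct_rt, error_rt) else correct_rt

  ssd_mean <- if (ssd_source == "meta") {
    mean(stop_rows$ssd_meta_ms)
  } else {
    mean(stop_rows$ssd_programmed_ms)
  }
  go_rt_mean <- mean_or_na(main_rt)

  tibble::tibble(
    go_accuracy = 100 * sum(go$outcome == "go_correct") / n_go,
    go_omissions = 100 * sum(go$outcome == "go_omission") / n_go,
    go_errors = 100 * sum(go$outcome == "go_error") / n_go,
    go_rt_mean = go_rt_mean,
    go_error_rt_mean = mean_or_na(error_rt),
    intraindividual_sd = sd_or_na(main_rt),
    stop_accuracy = 100 * sum(stop_rows$outcome == "stop_inhibited") / n_stop,
    ssd_programmed_mean = mean(stop_rows$ssd_programmed_ms),
    ssd_meta_mean = mean(stop_rows$ssd_meta_ms),
    failed_stop_correct_key_rt_mean =
      mean_or_na(stop_rows$rt_ms[stop_rows$outcome == "stop_failed_correct_key"]),
    failed_stop_incorrect_key_rt_mean =
      mean_or_na(stop_rows$rt_ms[stop_rows$outcome == "stop_failed_incorrect_key"]),
    ssrt = compute_ssrt(go_rt_mean, ssd_mean),
    n_go = n_go,
    n_stop = n_stop
  )
}

#' Score many sessions at once
#'
#' @param logs A tibble of trial rows for several sessions, carrying
#'   `session_id` (and optionally `participant_id`, `session`, `condition`,
#'   `order`) alongside the trial-log columns.
#' @inheritParams score_session
#' @return A tibble with one metrics row per session, keyed by the
#'   identifying columns present in `logs`.
#' @export
score_sessions <- function(logs, ssd_source = c("meta", "programmed"),
                           include_error_rts = FALSE) {
  ssd_source <- match.arg(ssd_source)
  if (!"session_id" %in% names(logs)) {
    stop("`logs` must carry a `session_id` column.", call. = FALSE)
  }
  keys <- intersect(c("session_id", "participant_id", "session", "condition",
                      "order"), names(logs))
  logs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ score_session(.x, ssd_source = ssd_source,
                                        include_error_rts = include_error_rts)) |>
    dplyr::ungroup()
}
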
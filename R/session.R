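#' Run one simulated session of the stop-signal task
#'
#' Drives a synthetic participant through a trial schedule, advancing the
#' SSD staircase on every stop trial. On stop trials the staircase supplies
#' the programmed SSD, the clock model perturbs it into the meta-SSD
#' actually realised on screen, and the horse race is run against that
#' realised delay. The staircase runs during practice as well; by default it
#' resets to the initial SSD at the start of the first experimental block so
#' that experimental sessions are comparable (see
#' [session_config()]`$carry_practice_ssd`).
#'
#' @param schedule A schedule tibble from [generate_schedule()].
#' @param participant A [participant_params()] (or coercible list/one-row
#'   data frame).
#' @param clock A [clock_model()]; the default adds no jitter, making meta
#'   and programmed SSD identical.
#' @param config The [session_config()] used to build the schedule.
#' @param seed Integer seed; identical seeds give identical logs.
#' @return A tibble of class `sst_trial_log`, one row per trial:
#'   `trial_index`, `block`, `trial_type`, `go_stimulus`,
#'   `ssd_programmed_ms`, `ssd_meta_ms` (NA on go trials), `responded`,
#'   `response_key`, `rt_ms`, `outcome`.
#' @examples
#' cfg <- session_config()
#' log <- run_session(generate_schedule(cfg, seed = 1),
#'                    participant_params(), config = cfg, seed = 1)
#' table(log$outcome)
#' @export
run_session <- function(schedule, participant, clock = clock_model(),
                        config = session_config(), seed = 1L) {
  participant <- as_participant(participant)
  stopifnot(inherits(clock, "sst_clock"))
  validate_session_config(config)
  required <- c("trial_index", "block", "trial_type", "go_stimulus")
  missing <- setdiff(required, names(schedule))
  if (length(missing)) {
    stop("Schedule is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- nrow(schedule)
  window <- config$stimulus_duration
  state <- staircase_state(config$initial_ssd, config$ssd_step,
                           config$ssd_floor, config$ssd_ceiling)

  ssd_prog <- rep(NA_real_, n)
  ssd_meta <- rep(NA_real_, n)
  responded <- logical(n)
  key <- rep(NA_character_, n)
  rt <- rep(NA_real_, n)
  outcome <- character(n)

  block <- as.character(schedule$block)
  in_practice_prev <- NA
  for (i in seq_len(n)) {
    if (!config$carry_practice_ssd &&
        identical(in_practice_prev, "practice") && block[i] != "practice") {
      state <- staircase_state(config$initial_ssd, config$ssd_step,
                               config$ssd_floor, config$ssd_ceiling)
    }
    in_practice_prev <- block[i]
    stim <- schedule$go_stimulus[i]
    if (schedule$trial_type[i] == "stop") {
      ssd_prog[i] <- state$current_ssd
      ssd_meta[i] <- apply_clock(state$current_ssd, clock)
      res <- sample_stop_outcome(participant, ssd = ssd_meta[i],
                                 stimulus = stim, window = window)
      state <- update_ssd(state,
                          if (res$responded) "responded" else "inhibited")
    } else {
      res <- sample_go_response(participant, stimulus = stim, window = window)
    }
    responded[i] <- res$responded
    key[i] <- res$response_key
    rt[i] <- res$rt
    outcome[i] <- res$outcome
  }

  out <- tibble::tibble(
    trial_index = schedule$trial_index,
    block = schedule$block,
    trial_type = schedule$trial_type,
    go_stimulus = schedule$go_stimulus,
    ssd_programmed_ms = ssd_prog,
    ssd_meta_ms = ssd_meta,
    responded = responded,
    response_key = key,
    rt_ms = rt,
    outcome = outcome
  )
  class(out) <- c("sst_trial_log", class(out))
  out
}

feedback_messages <- c(
  get_ready = "white", go_prompt_x = "white", go_prompt_o = "white",
  stop_prompt = "white", wait = "white",
  hit = "green", hit_too_slow = "yellow",
  miss_omission = "red", miss_incorrect_key = "red",
  stop_success = "green", stop_fail = "red",
  omission_warning = "red",
  summary_go_errors = "white", summary_go_misses = "white",
  summary_mean_rt = "white", summary_stop_pct = "white",
  summary_countdown = "white"
)

#' Derive the feedback events a session would have displayed
#'
#' Reconstructs the task's feedback stream from a trial log: one outcome
#' message per practice trial (Hit in green below the slow-RT threshold,
#' Hit-but-faster in yellow at or above it, Miss variants in red, and the
#' stop-success/stop-fail messages), a red warning at every third
#' consecutive go omission in any block, and five block-summary items at
#' the end of every block (go error count, go miss count, mean go RT — with
#' the "Too slow! Respond faster" variant when the block's mean correct-go
#' RT is at or above the threshold — stop accuracy percent, and the
#' 10-second countdown).
#'
#' Consecutive-omission counting follows the task's wording literally:
#' only go trials advance or reset the counter, so an intervening stop
#' trial does not reset it.
#'
#' @param results A trial log from [run_session()] (or [read_trial_log()]),
#'   ordered by `trial_index`.
#' @param config The [session_config()] in force.
#' @return A tibble of events: `trial_index` (NA for block summaries),
#'   `block`, `message_id`, `color`, and a `payload` list-column carrying
#'   summary numbers.
#' @examples
#' cfg <- session_config()
#' log <- run_session(generate_schedule(cfg, seed = 1),
#'                    participant_params(), config = cfg, seed = 1)
#' dplyr::count(feedback_events(log, cfg), message_id)
#' @export
feedback_events <- function(results, config = session_config()) {
  stopifnot(all(c("trial_index", "block", "trial_type", "rt_ms",
                  "outcome") %in% names(results)))
  if (is.unsorted(results$trial_index)) {
    stop("`results` must be ordered by `trial_index`.", call. = FALSE)
  }
  events <- list()
  emit <- function(trial_index, block, message_id, payload = NULL) {
    events[[length(events) + 1L]] <<- tibble::tibble(
      trial_index = trial_index, block = block, message_id = message_id,
      color = unname(feedback_messages[[message_id]]),
      payload = list(payload)
    )
  }

  for (blk in unique(as.character(results$block))) {
    rows <- results[as.character(results$block) == blk, ]
    consec_om <- 0L
    for (i in seq_len(nrow(rows))) {
      out <- rows$outcome[i]
      if (rows$trial_type[i] == "go") {
        consec_om <- if (out == "go_omission") consec_om + 1L else 0L
      }
      if (blk == "practice") {
        msg <- switch(out,
          go_correct = if (rows$rt_ms[i] < config$slow_rt_threshold) "hit"
                       else "hit_too_slow",
          go_omission = "miss_omission",
          go_error = "miss_incorrect_key",
          stop_inhibited = "stop_success",
          stop_failed_correct_key = "stop_fail",
          stop_failed_incorrect_key = "stop_fail"
        )
        emit(rows$trial_index[i], blk, msg)
      }
      if (consec_om > 0L &&
          consec_om %% config$consecutive_omission_warning == 0L) {
        emit(rows$trial_index[i], blk, "omission_warning")
      }
    }
    go_rows <- rows[rows$trial_type == "go", ]
    correct_rt <- go_rows$rt_ms[go_rows$outcome == "go_correct"]
    mean_rt <- if (length(correct_rt)) mean(correct_rt) else NA_real_
    stop_rows <- rows[rows$trial_type == "stop", ]
    stop_pct <- if (nrow(stop_rows)) {
      100 * mean(stop_rows$outcome == "stop_inhibited")
    } else {
      NA_real_
    }
    emit(NA_integer_, blk, "summary_go_errors",
         list(n_go_errors = sum(go_rows$outcome == "go_error")))
    emit(NA_integer_, blk, "summary_go_misses",
         list(n_go_omissions = sum(go_rows$outcome == "go_omission")))
    emit(NA_integer_, blk, "summary_mean_rt",
         list(mean_go_rt = mean_rt,
              too_slow = isTRUE(mean_rt >= config$slow_rt_threshold)))
    emit(NA_integer_, blk, "summary_stop_pct", list(stop_accuracy = stop_pct))
    emit(NA_integer_, blk, "summary_countdown", list(seconds = 10))
  }
  dplyr::bind_rows(events)
}
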
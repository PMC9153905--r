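#' Staircase state for adaptive stop-signal-delay tracking
#'
#' The task titrates the stop-signal delay (SSD) with a 1-up/1-down rule:
#' each successful inhibition makes stopping harder (SSD up one step), each
#' failed inhibition makes it easier (SSD down one step), converging on the
#' delay at which stopping succeeds about half the time.
#'
#' @param current_ssd Current SSD in ms.
#' @param step Step size in ms.
#' @param floor,ceiling Clamping bounds in ms.
#' @return A list of class `sst_staircase` with fields `current_ssd`, `step`,
#'   `floor`, `ceiling` and `n_updates`.
#' @examples
#' st <- staircase_state(250)
#' update_ssd(st, "inhibited")$current_ssd # 300
#' @export
staircase_state <- function(current_ssd = 250, step = 50, floor = 0,
                            ceiling = 950) {
  if (floor > ceiling) stop("`floor` must not exceed `ceiling`.", call. = FALSE)
  if (current_ssd < floor || current_ssd > ceiling) {
    stop("`current_ssd` must lie within [floor, ceiling].", call. = FALSE)
  }
  if (step <= 0) stop("`step` must be positive.", call. = FALSE)
  structure(list(current_ssd = current_ssd, step = step, floor = floor,
                 ceiling = ceiling, n_updates = 0L),
            class = "sst_staircase")
}

#' Advance the SSD staircase after a stop trial
#'
#' @param state A [staircase_state()].
#' @param stop_outcome `"inhibited"` (response withheld; SSD increases one
#'   step) or `"responded"` (inhibition failed; SSD decreases one step).
#'   Clamping at the floor/ceiling is the defined behaviour, not an error.
#' @return The updated `sst_staircase`.
#' @export
update_ssd <- function(state, stop_outcome = c("inhibited", "responded")) {
  stopifnot(inherits(state, "sst_staircase"))
  stop_outcome <- match.arg(stop_outcome)
  state$current_ssd <- if (stop_outcome == "inhibited") {
    min(state$current_ssd + state$step, state$ceiling)
  } else {
    max(state$current_ssd - state$step, state$floor)
  }
  state$n_updates <- state$n_updates + 1L
  state
}
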
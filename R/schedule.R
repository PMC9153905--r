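#' Generate a constrained trial schedule
#'
#' Builds the full trial list for one session: a practice block followed by
#' the experimental blocks. Within every block exactly `stop_fraction *
#' trials_per_block` trials are stop trials (the practice block uses the same
#' fraction of its own length), placed by constrained shuffle so that no two
#' stop trials are adjacent; go stimuli are drawn independently and uniformly
#' from X and O. Block boundaries break the adjacency constraint by default
#' (feedback screens intervene); set `stops_span_blocks` in the config to
#' enforce it across boundaries too.
#'
#' @param config A [session_config()].
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return A tibble with one row per trial: `trial_index` (0-based),
#'   `block` (`practice`, `exp1`, ...), `trial_type` (`go`/`stop`) and
#'   `go_stimulus` (`X`/`O`).
#' @examples
#' sched <- generate_schedule(session_config(), seed = 1)
#' table(sched$block, sched$trial_type)
#' @export
generate_schedule <- function(config = session_config(), seed = 1L) {
  validate_session_config(config)
  if (config$stop_fraction > 0.5) {
    stop("Unsatisfiable constraint: `stop_fraction` > 0.5 cannot avoid ",
         "consecutive stop trials.", call. = FALSE)
  }
  set.seed(as.integer(seed))

  block_lengths <- c(config$n_practice_trials,
                     rep(config$trials_per_block, config$n_experimental_blocks))
  block_names <- c("practice", paste0("exp", seq_len(config$n_experimental_blocks)))
  keep <- block_lengths > 0
  block_lengths <- block_lengths[keep]
  block_names <- block_names[keep]

  prev_last_stop <- FALSE
  blocks <- vector("list", length(block_lengths))
  for (b in seq_along(block_lengths)) {
    len <- block_lengths[b]
    n_stop <- round(config$stop_fraction * len)
    forbid_first <- config$stops_span_blocks && prev_last_stop
    types <- place_stops(len, n_stop, forbid_first)
    prev_last_stop <- length(types) > 0 && types[len] == "stop"
    blocks[[b]] <- tibble::tibble(
      block = block_names[b],
      trial_type = types,
      go_stimulus = sample(c("X", "O"), len, replace = TRUE)
    )
  }
  out <- dplyr::bind_rows(blocks)
  out <- dplyr::mutate(out, trial_index = dplyr::row_number() - 1L,
                       .before = 1)
  out$block <- factor(out$block, levels = block_names)
  out
}

# Constrained shuffle: draw stop positions uniformly, reject adjacency
# violations, with a deterministic fallback construction if rejection
# sampling exhausts its retry budget (only possible near the feasibility
# boundary n_stop = ceiling(len / 2)).
place_stops <- function(len, n_stop, forbid_first = FALSE, max_tries = 1000L) {
  types <- rep("go", len)
  if (n_stop == 0) return(types)
  lo <- if (forbid_first) 2L else 1L
  if (n_stop > ceiling((len - lo + 1L) / 2)) {
    stop("Unsatisfiable constraint: ", n_stop, " non-adjacent stop trials do ",
         "not fit in a block of ", len, ".", call. = FALSE)
  }
  for (try in seq_len(max_tries)) {
    pos <- sort(sample(lo:len, n_stop))
    if (all(diff(pos) > 1L)) {
      types[pos] <- "stop"
      return(types)
    }
  }
  # gap construction: distribute the spare go trials uniformly at random
  # among the n_stop + 1 gaps, then force one go between consecutive stops
  spare <- (len - lo + 1L) - (2L * n_stop - 1L)
  gaps <- as.vector(stats::rmultinom(1, spare, rep(1, n_stop + 1L)))
  steps <- gaps[seq_len(n_stop)] + 1L
  if (n_stop > 1L) steps[-1] <- steps[-1] + 1L
  pos <- (lo - 1L) + cumsum(steps)
  types[pos] <- "stop"
  types
}
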
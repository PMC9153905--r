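#' Session configuration for the stop-signal task
#'
#' Describes one administration of the web-based stop-signal task: a practice
#' block followed by experimental blocks, a fixed fraction of stop trials, and
#' the 1-up/1-down stop-signal-delay (SSD) staircase. Defaults reproduce the
#' standard design: 32 practice trials, 3 blocks of 64 experimental trials,
#' 25% stop trials, initial SSD 250 ms moving in 50 ms steps.
#'
#' Trial timing fields describe the event sequence of one trial (blank,
#' fixation, stimulus, and — during practice — a feedback screen). At the
#' defaults the practice inter-trial interval is 1000 + 250 + 1000 + 2000 =
#' 4250 ms and the experimental ITI is 2250 ms. The simulation engine treats
#' the stimulus window as the response deadline; the timing fields are
#' retained so that configurations mirror the task they emulate.
#'
#' @param n_practice_trials Number of practice trials.
#' @param n_experimental_blocks Number of experimental blocks.
#' @param trials_per_block Trials per experimental block.
#' @param stop_fraction Fraction of stop trials per block; `stop_fraction *
#'   trials_per_block` must be a whole number.
#' @param initial_ssd Starting SSD in ms.
#' @param ssd_step Staircase step in ms.
#' @param ssd_floor,ssd_ceiling Clamping bounds for the SSD in ms.
#' @param stimulus_duration Stimulus presentation time in ms; also the
#'   response window.
#' @param fixation_duration,blank_duration,practice_feedback_duration Trial
#'   event durations in ms.
#' @param slow_rt_threshold Go RT (ms) at or above which feedback switches to
#'   the "too slow" variants.
#' @param consecutive_omission_warning Number of consecutive go omissions
#'   that triggers the warning prompt.
#' @param carry_practice_ssd If `TRUE` the staircase carries its practice
#'   value into the first experimental block; by default it resets to
#'   `initial_ssd` so that sessions are comparable.
#' @param stops_span_blocks If `TRUE` the no-consecutive-stops constraint is
#'   enforced across block boundaries as well as within blocks.
#'
#' @return A list of class `sst_config`.
#' @examples
#' cfg <- session_config()
#' cfg$initial_ssd
#' @export
session_config <- function(n_practice_trials = 32L,
                           n_experimental_blocks = 3L,
                           trials_per_block = 64L,
                           stop_fraction = 0.25,
                           initial_ssd = 250,
                           ssd_step = 50,
                           ssd_floor = 0,
                           ssd_ceiling = 950,
                           stimulus_duration = 1000,
                           fixation_duration = 250,
                           blank_duration = 1000,
                           practice_feedback_duration = 2000,
                           slow_rt_threshold = 500,
                           consecutive_omission_warning = 3L,
                           carry_practice_ssd = FALSE,
                           stops_span_blocks = FALSE) {
  cfg <- list(
    n_practice_trials = as.integer(n_practice_trials),
    n_experimental_blocks = as.integer(n_experimental_blocks),
    trials_per_block = as.integer(trials_per_block),
    stop_fraction = stop_fraction,
    initial_ssd = initial_ssd,
    ssd_step = ssd_step,
    ssd_floor = ssd_floor,
    ssd_ceiling = ssd_ceiling,
    stimulus_duration = stimulus_duration,
    fixation_duration = fixation_duration,
    blank_duration = blank_duration,
    practice_feedback_duration = practice_feedback_duration,
    slow_rt_threshold = slow_rt_threshold,
    consecutive_omission_warning = as.integer(consecutive_omission_warning),
    carry_practice_ssd = isTRUE(carry_practice_ssd),
    stops_span_blocks = isTRUE(stops_span_blocks)
  )
  class(cfg) <- "sst_config"
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  stopifnot(inherits(cfg, "sst_config"))
  n_stop <- cfg$stop_fraction * cfg$trials_per_block
  if (abs(n_stop - round(n_stop)) > 1e-9) {
    stop("`stop_fraction` (", cfg$stop_fraction, ") times `trials_per_block` (",
         cfg$trials_per_block, ") must be a whole number of stop trials.",
         call. = FALSE)
  }
  if (cfg$stop_fraction < 0 || cfg$stop_fraction > 1) {
    stop("`stop_fraction` must lie in [0, 1].", call. = FALSE)
  }
  if (cfg$initial_ssd < cfg$ssd_floor || cfg$initial_ssd > cfg$ssd_ceiling) {
    stop("`initial_ssd` must lie within [ssd_floor, ssd_ceiling].", call. = FALSE)
  }
  if (cfg$ssd_floor > cfg$ssd_ceiling) {
    stop("`ssd_floor` must not exceed `ssd_ceiling`.", call. = FALSE)
  }
  durs <- c(cfg$stimulus_duration, cfg$fixation_duration, cfg$blank_duration,
            cfg$practice_feedback_duration)
  if (any(durs <= 0)) stop("All durations must be positive.", call. = FALSE)
  if (cfg$ssd_step <= 0) stop("`ssd_step` must be positive.", call. = FALSE)
  if (cfg$n_practice_trials < 0 || cfg$n_experimental_blocks < 1 ||
      cfg$trials_per_block < 1) {
    stop("Block structure counts must be positive.", call. = FALSE)
  }
  invisible(cfg)
}

#' Clock model separating programmed from measured (meta) SSD
#'
#' The task schedules a "programmed" SSD, but the stop signal is actually
#' drawn on screen at a time measured by the participant machine's real-time
#' clock — the meta-SSD. This model perturbs the programmed SSD with a
#' Gaussian offset (browser/OS scheduling latency) and an optional frame
#' quantization, producing meta-SSD values that correlate near-perfectly with
#' the programmed values while differing by a few milliseconds on average.
#'
#' @param offset_mean Mean timing offset in ms.
#' @param offset_sd SD of the offset in ms (>= 0).
#' @param quantum Frame quantum in ms; 0 disables quantization.
#' @return A list of class `sst_clock`.
#' @examples
#' clock_model(offset_mean = 4, offset_sd = 1)
#' @export
clock_model <- function(offset_mean = 0, offset_sd = 0, quantum = 0) {
  if (offset_sd < 0) stop("`offset_sd` must be >= 0.", call. = FALSE)
  if (quantum < 0) stop("`quantum` must be >= 0.", call. = FALSE)
  structure(list(offset_mean = offset_mean, offset_sd = offset_sd,
                 quantum = quantum),
            class = "sst_clock")
}

#' Latent race-model parameters for one participant-session
#'
#' The synthetic participant is an independent horse race: go responses
#' finish at ex-Gaussian times (`go_mu`, `go_sigma`, `go_tau`; mean go RT is
#' `go_mu + go_tau`), the stop process finishes `stop_mu` ms (SD
#' `stop_sigma`) after stop-signal onset, and the response is withheld when
#' the stop process wins the race. Lapse parameters add go omissions, choice
#' errors, and stop-trigger failures.
#'
#' @param go_mu,go_sigma,go_tau Ex-Gaussian go-finish-time parameters (ms).
#' @param stop_mu,stop_sigma Stop-latency mean and SD (ms). `stop_mu` is the
#'   true stop-signal reaction time the scoring pipeline tries to recover.
#' @param p_trigger_failure Probability the stop process never starts on a
#'   stop trial.
#' @param p_go_omission Probability the go process never starts on a trial.
#' @param p_choice_error Probability a response uses the wrong key.
#' @return A list of class `sst_participant`.
#' @examples
#' participant_params(go_mu = 400, go_sigma = 50, go_tau = 90, stop_mu = 250)
#' @export
participant_params <- function(go_mu = 400, go_sigma = 50, go_tau = 90,
                               stop_mu = 250, stop_sigma = 30,
                               p_trigger_failure = 0,
                               p_go_omission = 0,
                               p_choice_error = 0) {
  p <- list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
            stop_mu = stop_mu, stop_sigma = stop_sigma,
            p_trigger_failure = p_trigger_failure,
            p_go_omission = p_go_omission,
            p_choice_error = p_choice_error)
  probs <- c(p$p_trigger_failure, p$p_go_omission, p$p_choice_error)
  if (any(probs < 0 | probs > 1)) {
    stop("Probabilities must lie in [0, 1].", call. = FALSE)
  }
  if (p$go_sigma < 0 || p$stop_sigma < 0 || p$go_tau < 0) {
    stop("`go_sigma`, `go_tau` and `stop_sigma` must be >= 0.", call. = FALSE)
  }
  if (p$go_mu + p$go_tau >= 1000) {
    warning("Mean go finish time (go_mu + go_tau = ", p$go_mu + p$go_tau,
            " ms) is at or beyond a typical 1000 ms response window; ",
            "most responses will be omissions.", call. = FALSE)
  }
  class(p) <- "sst_participant"
  p
}

as_participant <- function(x) {
  if (inherits(x, "sst_participant")) return(x)
  x <- as.list(x)
  fields <- c("go_mu", "go_sigma", "go_tau", "stop_mu", "stop_sigma",
              "p_trigger_failure", "p_go_omission", "p_choice_error")
  missing <- setdiff(fields, names(x))
  if (length(missing)) {
    stop("Participant parameters missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(participant_params, lapply(x[fields], function(v) unname(v[[1]])))
}

#' Cohort-level generative parameters for a two-condition study
#'
#' Describes a cohort for the counterbalanced two-session design: every
#' participant completes the task once under laboratory conditions and once
#' independently (own computer, no supervision). Participant-level race
#' parameters are drawn from Gaussian population distributions; the latent
#' stop latency of the two sessions is bivariate Gaussian with correlation
#' `session_correlation`, and the independent session receives an additive
#' stop-latency shift (`condition_effect_ssrt`) and a choice-error increment
#' (`condition_effect_go_error`).
#'
#' Defaults emulate a healthy young-adult cohort on this task: mean go RT
#' near 490 ms with positive skew, stop latency near 240 ms with
#' between-subject SD ~33 ms, sub-1% omission and ~1.4% choice-error rates,
#' a latent test-retest correlation of 0.6, and a +22 ms / +0.8 percentage
#' point independent-condition effect.
#'
#' @param n_participants Number of participants completing both sessions.
#' @param n_incomplete Additional recruited participants who complete only
#'   one session (dropped later by [pair_filter()]).
#' @param go_mu_mean,go_mu_sd,go_sigma_mean,go_sigma_sd,go_tau_mean,go_tau_sd
#'   Population mean/SD of the ex-Gaussian go parameters (ms).
#' @param stop_mu_mean,stop_mu_sd Population mean/SD of stop latency (ms).
#' @param stop_sigma_mean,stop_sigma_sd Population mean/SD of within-subject
#'   stop-latency SD (ms).
#' @param p_trigger_failure_mean,p_go_omission_mean,p_go_omission_sd,p_choice_error_mean,p_choice_error_sd
#'   Population location/spread of the lapse probabilities.
#' @param session_correlation Correlation of latent stop latency across the
#'   two sessions, in `[-1, 1]`.
#' @param condition_effect_ssrt Stop-latency shift (ms) added in the
#'   independent condition.
#' @param condition_effect_go_error Additive shift on `p_choice_error` in the
#'   independent condition.
#' @param order `"counterbalanced"` alternates which condition comes first;
#'   `"independent_first"` / `"lab_first"` fix it.
#' @return A list of class `sst_cohort`.
#' @examples
#' cohort_params(n_participants = 20)
#' @export
cohort_params <- function(n_participants = 157L,
                          n_incomplete = 0L,
                          go_mu_mean = 400, go_mu_sd = 55,
                          go_sigma_mean = 50, go_sigma_sd = 10,
                          go_tau_mean = 90, go_tau_sd = 25,
                          stop_mu_mean = 240, stop_mu_sd = 33,
                          stop_sigma_mean = 30, stop_sigma_sd = 5,
                          p_trigger_failure_mean = 0,
                          p_go_omission_mean = 0.006, p_go_omission_sd = 0.005,
                          p_choice_error_mean = 0.014, p_choice_error_sd = 0.010,
                          session_correlation = 0.6,
                          condition_effect_ssrt = 22,
                          condition_effect_go_error = 0.008,
                          order = c("counterbalanced", "independent_first",
                                    "lab_first")) {
  order <- match.arg(order)
  ch <- list(n_participants = as.integer(n_participants),
             n_incomplete = as.integer(n_incomplete),
             go_mu_mean = go_mu_mean, go_mu_sd = go_mu_sd,
             go_sigma_mean = go_sigma_mean, go_sigma_sd = go_sigma_sd,
             go_tau_mean = go_tau_mean, go_tau_sd = go_tau_sd,
             stop_mu_mean = stop_mu_mean, stop_mu_sd = stop_mu_sd,
             stop_sigma_mean = stop_sigma_mean, stop_sigma_sd = stop_sigma_sd,
             p_trigger_failure_mean = p_trigger_failure_mean,
             p_go_omission_mean = p_go_omission_mean,
             p_go_omission_sd = p_go_omission_sd,
             p_choice_error_mean = p_choice_error_mean,
             p_choice_error_sd = p_choice_error_sd,
             session_correlation = session_correlation,
             condition_effect_ssrt = condition_effect_ssrt,
             condition_effect_go_error = condition_effect_go_error,
             order = order)
  if (ch$n_participants < 2) stop("`n_participants` must be >= 2.", call. = FALSE)
  if (ch$n_incomplete < 0) stop("`n_incomplete` must be >= 0.", call. = FALSE)
  if (abs(ch$session_correlation) > 1) {
    stop("`session_correlation` must lie in [-1, 1].", call. = FALSE)
  }
  sds <- c(ch$go_mu_sd, ch$go_sigma_sd, ch$go_tau_sd, ch$stop_mu_sd,
           ch$stop_sigma_sd, ch$p_go_omission_sd, ch$p_choice_error_sd)
  if (any(sds < 0)) stop("Population SDs must be >= 0.", call. = FALSE)
  class(ch) <- "sst_cohort"
  ch
}

#' Whole-study configuration
#'
#' Bundles the session design, cohort model, per-condition clock models,
#' scoring options and a master seed into one object consumed by
#' [run_study()]. The master seed deterministically derives every
#' per-participant, per-session random stream by a counter-based scheme
#' (`master_seed * 1000 + participant_index * 2 + session`, mod 2^31 - 1), so
#' enlarging the cohort never perturbs streams already drawn.
#'
#' @param session A [session_config()].
#' @param cohort A [cohort_params()].
#' @param clock_lab,clock_independent [clock_model()]s for the two
#'   conditions. The laboratory machine is modelled as slightly more
#'   punctual than participants' own computers.
#' @param ssd_source Which SSD mean enters the SSRT: the clock-measured
#'   `"meta"` value (default) or the `"programmed"` staircase value.
#' @param include_error_rts Include wrong-key go RTs in the mean go RT.
#' @param master_seed Integer master seed.
#' @return A list of class `sst_study_config`.
#' @examples
#' study_config(cohort = cohort_params(n_participants = 10), master_seed = 1)
#' @export
study_config <- function(session = session_config(),
                         cohort = cohort_params(),
                         clock_lab = clock_model(offset_mean = 1, offset_sd = 1),
                         clock_independent = clock_model(offset_mean = 4,
                                                         offset_sd = 2),
                         ssd_source = c("meta", "programmed"),
                         include_error_rts = FALSE,
                         master_seed = 1L) {
  stopifnot(inherits(session, "sst_config"), inherits(cohort, "sst_cohort"),
            inherits(clock_lab, "sst_clock"),
            inherits(clock_independent, "sst_clock"))
  structure(list(session = session, cohort = cohort, clock_lab = clock_lab,
                 clock_independent = clock_independent,
                 ssd_source = match.arg(ssd_source),
                 include_error_rts = isTRUE(include_error_rts),
                 master_seed = as.integer(master_seed)),
            class = "sst_study_config")
}

#' Read a study configuration from YAML or JSON
#'
#' The file may contain any of the top-level blocks `session`, `cohort`,
#' `clock_lab`, `clock_independent`, plus scalar `ssd_source`,
#' `include_error_rts` and `master_seed`; omitted entries keep their
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [study_config()] object.
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build <- function(ctor, block) do.call(ctor, as.list(block %||% list()))
  args <- list(session = build(session_config, raw$session),
               cohort = build(cohort_params, raw$cohort))
  if (!is.null(raw$clock_lab)) args$clock_lab <- build(clock_model, raw$clock_lab)
  if (!is.null(raw$clock_independent)) {
    args$clock_independent <- build(clock_model, raw$clock_independent)
  }
  if (!is.null(raw$ssd_source)) args$ssd_source <- raw$ssd_source
  if (!is.null(raw$include_error_rts)) args$include_error_rts <- raw$include_error_rts
  if (!is.null(raw$master_seed)) args$master_seed <- raw$master_seed
  do.call(study_config, args)
}

derive_seed <- function(master_seed, participant_index, session) {
  s <- (as.double(master_seed) * 1000 + as.double(participant_index) * 2 +
          session) %% (2^31 - 1)
  as.integer(s)
}
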
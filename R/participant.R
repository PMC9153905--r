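#' Draw ex-Gaussian variates
#'
#' Sum of a Gaussian and an independent exponential, the standard
#' positive-skew model for simple reaction times. Mean is `mu + tau`,
#' variance `sigma^2 + tau^2`.
#'
#' @param n Number of draws.
#' @param mu,sigma Gaussian component mean/SD.
#' @param tau Exponential component mean; 0 gives a plain Gaussian.
#' @return Numeric vector of length `n`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  x <- stats::rnorm(n, mu, sigma)
  if (tau > 0) x <- x + stats::rexp(n, rate = 1 / tau)
  x
}

#' Simulate the go process on one go trial
#'
#' With probability `p_go_omission` the go process never starts; otherwise
#' the finish time is ex-Gaussian, responses landing beyond the response
#' window count as omissions, and the key is wrong with probability
#' `p_choice_error`.
#'
#' @param params A [participant_params()] (or coercible list/row).
#' @param stimulus The go stimulus, `"X"` or `"O"`.
#' @param window Response window in ms (the stimulus duration).
#' @return A list with `responded`, `rt`, `response_key` and `outcome`
#'   (`go_correct`, `go_error` or `go_omission`); `rt`/`response_key` are
#'   `NA` when no response occurred.
#' @examples
#' set.seed(1)
#' sample_go_response(participant_params(), "X")
#' @export
sample_go_response <- function(params, stimulus = c("X", "O"), window = 1000) {
  params <- as_participant(params)
  stimulus <- match.arg(stimulus)
  if (stats::runif(1) < params$p_go_omission) {
    return(list(responded = FALSE, rt = NA_real_, response_key = NA_character_,
                outcome = "go_omission"))
  }
  rt <- rexgauss(1, params$go_mu, params$go_sigma, params$go_tau)
  if (rt <= 0 || rt > window) {
    return(list(responded = FALSE, rt = NA_real_, response_key = NA_character_,
                outcome = "go_omission"))
  }
  wrong <- stats::runif(1) < params$p_choice_error
  key <- if (wrong) setdiff(c("X", "O"), stimulus) else stimulus
  list(responded = TRUE, rt = rt, response_key = key,
       outcome = if (wrong) "go_error" else "go_correct")
}

#' Simulate the race on one stop trial
#'
#' Independent horse race: the response escapes inhibition iff the go
#' process finishes before `ssd + stop_latency` (and within the response
#' window). With probability `p_trigger_failure` the stop process never
#' starts, so any in-window go finish produces a response. A go process that
#' never starts (probability `p_go_omission`) yields a (trivially)
#' successful stop.
#'
#' @inheritParams sample_go_response
#' @param ssd Stop-signal delay actually realised on screen, in ms (>= 0).
#' @return A list with `responded`, `rt`, `response_key` and `outcome`
#'   (`stop_inhibited`, `stop_failed_correct_key` or
#'   `stop_failed_incorrect_key`).
#' @examples
#' set.seed(1)
#' sample_stop_outcome(participant_params(), ssd = 250, stimulus = "O")
#' @export
sample_stop_outcome <- function(params, ssd, stimulus = c("X", "O"),
                                window = 1000) {
  params <- as_participant(params)
  stimulus <- match.arg(stimulus)
  if (ssd < 0) stop("`ssd` must be >= 0.", call. = FALSE)
  inhibited_result <- list(responded = FALSE, rt = NA_real_,
                           response_key = NA_character_,
                           outcome = "stop_inhibited")
  if (stats::runif(1) < params$p_go_omission) return(inhibited_result)
  go_finish <- rexgauss(1, params$go_mu, params$go_sigma, params$go_tau)
  triggered <- stats::runif(1) >= params$p_trigger_failure
  stop_finish <- if (triggered) {
    ssd + stats::rnorm(1, params$stop_mu, params$stop_sigma)
  } else {
    Inf
  }
  if (go_finish < stop_finish && go_finish > 0 && go_finish <= window) {
    wrong <- stats::runif(1) < params$p_choice_error
    key <- if (wrong) setdiff(c("X", "O"), stimulus) else stimulus
    list(responded = TRUE, rt = go_finish, response_key = key,
         outcome = if (wrong) "stop_failed_incorrect_key"
                   else "stop_failed_correct_key")
  } else {
    inhibited_result
  }
}

#' Perturb a programmed SSD into its clock-measured (meta) value
#'
#' @param ssd_programmed Programmed SSD(s) in ms (vectorised).
#' @param clock A [clock_model()].
#' @return Meta-SSD value(s): programmed + Gaussian offset, optionally
#'   quantized to the frame quantum, clamped at 0.
#' @examples
#' set.seed(1)
#' apply_clock(250, clock_model(offset_mean = 4, offset_sd = 1))
#' @export
apply_clock <- function(ssd_programmed, clock = clock_model()) {
  stopifnot(inherits(clock, "sst_clock"))
  if (any(ssd_programmed < 0)) stop("`ssd_programmed` must be >= 0.", call. = FALSE)
  meta <- ssd_programmed +
    stats::rnorm(length(ssd_programmed), clock$offset_mean, clock$offset_sd)
  if (clock$quantum > 0) meta <- round(meta / clock$quantum) * clock$quantum
  pmax(meta, 0)
}

#' Draw a cohort of synthetic participants for the two-session design
#'
#' Each participant receives stable trait parameters (ex-Gaussian go
#' parameters, lapse probabilities) shared by both sessions, and a latent
#' stop latency drawn from a bivariate Gaussian across sessions with the
#' configured test-retest correlation. Whichever session is performed in the
#' independent condition receives the additive stop-latency shift and
#' choice-error increment. The last `n_incomplete` recruits have session 2
#' removed (they model recruits who never completed the second visit).
#'
#' Each participant's parameters are drawn from their own counter-derived
#' random stream, so enlarging the cohort reproduces earlier participants
#' exactly.
#'
#' @param cohort A [cohort_params()].
#' @param seed Integer seed.
#' @return A tibble with one row per participant-session: `participant_id`,
#'   `session` (1 or 2), `condition` (`lab`/`independent`), `order`, the
#'   eight race parameters, and `complete`.
#' @examples
#' head(sample_cohort(cohort_params(n_participants = 4), seed = 1))
#' @export
sample_cohort <- function(cohort = cohort_params(), seed = 1L) {
  stopifnot(inherits(cohort, "sst_cohort"))
  n_total <- cohort$n_participants + cohort$n_incomplete
  rho <- cohort$session_correlation

  # one counter-derived stream per participant: cohort growth never
  # perturbs participants already drawn
  traits <- purrr::map_dfr(seq_len(n_total), function(i) {
    set.seed(derive_seed(seed, i, 0L))
    z1 <- stats::rnorm(1)
    z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(1)
    tibble::tibble(
      participant_id = sprintf("P%03d", i),
      go_mu = stats::rnorm(1, cohort$go_mu_mean, cohort$go_mu_sd),
      go_sigma = pmax(stats::rnorm(1, cohort$go_sigma_mean,
                                   cohort$go_sigma_sd), 1),
      go_tau = pmax(stats::rnorm(1, cohort$go_tau_mean, cohort$go_tau_sd), 1),
      stop_sigma = pmax(stats::rnorm(1, cohort$stop_sigma_mean,
                                     cohort$stop_sigma_sd), 1),
      p_trigger_failure = pmin(pmax(cohort$p_trigger_failure_mean, 0), 1),
      p_go_omission = pmin(pmax(stats::rnorm(1, cohort$p_go_omission_mean,
                                             cohort$p_go_omission_sd), 0), 1),
      p_choice_error = pmin(pmax(stats::rnorm(1, cohort$p_choice_error_mean,
                                              cohort$p_choice_error_sd), 0), 1),
      stop_mu_s1 = cohort$stop_mu_mean + cohort$stop_mu_sd * z1,
      stop_mu_s2 = cohort$stop_mu_mean + cohort$stop_mu_sd * z2
    )
  })
  stop_mu_s1 <- traits$stop_mu_s1
  stop_mu_s2 <- traits$stop_mu_s2
  traits$stop_mu_s1 <- NULL
  traits$stop_mu_s2 <- NULL

  first_cond <- switch(cohort$order,
    independent_first = rep("independent", n_total),
    lab_first = rep("lab", n_total),
    counterbalanced = rep(c("independent", "lab"), length.out = n_total)
  )
  complete <- rep(c(TRUE, FALSE),
                  c(cohort$n_participants, cohort$n_incomplete))

  per_session <- function(sess) {
    cond <- ifelse((sess == 1) == (first_cond == "independent"),
                   "independent", "lab")
    stop_mu <- if (sess == 1) stop_mu_s1 else stop_mu_s2
    dplyr::mutate(
      traits,
      session = sess,
      condition = cond,
      order = paste0(first_cond, "_first"),
      stop_mu = stop_mu +
        ifelse(cond == "independent", cohort$condition_effect_ssrt, 0),
      p_choice_error = pmin(pmax(
        p_choice_error +
          ifelse(cond == "independent", cohort$condition_effect_go_error, 0),
        0), 1),
      complete = complete
    )
  }
  out <- dplyr::bind_rows(per_session(1L), per_session(2L))
  out <- dplyr::filter(out, complete | session == 1L)
  out <- dplyr::arrange(out, participant_id, session)
  dplyr::select(out, participant_id, session, condition, order, complete,
                go_mu, go_sigma, go_tau, stop_mu, stop_sigma,
                p_trigger_failure, p_go_omission, p_choice_error)
}
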
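# Shared fixtures, built in code.

# A short session for fast engine tests: 8 practice + 2 blocks of 16.
tiny_config <- function(...) {
  session_config(n_practice_trials = 8L, n_experimental_blocks = 2L,
                 trials_per_block = 16L, ...)
}

# Constant-parameter racer: go finishes at exactly `go`, stop process at
# ssd + `stop`. Closed-form race threshold is SSD* = go - stop.
deterministic_racer <- function(go = 500, stop = 250) {
  participant_params(go_mu = go, go_sigma = 0, go_tau = 0,
                     stop_mu = stop, stop_sigma = 0)
}

# The stationary stochastic racer used for staircase-design checks.
exgauss_racer <- function() {
  participant_params(go_mu = 400, go_sigma = 50, go_tau = 90,
                     stop_mu = 250, stop_sigma = 30)
}

# Hand-built 8-trial experimental log: 6 go trials (4 correct with RTs
# 400/420/440/460, 1 wrong key at 300, 1 omission) and 2 stop trials at
# SSD 250 (1 inhibited, 1 failed with the correct key at 350).
hand_log <- function() {
  tibble::tibble(
    trial_index = 0:7,
    block = "exp1",
    trial_type = c(rep("go", 6), "stop", "stop"),
    go_stimulus = c("X", "O", "X", "O", "X", "O", "X", "O"),
    ssd_programmed_ms = c(rep(NA, 6), 250, 250),
    ssd_meta_ms = c(rep(NA, 6), 250, 250),
    responded = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    response_key = c("X", "O", "X", "O", "O", NA, NA, "O"),
    rt_ms = c(400, 420, 440, 460, 300, NA, NA, 350),
    outcome = c(rep("go_correct", 4), "go_error", "go_omission",
                "stop_inhibited", "stop_failed_correct_key")
  )
}

# A clean scored-session row; individual fields are overridden to probe
# one exclusion rule at a time.
clean_metrics <- function(...) {
  row <- tibble::tibble(
    session_id = "S1",
    go_accuracy = 97, go_omissions = 1, go_errors = 2,
    go_rt_mean = 500, go_error_rt_mean = 450, intraindividual_sd = 80,
    stop_accuracy = 50, ssd_programmed_mean = 250, ssd_meta_mean = 252,
    failed_stop_correct_key_rt_mean = 450,
    failed_stop_incorrect_key_rt_mean = 430,
    ssrt = 248, n_go = 144, n_stop = 48
  )
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}

# Independent Bayes-factor oracle: marginalize the noncentral-t likelihood
# over the Cauchy effect-size prior directly, by fine-grid trapezoid
# integration over delta (a different parameterization and integrator than
# the package's inverse-gamma-mixture quadrature).
bf10_trapezoid_oracle <- function(t, n, scale = 0.707, half_width = 60,
                                  n_grid = 40001L) {
  nu <- n - 1
  delta <- seq(-half_width, half_width, length.out = n_grid)
  like <- suppressWarnings(stats::dt(t, df = nu, ncp = delta * sqrt(n)))
  prior <- stats::dcauchy(delta, 0, scale)
  f <- like * prior
  h <- delta[2] - delta[1]
  num <- h * (sum(f) - (f[1] + f[n_grid]) / 2)
  num / stats::dt(t, df = nu)
}

expect_valid_schedule <- function(sched, config) {
  per_block <- split(sched$trial_type, sched$block)
  for (blk in names(per_block)) {
    types <- per_block[[blk]]
    n_stop_expected <- round(config$stop_fraction * length(types))
    expect_identical(sum(types == "stop"), as.integer(n_stop_expected))
    runs <- rle(types)
    expect_true(all(runs$lengths[runs$values == "stop"] == 1L))
  }
}
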
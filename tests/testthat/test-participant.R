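test_that("go-response lapses behave as configured", {
  set.seed(1)
  always_miss <- participant_params(p_go_omission = 1)
  for (i in 1:5) {
    res <- sample_go_response(always_miss, "X")
    expect_identical(res$outcome, "go_omission")
    expect_false(res$responded)
    expect_true(is.na(res$rt))
  }
  clean <- participant_params(p_go_omission = 0, p_choice_error = 0)
  outs <- replicate(50, sample_go_response(clean, "O", window = 1e6)$outcome)
  expect_true(all(outs == "go_correct"))
  wrong <- participant_params(p_choice_error = 1)
  res <- sample_go_response(wrong, "X", window = 1e6)
  expect_identical(res$outcome, "go_error")
  expect_identical(res$response_key, "O")
})

test_that("ex-Gaussian sampler has mean mu + tau", {
  set.seed(7)
  draws <- rexgauss(10000, 400, 50, 90)
  expect_lt(abs(mean(draws) - 490), 5)
  expect_lt(abs(sd(draws) - sqrt(50^2 + 90^2)), 5)
})

test_that("the race rule decides stop outcomes deterministically at zero noise", {
  racer <- deterministic_racer(go = 500, stop = 250)
  set.seed(1)
  expect_identical(sample_stop_outcome(racer, ssd = 200, "X")$outcome,
                   "stop_inhibited") # 500 >= 450
  res <- sample_stop_outcome(racer, ssd = 300, "X")
  expect_identical(res$outcome, "stop_failed_correct_key") # 500 < 550
  expect_equal(res$rt, 500)
  tf <- participant_params(go_mu = 500, go_sigma = 0, go_tau = 0,
                           p_trigger_failure = 1)
  outs <- replicate(10, sample_stop_outcome(tf, ssd = 0, "X")$responded)
  expect_true(all(outs))
})

test_that("P(respond | stop trial) is non-decreasing in SSD", {
  racer <- exgauss_racer()
  p_at <- vapply(c(100, 250, 400), function(ssd) {
    set.seed(ssd)
    mean(replicate(800, sample_stop_outcome(racer, ssd, "X")$responded))
  }, numeric(1))
  expect_true(all(diff(p_at) > 0))
})

test_that("the clock model shifts and barely decorrelates the SSD", {
  expect_equal(apply_clock(c(0, 250, 900), clock_model()), c(0, 250, 900))
  set.seed(2)
  prog <- rep(seq(150, 350, by = 50), length.out = 48)
  meta <- apply_clock(prog, clock_model(offset_mean = 4, offset_sd = 1))
  expect_lt(abs(mean(meta) - mean(prog) - 4), 1)
  expect_gt(cor(prog, meta), 0.99)
  quant <- apply_clock(rep(250, 20), clock_model(offset_mean = 5, offset_sd = 3,
                                                 quantum = 16.67))
  expect_true(all(abs(quant / 16.67 - round(quant / 16.67)) < 1e-9))
  expect_error(apply_clock(-1, clock_model()), ">= 0")
})

test_that("cohorts reproduce the configured cross-session structure", {
  ch <- cohort_params(n_participants = 10, session_correlation = 1,
                      condition_effect_ssrt = 0, condition_effect_go_error = 0)
  coh <- sample_cohort(ch, seed = 1)
  wide <- tidyr::pivot_wider(coh[c("participant_id", "session", "stop_mu")],
                             names_from = session, values_from = stop_mu)
  expect_equal(wide$`1`, wide$`2`)

  ch2 <- cohort_params(n_participants = 200, session_correlation = 0.6,
                       condition_effect_ssrt = 0, condition_effect_go_error = 0)
  rs <- vapply(1:5, function(seed) {
    coh2 <- sample_cohort(ch2, seed = seed)
    wide2 <- tidyr::pivot_wider(coh2[c("participant_id", "session", "stop_mu")],
                                names_from = session, values_from = stop_mu)
    cor(wide2$`1`, wide2$`2`)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.1)
})

test_that("counterbalancing splits the cohort into equal order arms", {
  coh <- sample_cohort(cohort_params(n_participants = 158), seed = 2)
  arms <- table(unique(coh[c("participant_id", "order")])$order)
  expect_equal(unname(arms[["independent_first"]]), 79)
  expect_equal(unname(arms[["lab_first"]]), 79)
  # the independent condition carries the configured stop-latency shift
  ch <- cohort_params(n_participants = 50, session_correlation = 1,
                      condition_effect_ssrt = 30, condition_effect_go_error = 0)
  coh2 <- sample_cohort(ch, seed = 5)
  wide <- tidyr::pivot_wider(coh2[c("participant_id", "condition", "stop_mu")],
                             names_from = condition, values_from = stop_mu)
  expect_equal(wide$independent - wide$lab, rep(30, 50))
})

test_that("incomplete participants lose their second session", {
  coh <- sample_cohort(cohort_params(n_participants = 10, n_incomplete = 3),
                       seed = 4)
  counts <- table(coh$participant_id)
  expect_equal(sum(counts == 2), 10)
  expect_equal(sum(counts == 1), 3)
})
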
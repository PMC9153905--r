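test_that("the full pipeline is deterministic under a fixed master seed", {
  cfg <- study_config(cohort = cohort_params(n_participants = 8),
                      master_seed = 31)
  a <- run_study(cfg)
  b <- run_study(cfg)
  expect_identical(a$logs, b$logs)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$analysis$comparisons, b$analysis$comparisons)
  expect_identical(a$manifest, b$manifest)
  c <- run_study(study_config(cohort = cohort_params(n_participants = 8),
                              master_seed = 32))
  expect_false(identical(a$logs, c$logs))
})

test_that("adding participants never perturbs earlier streams", {
  small <- run_study(study_config(cohort = cohort_params(n_participants = 6),
                                  master_seed = 17))
  big <- run_study(study_config(cohort = cohort_params(n_participants = 9),
                                master_seed = 17))
  shared <- small$logs$participant_id %in% sprintf("P%03d", 1:6)
  expect_identical(
    small$logs[c("participant_id", "trial_index", "rt_ms", "outcome")],
    big$logs[big$logs$participant_id %in% sprintf("P%03d", 1:6),
             c("participant_id", "trial_index", "rt_ms", "outcome")]
  )
})

test_that("the manifest funnel is monotone and counts match the tables", {
  study <- run_study(study_config(
    cohort = cohort_params(n_participants = 10, n_incomplete = 2),
    master_seed = 5
  ))
  m <- study$manifest
  expect_equal(m$n_recruited, 12)
  expect_equal(m$n_completed_both, 10)
  expect_gte(m$n_completed_both, m$n_retained)
  expect_gte(m$n_recruited, m$n_completed_both)
  expect_equal(m$n_retained, sum(study$retained$retained))
  incomplete <- study$retained[grepl("incomplete_pair",
                                     study$retained$reasons), ]
  expect_equal(nrow(incomplete), 2)
  expect_equal(m$n_sessions, nrow(study$metrics))
})

test_that("report files are written and reread consistently", {
  out <- withr::local_tempdir()
  study <- run_study(study_config(cohort = cohort_params(n_participants = 6),
                                  master_seed = 23),
                     out_dir = out)
  expect_true(all(file.exists(file.path(out,
    c("logs.csv", "metrics.csv", "exclusions.csv", "retained.csv",
      "analysis.json", "manifest.json")))))
  metrics <- readr::read_csv(file.path(out, "metrics.csv"),
                             show_col_types = FALSE)
  expect_equal(nrow(metrics), nrow(study$metrics))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$n_retained, study$manifest$n_retained)
  report <- jsonlite::read_json(file.path(out, "analysis.json"),
                                simplifyVector = TRUE)
  expect_equal(report$schema_version, "1.0")
  expect_equal(nrow(report$comparisons), 11)
})

test_that("simulated metrics land in a plausible human range", {
  study <- run_study(study_config(cohort = cohort_params(n_participants = 20),
                                  master_seed = 41))
  m <- study$metrics
  expect_true(all(m$go_accuracy > 85))
  expect_true(abs(mean(m$stop_accuracy) - 50) < 5)
  expect_true(mean(m$ssrt) > 150 && mean(m$ssrt) < 350)
  # meta-SSD tracks programmed SSD near-perfectly within sessions
  per_session_r <- study$logs |>
    dplyr::filter(trial_type == "stop", block != "practice") |>
    dplyr::group_by(session_id) |>
    dplyr::summarise(r = cor(ssd_programmed_ms, ssd_meta_ms),
                     .groups = "drop")
  expect_true(all(per_session_r$r > 0.99))
})

test_that("estimated SSRT correlations recover the latent test-retest structure", {
  # latent correlation 0.5; estimation noise attenuates the observed value
  study <- run_study(study_config(
    cohort = cohort_params(n_participants = 120, session_correlation = 0.5,
                           condition_effect_ssrt = 0,
                           condition_effect_go_error = 0),
    master_seed = 207
  ))
  overall <- study$analysis$correlations
  overall <- overall[overall$group == "all", ]
  expect_gt(overall$r, 0.3)
  expect_lt(overall$r, 0.65)
  expect_lt(overall$p, 0.001)
})

test_that("a null cohort shows no SSRT condition effect at the .005 criterion", {
  study <- run_study(study_config(
    cohort = cohort_params(n_participants = 40, condition_effect_ssrt = 0,
                           condition_effect_go_error = 0),
    master_seed = 123
  ))
  row <- study$analysis$comparisons
  row <- row[row$metric == "ssrt", ]
  expect_false(row$significant)
})

test_that("a +22 ms independent shift is detected in a full-size cohort", {
  study <- run_study(study_config(
    cohort = cohort_params(n_participants = 120, condition_effect_ssrt = 22),
    master_seed = 55
  ))
  row <- study$analysis$comparisons
  row <- row[row$metric == "ssrt", ]
  expect_true(row$significant)
  expect_lt(row$mean_diff, 0) # independent SSRT is longer
})
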
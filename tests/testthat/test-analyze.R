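build_metrics <- function(n = 12, seed = 1, ssrt_shift = 0) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n))
  base <- tibble::tibble(
    participant_id = rep(ids, 2),
    condition = rep(c("lab", "independent"), each = n),
    order = rep(rep(c("independent_first", "lab_first"), length.out = n), 2),
    go_accuracy = rnorm(2 * n, 97, 1.5),
    go_rt_mean = rnorm(2 * n, 490, 60),
    go_omissions = pmax(rnorm(2 * n, 0.6, 0.5), 0),
    go_errors = pmax(rnorm(2 * n, 1.8, 1), 0),
    go_error_rt_mean = rnorm(2 * n, 420, 80),
    intraindividual_sd = rnorm(2 * n, 85, 20),
    stop_accuracy = rnorm(2 * n, 50, 2),
    failed_stop_correct_key_rt_mean = rnorm(2 * n, 450, 50),
    failed_stop_incorrect_key_rt_mean = rnorm(2 * n, 380, 60),
    ssd_meta_mean = rnorm(2 * n, 240, 60),
    ssrt = rnorm(2 * n, 250, 35) +
      ifelse(rep(c(FALSE, TRUE), each = n), ssrt_shift, 0)
  )
  base
}

test_that("analysis rows match a manual paired t on the same columns", {
  metrics <- build_metrics(n = 10, seed = 2)
  an <- analyze_study(metrics)
  wide <- tidyr::pivot_wider(metrics[c("participant_id", "condition", "ssrt")],
                             names_from = condition, values_from = ssrt)
  manual <- paired_t(wide$lab, wide$independent)
  row <- an$comparisons[an$comparisons$metric == "ssrt", ]
  expect_equal(row$t, manual$t)
  expect_equal(row$p, manual$p)
  expect_equal(row$bf10, manual$bf10)
  expect_equal(row$cohen_d, abs(row$t) / sqrt(row$n))
  expect_equal(nrow(an$comparisons), 11)
})

test_that("missing strata reduce the degrees of freedom pairwise", {
  metrics <- build_metrics(n = 10, seed = 3)
  gone <- metrics$participant_id %in% c("p01", "p02") &
    metrics$condition == "independent"
  metrics$failed_stop_incorrect_key_rt_mean[gone] <- NA
  an <- analyze_study(metrics)
  row <- an$comparisons[an$comparisons$metric ==
                          "failed_stop_incorrect_key_rt_mean", ]
  expect_equal(row$n, 8)
  expect_equal(row$df, 7)
  full <- an$comparisons[an$comparisons$metric == "ssrt", ]
  expect_equal(full$df, 9)
})

test_that("a variable with too few complete pairs is reported, not dropped", {
  metrics <- build_metrics(n = 8, seed = 4)
  metrics$failed_stop_incorrect_key_rt_mean[
    metrics$condition == "independent"][1:7] <- NA
  an <- analyze_study(metrics)
  row <- an$comparisons[an$comparisons$metric ==
                          "failed_stop_incorrect_key_rt_mean", ]
  expect_equal(nrow(row), 1)
  expect_true(is.na(row$t))
  expect_true(is.na(row$significant))
})

test_that("the retention filter and the sign convention are honoured", {
  metrics <- build_metrics(n = 12, seed = 5, ssrt_shift = 40)
  keep <- tibble::tibble(participant_id = sprintf("p%02d", 1:10),
                         retained = TRUE, reasons = "")
  an <- analyze_study(metrics, retained = keep)
  expect_equal(an$n_participants, 10)
  # independent SSRT is longer, so lab - independent is negative
  row <- an$comparisons[an$comparisons$metric == "ssrt", ]
  expect_lt(row$mean_diff, 0)
  expect_equal(row$mean_diff, row$mean_lab - row$mean_independent)
})

test_that("SSRT correlations are reported overall and by order arm", {
  metrics <- build_metrics(n = 16, seed = 6)
  an <- analyze_study(metrics)
  expect_setequal(an$correlations$group,
                  c("all", "independent_first", "lab_first"))
  overall <- an$correlations[an$correlations$group == "all", ]
  wide <- tidyr::pivot_wider(metrics[c("participant_id", "condition", "ssrt")],
                             names_from = condition, values_from = ssrt)
  expect_equal(overall$r, cor(wide$lab, wide$independent))
  expect_equal(overall$n, 16)
})

test_that("tidy and glance expose the analysis tables", {
  metrics <- build_metrics(n = 10, seed = 7)
  an <- analyze_study(metrics)
  expect_identical(tidy(an), an$comparisons)
  g <- glance(an)
  expect_equal(g$n_participants, 10)
  expect_equal(g$n_variables, 11)
  expect_equal(g$alpha, 0.005)
})

test_that("autoplot methods return ggplot objects", {
  metrics <- build_metrics(n = 10, seed = 8)
  an <- analyze_study(metrics)
  expect_s3_class(ggplot2::autoplot(an), "ggplot")
  cfg <- tiny_config()
  log <- run_session(generate_schedule(cfg, seed = 1), exgauss_racer(),
                     config = cfg, seed = 1)
  expect_s3_class(plot_staircase(log), "ggplot")
  expect_s3_class(plot_rt_distribution(log), "ggplot")
  expect_s3_class(ggplot2::autoplot(log), "ggplot")
})

test_that("too few participants abort the analysis by count", {
  expect_error(analyze_study(build_metrics(n = 3)), "at least 4")
})
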
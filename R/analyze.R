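sst_variable_labels <- c(
  go_accuracy = "Go accuracy",
  go_rt_mean = "Go reaction time (ms)",
  go_omissions = "Go omissions",
  go_errors = "Go errors",
  go_error_rt_mean = "Go errors reaction time (ms)",
  intraindividual_sd = "Intraindividual SD",
  stop_accuracy = "Stop accuracy",
  failed_stop_correct_key_rt_mean = "Failed (correct key) stop RT (ms)",
  failed_stop_incorrect_key_rt_mean = "Failed (incorrect key) stop RT (ms)",
  ssd_meta_mean = "Meta stop-signal delay (ms)",
  ssrt = "Stop-signal reaction time (ms)"
)

#' Compare the full variable battery across the two conditions
#'
#' The analysis layer for the two-condition within-subject design: one
#' paired t test (with Cohen d_z, JZS Bayes factor and evidence label) per
#' session-level variable, laboratory minus independent, plus Pearson
#' correlations between the laboratory and independent SSRT — overall and
#' within each counterbalancing-order subgroup.
#'
#' Variables with missing strata for some participants (e.g. sessions with
#' no wrong-key failed stops) are analysed over pairwise-complete
#' participants, with degrees of freedom reduced accordingly. A variable
#' with fewer than two complete pairs (or zero-variance differences) is
#' reported as not estimable rather than silently dropped.
#'
#' @param metrics A metrics tibble from [score_sessions()] carrying
#'   `participant_id` and `condition` (`"lab"`/`"independent"`) columns, and
#'   optionally `order` for the subgroup correlations.
#' @param retained Optional retention filter: a tibble from [pair_filter()]
#'   or a character vector of participant ids. `NULL` analyses everyone
#'   present in both conditions.
#' @param alpha Significance criterion applied per row (default .005).
#' @param bf_scale Cauchy prior scale for the Bayes factors.
#' @return An object of class `sst_analysis`: a list with `comparisons`
#'   (one row per variable), `correlations` (overall and by order),
#'   `n_participants` and `alpha`. Use [generics::tidy()] /
#'   [generics::glance()] or `autoplot()` on it.
#' @examples
#' \donttest{
#' study <- run_study(study_config(cohort = cohort_params(n_participants = 12),
#'                                 master_seed = 1))
#' tidy(study$analysis)
#' }
#' @export
analyze_study <- function(metrics, retained = NULL, alpha = 0.005,
                          bf_scale = 0.707) {
  needed <- c("participant_id", "condition")
  missing <- setdiff(needed, names(metrics))
  if (length(missing)) {
    stop("Metrics are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(metrics$condition %in% c("lab", "independent"))) {
    stop("`condition` must be 'lab' or 'independent'.", call. = FALSE)
  }
  if (!is.null(retained)) {
    ids <- if (is.data.frame(retained)) {
      retained$participant_id[retained$retained]
    } else {
      retained
    }
    metrics <- metrics[metrics$participant_id %in% ids, ]
  }
  both <- intersect(metrics$participant_id[metrics$condition == "lab"],
                    metrics$participant_id[metrics$condition == "independent"])
  metrics <- metrics[metrics$participant_id %in% both, ]
  if (length(both) < 4) {
    stop("Need at least 4 retained participants with both sessions; have ",
         length(both), ".", call. = FALSE)
  }

  vars <- intersect(names(sst_variable_labels), names(metrics))
  wide <- metrics |>
    dplyr::select(participant_id, condition,
                  dplyr::any_of(c("order", names(sst_variable_labels)))) |>
    tidyr::pivot_wider(names_from = condition,
                       values_from = dplyr::all_of(vars))

  comparisons <- purrr::map_dfr(vars, function(v) {
    lab <- wide[[paste0(v, "_lab")]]
    ind <- wide[[paste0(v, "_independent")]]
    res <- tryCatch(
      paired_t(lab, ind, variable = unname(sst_variable_labels[[v]]),
               alpha = alpha, bf_scale = bf_scale),
      error = function(e) {
        tibble::tibble(variable = unname(sst_variable_labels[[v]]),
                       n = sum(is.finite(lab) & is.finite(ind)),
                       mean_a = NA_real_, mean_b = NA_real_,
                       sd_a = NA_real_, sd_b = NA_real_,
                       mean_diff = NA_real_, t = NA_real_, df = NA_real_,
                       p = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       cohen_d = NA_real_, bf10 = NA_real_,
                       evidence = NA_character_, significant = NA)
      }
    )
    res$metric <- v
    res
  })
  comparisons <- dplyr::relocate(comparisons, metric, .before = 1) |>
    dplyr::rename(mean_lab = mean_a, mean_independent = mean_b,
                  sd_lab = sd_a, sd_independent = sd_b)

  cors <- list(
    tibble::tibble(group = "all",
                   pearson_r_ci(wide$ssrt_lab, wide$ssrt_independent))
  )
  if ("order" %in% names(wide)) {
    for (grp in sort(unique(wide$order))) {
      sub <- wide[wide$order == grp, ]
      if (sum(is.finite(sub$ssrt_lab) & is.finite(sub$ssrt_independent)) >= 4) {
        cors[[length(cors) + 1L]] <-
          tibble::tibble(group = grp,
                         pearson_r_ci(sub$ssrt_lab, sub$ssrt_independent))
      }
    }
  }

  structure(list(comparisons = comparisons,
                 correlations = dplyr::bind_rows(cors),
                 n_participants = length(both),
                 alpha = alpha),
            class = "sst_analysis")
}

#' @export
print.sst_analysis <- function(x, ...) {
  cat("Stop-signal task condition analysis (", x$n_participants,
      " participants, criterion p < ", format(x$alpha), ")\n\n", sep = "")
  print(x$comparisons |>
          dplyr::select(variable, mean_lab, mean_independent, t, df, p,
                        cohen_d, bf10, significant), n = Inf)
  cat("\nSSRT correlations between conditions:\n")
  print(x$correlations, n = Inf)
  invisible(x)
}

#' Tidy the per-variable comparisons of an analysis
#'
#' @param x An `sst_analysis` from [analyze_study()].
#' @param ... Unused.
#' @return The comparison tibble, one row per session-level variable.
#' @method tidy sst_analysis
#' @export
tidy.sst_analysis <- function(x, ...) {
  x$comparisons
}

#' One-row summary of an analysis
#'
#' @param x An `sst_analysis` from [analyze_study()].
#' @param ... Unused.
#' @return A one-row tibble: `n_participants`, `n_variables`,
#'   `n_significant` (at the analysis criterion), `ssrt_r`, `ssrt_r_ci_low`,
#'   `ssrt_r_ci_high`, `alpha`.
#' @method glance sst_analysis
#' @export
glance.sst_analysis <- function(x, ...) {
  overall <- x$correlations[x$correlations$group == "all", ]
  tibble::tibble(
    n_participants = x$n_participants,
    n_variables = nrow(x$comparisons),
    n_significant = sum(x$comparisons$significant, na.rm = TRUE),
    ssrt_r = overall$r,
    ssrt_r_ci_low = overall$ci_low,
    ssrt_r_ci_high = overall$ci_high,
    alpha = x$alpha
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
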
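#' Plot the SSD staircase trajectory of a session
#'
#' Programmed (step line) and clock-measured meta (points, coloured by stop
#' outcome) stop-signal delays across the stop trials of a session.
#'
#' @param log A trial log from [run_session()] or [read_trial_log()].
#' @return A ggplot object.
#' @export
plot_staircase <- function(log) {
  stops <- log[log$trial_type == "stop", ]
  stops$stopped <- ifelse(stops$outcome == "stop_inhibited",
                          "inhibited", "responded")
  ggplot2::ggplot(stops, ggplot2::aes(x = .data$trial_index)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ssd_programmed_ms),
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$ssd_meta_ms,
                                     colour = .data$stopped), size = 1.8) +
    ggplot2::scale_colour_manual(values = c(inhibited = "#2c7fb8",
                                            responded = "#d95f0e"),
                                 name = "stop outcome") +
    ggplot2::labs(x = "trial index", y = "SSD (ms)",
                  title = "Adaptive stop-signal-delay staircase") +
    ggplot2::theme_minimal()
}

#' Plot the session's reaction-time distributions
#'
#' Histogram of correct-go RTs with failed-stop RTs overlaid; under the
#' horse-race model failed-stop responses are the fast tail of the go
#' distribution, so their mass should sit left of the go mean.
#'
#' @param log A trial log from [run_session()] or [read_trial_log()].
#' @return A ggplot object.
#' @export
plot_rt_distribution <- function(log) {
  rts <- dplyr::bind_rows(
    tibble::tibble(kind = "correct go",
                   rt = log$rt_ms[log$outcome == "go_correct"]),
    tibble::tibble(kind = "failed stop",
                   rt = log$rt_ms[log$outcome %in%
                                    c("stop_failed_correct_key",
                                      "stop_failed_incorrect_key")])
  )
  ggplot2::ggplot(rts, ggplot2::aes(x = .data$rt, fill = .data$kind)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.55, bins = 30) +
    ggplot2::labs(x = "reaction time (ms)", y = "trials",
                  title = "Go and failed-stop reaction times") +
    ggplot2::theme_minimal()
}

#' @rdname plot_staircase
#' @param object A trial log (`sst_trial_log`).
#' @param ... Unused.
#' @method autoplot sst_trial_log
#' @export
autoplot.sst_trial_log <- function(object, ...) {
  plot_staircase(object)
}

#' Forest-style plot of the condition comparisons
#'
#' Mean laboratory-minus-independent differences with their 95\% CIs for
#' every session-level variable; filled points mark comparisons significant
#' at the analysis criterion.
#'
#' @param object An `sst_analysis` from [analyze_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sst_analysis
#' @export
autoplot.sst_analysis <- function(object, ...) {
  cmp <- object$comparisons
  cmp$variable <- factor(cmp$variable, levels = rev(cmp$variable))
  ggplot2::ggplot(cmp, ggplot2::aes(x = .data$mean_diff, y = .data$variable)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high,
                                          shape = .data$significant)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                name = paste0("p < ", format(object$alpha))) +
    ggplot2::labs(x = "laboratory - independent (variable units)", y = NULL,
                  title = "Condition differences with 95% CIs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
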
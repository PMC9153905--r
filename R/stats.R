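#' JZS Bayes factor for a one-sample or paired t design
#'
#' Default-prior Bayes factor BF10 comparing a point null against an
#' alternative that places a Cauchy(0, `scale`) prior on the standardized
#' effect size. The numerator marginalizes the t likelihood over the
#' prior's inverse-gamma mixing variable g (the Cauchy arises as a scale
#' mixture of normals); the half-infinite g domain is mapped to a finite
#' interval by the substitution g = scale^2 tan^2(theta) before adaptive
#' quadrature. The result is symmetric in t and -t.
#'
#' @param t Observed t statistic(s); vectorised.
#' @param n Number of pairs (or observations); the t has `n - 1` degrees of
#'   freedom.
#' @param scale Cauchy prior scale on effect size; 0.707 (\eqn{\sqrt{2}/2})
#'   is the conventional default.
#' @param rel_tol Relative tolerance of the quadrature.
#' @return BF10 value(s) > 0; values above 1 favour the alternative.
#' @examples
#' jzs_bf10(4.12, 123) # about 240
#' jzs_bf10(1.00, 123) # about 0.16
#' @export
jzs_bf10 <- function(t, n, scale = 0.707, rel_tol = 1e-6) {
  if (scale <= 0) stop("`scale` must be positive.", call. = FALSE)
  if (any(n < 2)) stop("`n` must be >= 2.", call. = FALSE)
  if (any(!is.finite(t))) stop("`t` must be finite.", call. = FALSE)
  if (length(n) == 1) n <- rep(n, length(t))
  mapply(function(t1, n1) jzs_bf10_one(t1, n1, scale, rel_tol), t, n)
}

jzs_bf10_one <- function(t, n, scale, rel_tol) {
  nu <- n - 1
  # log integrand in g: t likelihood scaled by (1+ng)^-1/2, times the
  # InverseGamma(1/2, scale^2/2) mixing density
  log_fg <- function(g) {
    -0.5 * log1p(n * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) +
      log(scale) - 0.5 * log(2 * pi) - 1.5 * log(g) - scale^2 / (2 * g)
  }
  # substitution g = scale^2 tan^2(theta), dg = 2 scale^2 tan sec^2 dtheta
  integrand <- function(theta) {
    g <- scale^2 * tan(theta)^2
    val <- exp(log_fg(g) + log(2 * scale^2) + log(tan(theta)) +
                 2 * log(1 / cos(theta)))
    val[!is.finite(val)] <- 0
    val
  }
  num <- tryCatch(
    stats::integrate(integrand, 0, pi / 2, rel.tol = rel_tol,
                     subdivisions = 500L),
    error = function(e) {
      stop("JZS quadrature failed to converge (t = ", t, ", n = ", n,
           "): ", conditionMessage(e), call. = FALSE)
    }
  )
  log_den <- -(nu + 1) / 2 * log1p(t^2 / nu)
  exp(log(num$value) - log_den)
}

#' Categorize a Bayes factor into conventional evidence bands
#'
#' BF10 above 1 favours the alternative: 1-3 anecdotal, 3-10 moderate,
#' 10-30 strong, above 30 very strong. Below 1 the reciprocal bands favour
#' the null: 1/3-1 anecdotal, 1/10-1/3 moderate, 1/30-1/10 strong, below
#' 1/30 very strong. A value falling exactly on a band edge is assigned to
#' the stronger-evidence band; BF10 = 1 (equally consistent with both
#' hypotheses) is labelled anecdotal for the alternative.
#'
#' @param bf10 Positive Bayes factor(s); vectorised.
#' @return Character vector of labels such as `"moderate (H1)"`.
#' @examples
#' bf_evidence(c(242.35, 1.08, 0.11))
#' @export
bf_evidence <- function(bf10) {
  if (any(bf10 <= 0)) stop("`bf10` must be positive.", call. = FALSE)
  lab <- function(b) {
    if (b >= 30) "very strong (H1)"
    else if (b >= 10) "strong (H1)"
    else if (b >= 3) "moderate (H1)"
    else if (b >= 1) "anecdotal (H1)"
    else if (b > 1 / 3) "anecdotal (H0)"
    else if (b > 1 / 10) "moderate (H0)"
    else if (b > 1 / 30) "strong (H0)"
    else "very strong (H0)"
  }
  vapply(bf10, lab, character(1))
}

#' Paired (dependent-samples) t test with effect size and Bayes factor
#'
#' Classical one-sample t test on the paired differences, augmented with
#' the paired-design Cohen effect size d_z = |mean difference| / SD of
#' differences (equal to |t|/sqrt(n)), the JZS Bayes factor, its evidence
#' label, and a significance flag at the multiple-comparison-corrected
#' criterion `alpha`.
#'
#' @param a First condition's values, or (if `b` is `NULL`) the differences
#'   themselves.
#' @param b Optional second condition's values; differences are `a - b`.
#' @param variable Optional label carried into the output.
#' @param alpha Significance criterion for the `significant` flag (default
#'   .005, the conventional correction for a battery of such tests).
#' @param bf_scale Cauchy prior scale for the Bayes factor.
#' @return A one-row tibble: `variable`, `n`, `mean_a`, `mean_b`, `sd_a`,
#'   `sd_b` (NA when only differences were supplied), `mean_diff`, `t`,
#'   `df`, `p`, `ci_low`, `ci_high` (95\% CI of the mean difference),
#'   `cohen_d`, `bf10`, `evidence`, `significant`.
#' @examples
#' paired_t(c(1, 2, 3, 4)) # t = 3.873 on df 3
#' @export
paired_t <- function(a, b = NULL, variable = NA_character_, alpha = 0.005,
                     bf_scale = 0.707) {
  if (!is.null(b)) {
    if (length(a) != length(b)) {
      stop("`a` and `b` must have equal length.", call. = FALSE)
    }
    keep <- is.finite(a) & is.finite(b)
    a2 <- a[keep]
    b2 <- b[keep]
    d <- a2 - b2
    mean_a <- mean(a2); mean_b <- mean(b2)
    sd_a <- stats::sd(a2); sd_b <- stats::sd(b2)
  } else {
    d <- a[is.finite(a)]
    mean_a <- mean_b <- sd_a <- sd_b <- NA_real_
  }
  n <- length(d)
  if (n < 2) stop("Need at least 2 complete pairs.", call. = FALSE)
  if (stats::sd(d) == 0) {
    stop("Degenerate input: paired differences have zero variance.",
         call. = FALSE)
  }
  ht <- stats::t.test(d)
  tstat <- unname(ht$statistic)
  tibble::tibble(
    variable = variable,
    n = n,
    mean_a = mean_a, mean_b = mean_b, sd_a = sd_a, sd_b = sd_b,
    mean_diff = mean(d),
    t = tstat,
    df = unname(ht$parameter),
    p = ht$p.value,
    ci_low = ht$conf.int[1],
    ci_high = ht$conf.int[2],
    cohen_d = abs(mean(d)) / stats::sd(d),
    bf10 = jzs_bf10(tstat, n, scale = bf_scale),
    evidence = bf_evidence(jzs_bf10(tstat, n, scale = bf_scale)),
    significant = ht$p.value < alpha
  )
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch–Satterthwaite (fractional) degrees of
#' freedom.
#'
#' @param x,y Independent samples (each of length >= 2).
#' @return A one-row tibble: `t`, `df`, `p`, `ci_low`, `ci_high`,
#'   `mean_x`, `mean_y`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 4, 6))
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("Each sample needs at least 2 finite values.", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("Degenerate input: both samples have zero variance.", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
    ci_low = ht$conf.int[1], ci_high = ht$conf.int[2],
    mean_x = mean(x), mean_y = mean(y)
  )
}

#' Fisher-z confidence interval for a correlation
#'
#' Transforms r to z = atanh(r), builds a Gaussian interval with standard
#' error 1/sqrt(n - 3), and maps back. Useful when only the printed r and n
#' are available; [pearson_r_ci()] applies it to raw data.
#'
#' @param r Pearson correlation in (-1, 1).
#' @param n Number of pairs (> 3).
#' @param conf_level Confidence level.
#' @return A one-row tibble with `r`, `n`, `ci_low`, `ci_high`.
#' @examples
#' fisher_z_ci(0.48, 123) # (0.33, 0.61)
#' @export
fisher_z_ci <- function(r, n, conf_level = 0.95) {
  if (any(abs(r) >= 1)) stop("`r` must lie strictly inside (-1, 1).", call. = FALSE)
  if (any(n <= 3)) stop("`n` must exceed 3.", call. = FALSE)
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
  tibble::tibble(r = r, n = n, ci_low = tanh(z - half),
                 ci_high = tanh(z + half))
}

#' Pearson correlation with p value and Fisher-z interval
#'
#' @param x,y Paired numeric vectors (n >= 4 complete pairs).
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble: `r`, `n`, `t`, `df`, `p`, `ci_low`, `ci_high`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); pearson_r_ci(x, x + rnorm(50))
#' @export
pearson_r_ci <- function(x, y, conf_level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("Need at least 4 complete pairs.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Degenerate input: zero variance in a margin.", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, conf.level = conf_level)
  r <- unname(ht$estimate)
  ci <- if (abs(r) >= 1) {
    tibble::tibble(ci_low = r, ci_high = r) # degenerate: perfectly linear
  } else {
    fisher_z_ci(r, n, conf_level)
  }
  tibble::tibble(
    r = r, n = n, t = unname(ht$statistic),
    df = unname(ht$parameter), p = ht$p.value,
    ci_low = ci$ci_low, ci_high = ci$ci_high
  )
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p value by summing the probabilities of all tables (with
#' the observed margins) no more probable than the observed one. A table
#' with an all-zero row or column is degenerate and returns p = 1.
#'
#' @param a,b,c,d Nonnegative integer cell counts, row-wise:
#'   rows are groups, columns outcomes.
#' @return A one-row tibble with `p` and `odds_ratio` (conditional MLE).
#' @examples
#' fisher_exact_2x2(1, 9, 11, 3) # p = 0.002759
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("Cell counts must be nonnegative integers.", call. = FALSE)
  }
  if (sum(counts) == 0) stop("All-zero table.", call. = FALSE)
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  ht <- stats::fisher.test(tab)
  tibble::tibble(p = ht$p.value, odds_ratio = unname(ht$estimate))
}
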
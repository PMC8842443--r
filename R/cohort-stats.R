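#' Designate a mouse as hyperglycemic
#'
#' A mouse is designated hyperglycemic when two consecutive weekly blood
#' glucose readings both exceed 250 mg/dL.
#'
#' @param glucose_mgdl numeric vector of weekly readings in week order
#'   (>= 2 readings).
#' @param cutoff_mgdl designation cutoff, mg/dL.
#' @return Logical.
#' @export
designate_hyperglycemic <- function(glucose_mgdl, cutoff_mgdl = 250) {
  n <- length(glucose_mgdl)
  if (n < 2)
    stop("designation needs at least 2 weekly readings")
  any(glucose_mgdl[-n] > cutoff_mgdl & glucose_mgdl[-1] > cutoff_mgdl)
}

#' Capillary stall rate
#'
#' Percentage of capillary segments observed stalled. The value is exact
#' (`100 * stalled / total`); the printed convention truncates to two
#' decimals (9 stalls in 589 segments prints as 1.52%).
#'
#' @param stalled logical vector of per-segment stall flags, or an
#'   integer count when `n` is given.
#' @param n total number of segments (when `stalled` is a count).
#' @return Stall rate in percent, with the truncated display string in
#'   attribute `display`.
#' @export
stall_rate <- function(stalled, n = NULL) {
  if (is.null(n)) {
    if (length(stalled) == 0) stop("no segments supplied")
    k <- sum(stalled); n <- length(stalled)
  } else {
    k <- stalled
    if (n < 1) stop("no segments supplied")
  }
  rate <- 100 * k / n
  attr(rate, "display") <- sprintf("%.2f%%", trunc(rate * 100) / 100)
  rate
}

#' Two-sided normal tolerance factor
#'
#' Exact factor `k` such that the interval `mean +/- k * sd` of a normal
#' sample of size `n` covers at least a proportion `coverage` of the
#' population with probability `conf`. Computed numerically from the
#' noncentral chi-square formulation: for each value of the standardised
#' sample mean the minimal half-width covering `coverage` is found by
#' root-finding, and `k` solves the resulting confidence integral. The
#' Howe approximation is available as a cheap fallback.
#'
#' @param n sample size (>= 2).
#' @param coverage population proportion to cover.
#' @param conf confidence level.
#' @param method `"exact"` (default) or `"howe"`.
#' @return The tolerance factor.
#' @export
tolerance_factor_normal <- function(n, coverage = 0.95, conf = 0.95,
                                    method = c("exact", "howe")) {
  stopifnot(n >= 2, coverage > 0, coverage < 1, conf > 0, conf < 1)
  method <- match.arg(method)
  if (method == "howe") {
    u <- stats::qnorm((1 + coverage) / 2)
    return(u * sqrt((n - 1) * (1 + 1 / n) /
                      stats::qchisq(1 - conf, n - 1)))
  }
  # r(u): half-width (in sigma) covering `coverage` centred at offset u
  r_of_u <- function(u) {
    stats::uniroot(function(r)
      stats::pnorm(u + r) - stats::pnorm(u - r) - coverage,
      lower = 1e-8, upper = 40, tol = 1e-10)$root
  }
  confidence <- function(k) {
    f <- Vectorize(function(z) {
      r <- r_of_u(z / sqrt(n))
      stats::pchisq((n - 1) * r^2 / k^2, df = n - 1,
                    lower.tail = FALSE) * stats::dnorm(z)
    })
    2 * stats::integrate(f, 0, 9, rel.tol = 1e-9)$value
  }
  stats::uniroot(function(k) confidence(k) - conf,
                 lower = stats::qnorm((1 + coverage) / 2),
                 upper = 60, tol = 1e-7)$root
}

#' Bland-Altman agreement of grader flux counts
#'
#' With no established ground truth for RBC flux, the per-capillary mean
#' across graders serves as the reference. For each grader the
#' differences `d = grader - reference` give the bias (mean of `d`), the
#' limits of agreement (bias +/- 1.96 sd(d)), a t-interval for the bias,
#' and exact tolerance-factor confidence intervals for the limits: the
#' outer bound of each limit is `bias +/- k * sd` with
#' `k = tolerance_factor_normal(n)`, the inner bound its mirror image
#' about the limit.
#'
#' @param grader_counts numeric matrix, capillaries x graders (>= 3
#'   capillaries, >= 2 graders, no missing cells).
#' @param conf confidence level for the intervals.
#' @param tol_method tolerance-factor method, see
#'   [tolerance_factor_normal()].
#' @return A data frame with one row per grader: `grader`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `ci_bias_low`, `ci_bias_high`,
#'   `ci_loa_low_lo/hi`, `ci_loa_high_lo/hi`, `n`, `degenerate` (flag for
#'   a zero-variance grader whose limits collapse onto the bias).
#' @export
bland_altman <- function(grader_counts, conf = 0.95,
                         tol_method = "exact") {
  m <- as.matrix(grader_counts)
  if (ncol(m) < 2) stop("need at least 2 graders")
  if (nrow(m) < 3) stop("need at least 3 capillaries")
  if (anyNA(m)) stop("grader table has missing cells")
  truth <- rowMeans(m)
  n <- nrow(m)
  k_tol <- tolerance_factor_normal(n, coverage = 0.95, conf = conf,
                                   method = tol_method)
  t_q <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  res <- lapply(seq_len(ncol(m)), function(j) {
    d <- m[, j] - truth
    bias <- mean(d); s <- stats::sd(d)
    degenerate <- s == 0
    se <- s / sqrt(n)
    data.frame(grader = colnames(m)[j] %||% paste0("grader_", j),
               bias = bias, sd_diff = s,
               loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
               ci_bias_low = bias - t_q * se,
               ci_bias_high = bias + t_q * se,
               ci_loa_low_lo = bias - k_tol * s,
               ci_loa_low_hi = bias - (2 * 1.96 - k_tol) * s,
               ci_loa_high_lo = bias + (2 * 1.96 - k_tol) * s,
               ci_loa_high_hi = bias + k_tol * s,
               n = n, degenerate = degenerate)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Fisher-Pearson standardised moment coefficient (skewness)
#'
#' `skew = n^2 / ((n-1)(n-2)) * m3 / s^3` with `m3` the third central
#' moment (divisor `n`) and `s` the sample SD (divisor `n-1`); the
#' spreadsheet SKEW convention.
#'
#' @param x numeric sample, `n >= 3`, nonzero variance.
#' @return Adjusted skewness.
#' @export
adjusted_skew <- function(x) {
  n <- length(x)
  if (n < 3) stop("skewness needs n >= 3")
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: skewness undefined")
  m3 <- mean((x - mean(x))^3)
  n^2 / ((n - 1) * (n - 2)) * m3 / s^3
}

#' Bias-adjusted excess kurtosis
#'
#' The spreadsheet KURT convention:
#' `n(n+1)/((n-1)(n-2)(n-3)) * sum(((x - mean)/s)^4) -
#'  3 (n-1)^2 / ((n-2)(n-3))`.
#'
#' @param x numeric sample, `n >= 4`, nonzero variance.
#' @return Excess kurtosis (0 for a normal population in expectation).
#' @export
excess_kurtosis <- function(x) {
  n <- length(x)
  if (n < 4) stop("kurtosis needs n >= 4")
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: kurtosis undefined")
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) *
    sum(((x - mean(x)) / s)^4) - 3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Two-sample comparison by Student's t-test
#'
#' Two-tailed unpaired Student's test with pooled variance (the named
#' test's equal-variance assumption); Welch's correction is available
#' behind `var_equal = FALSE`.
#'
#' @param a,b numeric samples (each `n >= 2`).
#' @param var_equal pool the variances (default `TRUE`).
#' @return A list of class `group_comparison`: per-group `mean`, `sd`,
#'   `n`, plus `t` and two-tailed `p`.
#' @export
group_compare <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(structure(list(mean = c(mean(a), mean(b)),
                            sd = c(0, 0), n = c(length(a), length(b)),
                            t = 0, p = 1), class = "group_comparison"))
    stop("zero pooled variance with unequal means: t is unbounded")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(mean = c(mean(a), mean(b)),
                 sd = c(stats::sd(a), stats::sd(b)),
                 n = c(length(a), length(b)),
                 t = unname(ht$statistic), p = ht$p.value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group A: %.2f +/- %.2f (n=%d)\ngroup B: %.2f +/- %.2f (n=%d)\nt = %.3f, two-tailed p = %.3g\n",
              x$mean[1], x$sd[1], x$n[1], x$mean[2], x$sd[2], x$n[2],
              x$t, x$p))
  invisible(x)
}

#' Ordinary least-squares slope and Pearson R-squared
#'
#' @param x,y numeric vectors (`n >= 3`, `var(x) > 0`).
#' @return A list of class `regression_summary` with `slope`,
#'   `intercept`, `r_squared` (squared Pearson correlation) and `n`.
#' @export
regression_r2_slope <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("regression needs n >= 3")
  if (stats::var(x) == 0) stop("var(x) = 0: slope undefined")
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(x, y)^2, n = length(x)),
            class = "regression_summary")
}

#' Age group of a postnatal week
#'
#' Young adults are postnatal weeks 5-12, mature adults week 13 on.
#'
#' @param week postnatal week (>= 5; earlier weeks are outside the
#'   analysis epoch).
#' @return `"young"` or `"mature"` (vectorised).
#' @export
age_group <- function(week) {
  if (any(week < 5)) stop("weeks before 5 are outside the study epoch")
  ifelse(week <= 12, "young", "mature")
}

#' Per-week, per-group mean and SD of a cohort variable
#'
#' @param cohort a [simulate_cohort()] result (or any list with `mice`,
#'   `capillaries`, `thickness` data frames).
#' @param variable one of `"glucose_mgdl"`, `"weight_g"`,
#'   `"flux_cells_s"`, `"diameter_um"`, `"thickness_um"`.
#' @return Data frame `group, week, mean, sd, n`, weeks without data
#'   omitted.
#' @export
weekly_summary <- function(cohort, variable) {
  tabs <- list(glucose_mgdl = "mice", weight_g = "mice",
               flux_cells_s = "capillaries", diameter_um = "capillaries",
               thickness_um = "thickness")
  if (!variable %in% names(tabs))
    stop("unknown variable: ", variable)
  df <- cohort[[tabs[[variable]]]]
  agg <- stats::aggregate(df[[variable]],
                          by = list(group = df$group, week = df$week),
                          FUN = function(v) c(mean = mean(v),
                                              sd = if (length(v) > 1)
                                                stats::sd(v) else 0,
                                              n = length(v)))
  out <- data.frame(group = agg$group, week = agg$week,
                    mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                    n = as.integer(agg$x[, "n"]))
  out[order(out$group, out$week), ]
}
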
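# Cohort statistics: normality battery, routed two-sample comparison,
# chi-squared for categorical composition, and group comparison tables.
#
# Shapiro-Wilk and Kolmogorov-Smirnov statistics come from stats::; the
# Anderson-Darling and D'Agostino-Pearson tests (and the estimated-parameter
# Lilliefors p-value) have no implementation in the installed stack and are
# coded from the standard published approximations.

# Anderson-Darling normality test (mean and variance estimated), p-value from
# the piecewise formula for the modified statistic A*^2 = A^2 (1 + 0.75/n +
# 2.25/n^2) in D'Agostino & Stephens (1986).
ad_normality <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(p) + log(1 - rev(p))))
  A <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  pval <- if (A < 0.2) {
    1 - exp(-13.436 + 101.14 * A - 223.73 * A^2)
  } else if (A < 0.34) {
    1 - exp(-8.318 + 42.796 * A - 59.938 * A^2)
  } else if (A < 0.6) {
    exp(0.9177 - 4.279 * A - 1.38 * A^2)
  } else {
    exp(1.2937 - 5.709 * A + 0.0186 * A^2)
  }
  list(statistic = A2, p_value = min(max(pval, 0), 1))
}

# D'Agostino-Pearson omnibus K^2: squared sum of the D'Agostino (1970)
# skewness z and the Anscombe-Glynn (1983) kurtosis z, referred to chi^2(2).
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  # skewness transform
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zg1 <- delta * asinh(Y / alpha)
  # kurtosis transform
  Eg2 <- -6 / (n + 1)
  Vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eg2) / sqrt(Vg2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  Zg2 <- ((1 - 2 / (9 * A)) -
            ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zg1^2 + Zg2^2
  list(statistic = K2, p_value = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

# Lilliefors (Kolmogorov-Smirnov with estimated mean and SD); p-value by the
# Dallal-Wilkinson (1986) approximation, which is designed for p <= 0.10 and
# is clamped to [0, 1] here (larger values mean only "clearly not rejected").
lilliefors <- function(x) {
  n <- length(x)
  p <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  D <- max(i / n - p, p - (i - 1) / n)
  if (n > 100) {
    Kd <- D * (n / 100)^0.49
    nd <- 100
  } else {
    Kd <- D
    nd <- n
  }
  pval <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
                2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
                0.974598 / sqrt(nd) + 1.67997 / nd)
  list(statistic = D, p_value = min(max(pval, 0), 1))
}

#' Normality battery
#'
#' Runs the four normality tests of the analysis protocol — Anderson-Darling,
#' D'Agostino-Pearson, Shapiro-Wilk and Kolmogorov-Smirnov (Lilliefors,
#' parameters estimated) — on one sample. All four are reported; the verdict
#' that routes downstream comparisons is gated on Shapiro-Wilk alone
#' (`p >= alpha` means "treat as normal"), since the protocol names four tests
#' but no combination rule.
#'
#' @param x Numeric sample, `n >= 8` and non-constant.
#' @param alpha Gate level (default 0.05).
#' @return Object of class `normality_report`: data frame `tests` (test,
#'   statistic, p_value), logical `normal`, `n`, `alpha`.
#' @export
normality_battery <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (anyNA(x)) x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("normality battery requires n >= 8", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate (constant) sample: normality undefined", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  ad <- ad_normality(x)
  dp <- dagostino_pearson(x)
  ks <- lilliefors(x)
  tests <- data.frame(
    test = c("Anderson-Darling", "D'Agostino-Pearson", "Shapiro-Wilk",
             "Kolmogorov-Smirnov (Lilliefors)"),
    statistic = c(ad$statistic, dp$statistic, unname(sw$statistic), ks$statistic),
    p_value = c(ad$p_value, dp$p_value, sw$p.value, ks$p_value)
  )
  structure(
    list(tests = tests, normal = sw$p.value >= alpha, n = n, alpha = alpha),
    class = "normality_report"
  )
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf("Normality battery (n = %d): verdict %s (Shapiro-Wilk gate at alpha = %g)\n",
              x$n, if (x$normal) "normal" else "non-normal", x$alpha))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

new_test_result <- function(test, statistic, p_value, route, alpha) {
  structure(
    list(test = test, statistic = unname(statistic), p_value = p_value,
         significant = p_value < alpha, route = route, alpha = alpha),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s (%s route): statistic = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$test, x$route, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Normality-routed two-sample comparison
#'
#' The protocol's comparison step: if both samples pass the normality gate
#' (see [normality_battery()]) the Welch independent-samples t-test is used,
#' otherwise the two-sided Mann-Whitney U test (exact for small untied
#' samples, normal approximation with tie correction otherwise). Samples too
#' small for the battery (`n < 8`) or constant samples route non-parametric
#' with a warning.
#'
#' @param a,b Numeric samples, each `n >= 2`.
#' @param alpha Significance level (default 0.05).
#' @return A `test_result` (test, statistic, p_value, significant, route,
#'   alpha) with the two `normality` reports attached (or `NULL` where
#'   unavailable).
#' @export
compare_two_samples <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a[!is.na(a)])
  b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2 || length(b) < 2) {
    stop("both samples need n >= 2", call. = FALSE)
  }
  battery <- function(x) {
    tryCatch(normality_battery(x, alpha), error = function(e) NULL)
  }
  na <- battery(a)
  nb <- battery(b)
  small <- length(a) < 8 || length(b) < 8
  degenerate <- stats::sd(a) == 0 || stats::sd(b) == 0
  if (small) {
    warning("sample(s) too small for the normality battery (n < 8); routing non-parametric",
            call. = FALSE)
  }
  normal_route <- !small && !degenerate && !is.null(na) && !is.null(nb) &&
    na$normal && nb$normal
  res <- if (normal_route) {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    new_test_result("Welch two-sample t-test", tt$statistic, tt$p.value,
                    "parametric", alpha)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL, correct = TRUE))
    p <- wt$p.value
    # every observation tied across both samples: no evidence of a difference
    if (!is.finite(p)) p <- 1
    new_test_result("Mann-Whitney U", wt$statistic, p,
                    "nonparametric", alpha)
  }
  res$normality <- list(a = na, b = nb)
  res
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson chi-squared with `df = (r-1)(c-1)` and no continuity correction,
#' as used for group composition (e.g. the gender-by-group table). Warns when
#' any expected count falls below 5.
#'
#' @param counts Matrix of non-negative counts with positive row and column
#'   margins.
#' @param alpha Significance level.
#' @return A `test_result` with `df` and the `expected` matrix attached.
#' @export
chi_square_counts <- function(counts, alpha = 0.05) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ct$expected < 5)) {
    warning("some expected counts are below 5; the chi-squared approximation may be poor",
            call. = FALSE)
  }
  res <- new_test_result("Pearson chi-squared", ct$statistic, ct$p.value,
                         "parametric", alpha)
  res$df <- unname(ct$parameter)
  res$expected <- ct$expected
  res
}

#' Per-group summary of one metric
#'
#' `n`, mean, SD and SEM (`sd / sqrt(n)`) of a metric within one group. Both
#' dispersion readings are reported because the source table's `+/-` entries
#' are interpretable as SEM for the lesion metrics but as SD for the
#' parenchyma rows.
#'
#' @param x Numeric values (missing entries dropped).
#' @param group Group label.
#' @param metric Metric name.
#' @return One-row data frame `metric, group, n, mean, sd, sem`.
#' @export
group_summary <- function(x, group, metric) {
  x <- x[!is.na(x)]
  n <- length(x)
  s <- if (n >= 2) stats::sd(x) else NA_real_
  data.frame(metric = metric, group = group, n = n,
             mean = if (n >= 1) mean(x) else NA_real_,
             sd = s, sem = s / sqrt(n))
}

#' Group comparison table over a measurement cohort
#'
#' The cohort-level statistics stage: for every metric of the measurement
#' record, per-group summaries (n, mean, SD, SEM) and all pairwise
#' normality-routed two-sample comparisons between the groups present.
#' Raw p-values are reported; no multiple-testing adjustment is applied.
#' Groups with fewer than 2 non-missing values for a metric are skipped for
#' that metric with a warning.
#'
#' @param measurements Data frame in the measurement column contract (see
#'   [measurements_to_df()]) with a populated `group` column, or a list of
#'   `lesion_measurement` records.
#' @param alpha Significance level (default 0.05).
#' @param metrics Character vector of metric columns to analyze; defaults to
#'   every numeric metric in the contract.
#' @return Object of class `comparison_table`: data frames `summaries` and
#'   `tests` (metric, pair, route, statistic, p_value, significant).
#' @export
build_comparison_table <- function(measurements, alpha = 0.05, metrics = NULL) {
  df <- measurements_to_df(measurements)
  df <- df[!is.na(df$group), , drop = FALSE]
  groups <- unique(df$group)
  if (length(groups) < 2L) {
    stop("need at least 2 groups with measurements to compare", call. = FALSE)
  }
  if (is.null(metrics)) {
    metrics <- setdiff(measurement_columns(), c("image_id", "group"))
  }
  summaries <- NULL
  tests <- NULL
  for (metric in metrics) {
    vals <- split(df[[metric]], df$group)
    ok <- names(vals)[vapply(vals, function(v) sum(!is.na(v)) >= 2L, logical(1))]
    skipped <- setdiff(groups, ok)
    if (length(skipped)) {
      warning(sprintf("metric '%s': group(s) %s have < 2 values and were skipped",
                      metric, paste(skipped, collapse = ", ")), call. = FALSE)
    }
    for (g in ok) {
      summaries <- rbind(summaries, group_summary(vals[[g]], g, metric))
    }
    if (length(ok) >= 2L) {
      prs <- utils::combn(ok, 2L)
      for (k in seq_len(ncol(prs))) {
        g1 <- prs[1, k]; g2 <- prs[2, k]
        res <- suppressWarnings(
          compare_two_samples(vals[[g1]][!is.na(vals[[g1]])],
                              vals[[g2]][!is.na(vals[[g2]])], alpha = alpha)
        )
        tests <- rbind(tests, data.frame(
          metric = metric, pair = sprintf("%s vs %s", g1, g2),
          route = res$route, statistic = res$statistic,
          p_value = res$p_value, significant = res$significant
        ))
      }
    }
  }
  structure(list(summaries = summaries, tests = tests, alpha = alpha),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("Group comparison table (alpha = %g)\n\nSummaries:\n", x$alpha))
  print(x$summaries, row.names = FALSE, digits = 4)
  cat("\nPairwise tests (raw p-values, no multiplicity adjustment):\n")
  print(x$tests, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' Writes two UTF-8 CSVs next to `stem`: `<stem>_summaries.csv` (metric,
#' group, n, mean, sd, sem) and `<stem>_tests.csv` (metric, pair, route,
#' statistic, p_value, significant).
#'
#' @param table A [build_comparison_table()] result.
#' @param stem Output path stem (without extension).
#' @return Character vector of the two paths, invisibly.
#' @export
write_comparison_table <- function(table, stem) {
  stopifnot(inherits(table, "comparison_table"))
  paths <- paste0(stem, c("_summaries.csv", "_tests.csv"))
  utf8_write_csv(table$summaries, paths[1])
  utf8_write_csv(table$tests, paths[2])
  invisible(paths)
}
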
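#' Bland-Altman agreement between a method and a reference
#'
#' Differences are taken as `method - reference` (CMR minus histology in the
#' study design, so underestimation of the AAR gives a negative bias). Limits
#' of agreement use the classical 1.96 multiplier on the sample SD of the
#' differences.
#'
#' @param reference,method Paired numeric vectors (one value per animal).
#' @param reference_label,method_label Labels used in printing/plotting.
#' @return An object of class `bland_altman` with `n`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, and the per-pair means and differences.
#' @export
bland_altman <- function(reference, method,
                         reference_label = "reference", method_label = "method") {
  if (length(reference) != length(method)) stop("mismatched lengths")
  ok <- is.finite(reference) & is.finite(method)
  reference <- reference[ok]; method <- method[ok]
  n <- length(reference)
  if (n < 2) stop("at least 2 paired observations are required")
  d <- method - reference
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(n = n, bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 means = (method + reference) / 2, diffs = d,
                 reference_label = reference_label,
                 method_label = method_label),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> %s - %s (n = %d): bias %.3f, LoA [%.3f, %.3f]\n",
              x$method_label, x$reference_label, x$n, x$bias, x$loa_low,
              x$loa_high))
  invisible(x)
}

#' @export
#' @param x A `bland_altman` object.
#' @param ... Passed to [graphics::plot()].
#' @rdname bland_altman
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs,
                 xlab = sprintf("mean of %s and %s", x$method_label, x$reference_label),
                 ylab = sprintf("%s - %s", x$method_label, x$reference_label),
                 pch = 19, ...)
  graphics::abline(h = x$bias, col = "blue", lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "red", lty = 2)
  invisible(x)
}

.test_result <- function(test, statistic, df, p, p_adjusted = NA_real_,
                         groups = NULL, n = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p = p, p_adjusted = p_adjusted, groups = groups, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: stat %.4f, df %s, p %.4g", x$test,
              x$statistic, paste(signif(x$df, 5), collapse = ","), x$p))
  if (!is.na(x$p_adjusted)) cat(sprintf(" (adj. %.4g)", x$p_adjusted))
  cat("\n")
  invisible(x)
}

#' Paired two-sided t-test
#'
#' Thin wrapper over [stats::t.test()] with explicit degenerate-variance
#' contracts: all differences zero gives `t = 0, p = 1`; zero variance with a
#' non-zero mean difference gives `p = 0`.
#'
#' @param reference,method Paired vectors.
#' @return A `test_result`.
#' @export
paired_t <- function(reference, method) {
  if (length(reference) != length(method)) stop("mismatched lengths")
  if (length(reference) < 2) stop("at least 2 pairs are required")
  d <- method - reference
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(.test_result("paired t", 0, length(d) - 1, 1))
    return(.test_result("paired t", sign(mean(d)) * Inf, length(d) - 1, 0))
  }
  tt <- stats::t.test(method, reference, paired = TRUE)
  .test_result("paired t", unname(tt$statistic), unname(tt$parameter),
               tt$p.value, n = length(d))
}

#' Unpaired two-sided t-test
#'
#' Pooled-variance (Student) by default; Welch available via
#' `var_equal = FALSE`.
#'
#' @param group_a,group_b Numeric vectors.
#' @param var_equal Assume equal variances (pooled SD).
#' @return A `test_result`.
#' @export
unpaired_t <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    dd <- mean(group_a) - mean(group_b)
    df <- length(group_a) + length(group_b) - 2
    if (dd == 0) return(.test_result("unpaired t", 0, df, 1))
    return(.test_result("unpaired t", sign(dd) * Inf, df, 0))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  .test_result(if (var_equal) "unpaired t" else "Welch t",
               unname(tt$statistic), unname(tt$parameter), tt$p.value,
               n = c(length(group_a), length(group_b)))
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Omnibus F test across all groups, followed by all pairwise pooled-variance
#' t-tests with Bonferroni multiplicity adjustment
#' `p_adj = min(1, m * p_raw)` where `m` is the number of pairs.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return List with `omnibus` (a `test_result`) and `pairwise` (a data
#'   frame with raw and adjusted p-values).
#' @export
anova_bonferroni <- function(groups) {
  if (length(groups) < 2) stop("at least 2 groups are required")
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  gm <- tapply(y, g, mean)
  ssb <- sum(ns * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  if (ssw == 0) {
    omnibus <- if (ssb == 0) .test_result("one-way ANOVA", 0, c(df1, df2), 1)
               else .test_result("one-way ANOVA", Inf, c(df1, df2), 0)
  } else {
    f <- (ssb / df1) / (ssw / df2)
    omnibus <- .test_result("one-way ANOVA", f, c(df1, df2),
                            stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  prs <- utils::combn(names(groups), 2)
  m <- ncol(prs)
  pairwise <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    tt <- unpaired_t(groups[[a]], groups[[b]])
    data.frame(group_a = a, group_b = b, statistic = tt$statistic,
               df = tt$df, p_raw = tt$p,
               p_adjusted = min(1, m * tt$p), stringsAsFactors = FALSE)
  }))
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Group summaries of regional metrics
#'
#' Mean, sample SD and n per group for the requested metric columns, with a
#' formatted `"mean ± SD"` string per cell (SD left blank for single-animal
#' cells).
#'
#' @param metrics Metrics data frame with a `group` column.
#' @param value_cols Metric columns to summarise; default all numeric columns.
#' @return A long-format data frame (group, metric, n, mean, sd, formatted).
#' @export
group_summary <- function(metrics, value_cols = NULL) {
  if (is.null(value_cols)) {
    value_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
    value_cols <- setdiff(value_cols, "seed")
  }
  out <- list()
  for (g in unique(metrics$group)) {
    sub <- metrics[metrics$group == g, , drop = FALSE]
    for (cl in value_cols) {
      v <- sub[[cl]]; v <- v[is.finite(v)]
      n <- length(v)
      mu <- if (n > 0) mean(v) else NA_real_
      sdv <- if (n > 1) stats::sd(v) else NA_real_
      fmt <- if (n == 0) "" else if (is.na(sdv)) sprintf("%.1f ± ", mu)
             else sprintf("%.1f ± %.1f", mu, sdv)
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = cl, n = n, mean = mu, sd = sdv,
        formatted = fmt, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
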
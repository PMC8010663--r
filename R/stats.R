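# Group-comparison decision flow and regression used for the cohort
# analysis: outlier screening, Shapiro-Wilk + Levene gating between the
# independent-samples t-test and the Mann-Whitney U test, and ordinary
# least-squares regression.

#' Screen a sample for outliers (1.5 x IQR rule)
#'
#' The reproducible surrogate for graphical stem-and-leaf screening: values
#' outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are flagged. Nothing is removed
#' here; removal is an explicit, logged choice of the caller (see
#' [compare_groups()]).
#'
#' @param values Numeric sample.
#' @param ids Identifiers aligned with `values`.
#' @return List with `kept`, `flagged_ids`, `flagged` (logical) and the
#'   `bounds`. Samples with fewer than 3 values pass through unflagged.
#' @examples
#' screen_outliers(c(1, 2, 3, 4, 100))
#' @export
screen_outliers <- function(values, ids = seq_along(values)) {
  stopifnot(length(ids) == length(values))
  if (length(values) < 3L)
    return(list(kept = values, flagged_ids = ids[0],
                flagged = rep(FALSE, length(values)),
                bounds = c(-Inf, Inf)))
  qs <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[2L] - qs[1L]
  bounds <- c(qs[1L] - 1.5 * iqr, qs[2L] + 1.5 * iqr)
  flagged <- values < bounds[1L] | values > bounds[2L]
  list(kept = values[!flagged], flagged_ids = ids[flagged],
       flagged = flagged, bounds = bounds)
}

#' Gated two-group comparison
#'
#' The decision flow for small-sample group comparisons: optional 1.5 x IQR
#' outlier removal, Shapiro-Wilk normality per group and Levene's test for
#' homogeneity of variance; if every gate passes at `alpha` the two-sided
#' independent-samples t-test (pooled variance) is used, otherwise the
#' Mann-Whitney U test (normal approximation with tie correction). All
#' intermediate p-values are reported.
#'
#' @param a,b Numeric samples (>= 3 each).
#' @param alpha Gate and significance level.
#' @param remove_outliers If `TRUE`, values flagged by [screen_outliers()]
#'   are removed per group before testing (and logged in the result).
#' @param ids_a,ids_b Identifiers for outlier logging.
#' @return An object of class `group_comparison`: `test_used`, `statistic`,
#'   `p_value`, `normality_p`, `levene_p`, `outliers_removed` and per-group
#'   summaries. Two identical constant groups yield the explicit
#'   `test_used = "none"` degenerate result.
#' @export
compare_groups <- function(a, b, alpha = 0.05, remove_outliers = FALSE,
                           ids_a = paste0("a", seq_along(a)),
                           ids_b = paste0("b", seq_along(b))) {
  stopifnot(length(a) >= 3L, length(b) >= 3L, all(is.finite(c(a, b))))
  removed <- character(0)
  if (remove_outliers) {
    sa <- screen_outliers(a, ids_a); sb <- screen_outliers(b, ids_b)
    removed <- c(sa$flagged_ids, sb$flagged_ids)
    a <- sa$kept; b <- sb$kept
    if (length(a) < 3L || length(b) < 3L)
      stop("outlier removal left fewer than 3 values in a group")
  }
  summ <- data.frame(group = c("a", "b"),
                     n = c(length(a), length(b)),
                     mean = c(mean(a), mean(b)),
                     sd = c(sd(a), sd(b)))
  if (sd(a) == 0 && sd(b) == 0) {
    return(structure(list(test_used = "none",
                          statistic = NA_real_,
                          p_value = if (mean(a) == mean(b)) NA_real_ else 0,
                          normality_p = c(a = NA_real_, b = NA_real_),
                          levene_p = NA_real_,
                          outliers_removed = removed,
                          group_summaries = summ, alpha = alpha),
                     class = "group_comparison"))
  }
  sw <- function(x) {
    if (sd(x) == 0) return(NA_real_)
    shapiro.test(x)$p.value
  }
  norm_p <- c(a = sw(a), b = sw(b))
  lev <- car::leveneTest(c(a, b) ~ factor(rep(c("a", "b"), c(length(a), length(b)))),
                         center = mean)
  lev_p <- lev[["Pr(>F)"]][1L]
  gate <- all(is.finite(norm_p)) && all(norm_p > alpha) &&
    is.finite(lev_p) && lev_p > alpha
  if (gate) {
    tt <- t.test(a, b, var.equal = TRUE)
    res <- list(test_used = "t_test", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    res <- list(test_used = "mann_whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value)
  }
  structure(c(res, list(normality_p = norm_p, levene_p = lev_p,
                        outliers_removed = removed, group_summaries = summ,
                        alpha = alpha)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$test_used,
      sprintf("stat=%.4g p=%.4g", x$statistic, x$p_value), "\n")
  cat(sprintf("  gates: shapiro a=%.3g b=%.3g, levene=%.3g (alpha=%g)\n",
              x$normality_p[1], x$normality_p[2], x$levene_p, x$alpha))
  if (length(x$outliers_removed))
    cat("  outliers removed:", paste(x$outliers_removed, collapse = ", "), "\n")
  print(x$group_summaries, row.names = FALSE)
  invisible(x)
}

#' Ordinary least-squares regression of y on x
#'
#' Simple linear regression with `R^2 = 1 - SSres/SStot` and the two-sided
#' slope p-value, as used for the GCE-metabolite association.
#'
#' @param x,y Numeric vectors, `n >= 3`; `x` must not be constant.
#' @return An object of class `gce_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @examples
#' r <- regress(1:10, 2 * (1:10))
#' r$slope       # 2
#' r$r_squared   # 1
#' @export
regress <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(c(x, y))))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (var(x) == 0) stop("x is constant; regression is undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients["x", "Pr(>|t|)"]),
                 n = length(x)),
            class = "gce_regression")
}

#' @export
print.gce_regression <- function(x, ...) {
  cat(sprintf("<gce_regression> y = %.4g + %.4g x, R^2 = %.3f, p = %.4g, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Square-root transform utility
#'
#' Convenience transform used to bring right-skewed latency-type data closer
#' to normality before the gated comparison.
#'
#' @param x Non-negative values.
#' @return `sqrt(x)`.
#' @export
sqrt_transform <- function(x) {
  if (any(x < 0)) stop("square-root transform needs non-negative values")
  sqrt(x)
}
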
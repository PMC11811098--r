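# Method-agreement and group-comparison statistics used to validate blink
# metrics against an existing device: Bland-Altman limits of agreement,
# two-way random absolute-agreement ICC, Cohen's kappa, Spearman rank
# correlation, and a normality-screened two-group comparison.

#' Bland-Altman agreement between two paired measurement series
#'
#' In `"percent"` mode (the default, matching how blink-count agreement is
#' usually reported) each pair contributes the difference as a percentage of
#' the pair mean, `(a - b) / ((a + b) / 2) * 100`; pairs whose mean is zero
#' are excluded. In `"raw"` mode the plain differences `a - b` are used. The
#' 95\% limits of agreement are `mean(d) +/- 1.96 * sd(d)` with the sample
#' standard deviation.
#'
#' @param a,b Equal-length numeric vectors of paired measurements.
#' @param mode `"percent"` or `"raw"`.
#' @return List of class `"agreement"`: `mean_diff`, `loa_low`, `loa_high`,
#'   `sd_diff`, `n_used`, `mode`.
#' @examples
#' bland_altman(c(10, 10), c(9, 11))  # mean 0.50%, LoA [-27.29%, 28.29%]
#' @export
bland_altman <- function(a, b, mode = c("percent", "raw")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stopf("a and b must be paired")
  if (mode == "percent") {
    m <- (a + b) / 2
    keep <- m != 0
    d <- (a[keep] - b[keep]) / m[keep] * 100
  } else {
    d <- a - b
  }
  if (length(d) < 2) stopf("fewer than 2 usable pairs")
  s <- sd(d)
  structure(list(mean_diff = mean(d), loa_low = mean(d) - 1.96 * s,
                 loa_high = mean(d) + 1.96 * s, sd_diff = s,
                 n_used = length(d), mode = mode),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else ""
  cat(sprintf("Bland-Altman (%s): mean difference %.2f%s, 95%% LoA [%.2f%s, %.2f%s], n = %d\n",
              x$mode, x$mean_diff, unit, x$loa_low, unit, x$loa_high, unit,
              x$n_used))
  invisible(x)
}

#' Intraclass correlation, two-way random, absolute agreement, single measure
#'
#' The ICC(A,1) form: targets and raters are both treated as random effects
#' and systematic rater differences count against agreement. Computed from
#' the two-way ANOVA mean squares,
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k / n (MSC - MSE))`,
#' with `MSR`/`MSC`/`MSE` the row (target), column (rater) and residual mean
#' squares. Can be negative when raters disagree more than chance.
#'
#' @param ratings Numeric matrix, one row per target, one column per rater
#'   (at least 3 targets and 2 raters).
#' @return The ICC estimate.
#' @examples
#' icc_absolute(cbind(c(4, 6, 8), c(4.1, 6.2, 7.9)))
#' @export
icc_absolute <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3) stopf("need at least 3 targets")
  if (k < 2) stopf("need at least 2 raters")
  if (anyNA(ratings)) stopf("ratings contain NA")
  if (var(as.vector(ratings)) == 0)
    stopf("constant ratings: ICC undefined")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom == 0) stopf("degenerate ratings: ICC undefined")
  (msr - mse) / denom
}

#' Cohen's kappa for two label sequences
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` over the union of
#' observed categories; invariant under relabeling.
#'
#' @param labels_a,labels_b Equal-length vectors (coerced to character).
#' @return The kappa coefficient in `[-1, 1]`.
#' @examples
#' cohen_kappa(c("x", "x", "y"), c("x", "x", "y")) # 1
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  if (length(labels_a) != length(labels_b) || length(labels_a) == 0)
    stopf("label sequences must be non-empty and aligned")
  lev <- union(labels_a, labels_b)
  pa <- table(factor(labels_a, lev)) / length(labels_a)
  pb <- table(factor(labels_b, lev)) / length(labels_b)
  p_o <- mean(labels_a == labels_b)
  p_e <- sum(pa * pb)
  if (p_e == 1) stopf("degenerate marginals (p_e = 1): kappa undefined")
  (p_o - p_e) / (1 - p_e)
}

#' Spearman rank correlation with a two-sided p-value
#'
#' Rank correlation using average ranks for ties (via
#' [stats::cor.test()]).
#'
#' @param x,y Equal-length numeric vectors, length >= 3, neither constant.
#' @return List with `rho` and `p`.
#' @examples
#' spearman_corr(1:4, c(1, 3, 2, 4)) # rho = 0.8
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must be paired")
  if (length(x) < 3) stopf("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stopf("constant input: rank correlation undefined")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = "two.sided", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Compare two groups with an automatic test choice
#'
#' Screens both groups for normality (Shapiro-Wilk at alpha = 0.05); if both
#' pass, Student's two-sample t-test (equal variances) is used, otherwise
#' the Mann-Whitney U test. The selection is recorded in the result.
#'
#' @param g1,g2 Numeric vectors, each of length >= 3.
#' @param alpha Normality-screen significance level.
#' @return List of class `"group_test"`: `test` (`"t"` or
#'   `"mann-whitney"`), `statistic`, `p`, and `shapiro_p` for both groups.
#' @export
compare_groups <- function(g1, g2, alpha = 0.05) {
  if (length(g1) < 3 || length(g2) < 3)
    stopf("each group needs at least 3 observations")
  sh <- c(shapiro.test(g1)$p.value, shapiro.test(g2)$p.value)
  if (all(sh > alpha)) {
    tt <- t.test(g1, g2, var.equal = TRUE)
    out <- list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
                shapiro_p = sh)
  } else {
    wt <- suppressWarnings(wilcox.test(g1, g2, exact = FALSE))
    out <- list(test = "mann-whitney", statistic = unname(wt$statistic),
                p = wt$p.value, shapiro_p = sh)
  }
  class(out) <- "group_test"
  out
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s test: statistic %.4g, p = %.4g (Shapiro-Wilk p: %.3g, %.3g)\n",
              if (x$test == "t") "Student's t" else "Mann-Whitney U",
              x$statistic, x$p, x$shapiro_p[1], x$shapiro_p[2]))
  invisible(x)
}
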
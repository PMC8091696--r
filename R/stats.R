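#' Interquartile-range outlier exclusion
#'
#' Tukey fence rule: quartiles by linear interpolation of order statistics
#' (type-7 quantiles), values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
#' excluded. Applied within each stage group before summarizing. With fewer
#' than 4 values nothing is excluded (a warning is raised): the fences are
#' not meaningful.
#'
#' @param values Numeric vector.
#' @return A list with `kept` and `excluded` (order preserved in both).
#' @export
#' @examples
#' iqr_filter(c(1, 2, 3, 4, 100)) # excludes 100
iqr_filter <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 4) {
    if (length(values) > 0) warning("fewer than 4 values; no exclusion")
    return(list(kept = values, excluded = numeric(0)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  keep <- values >= lo & values <= hi
  list(kept = values[keep], excluded = values[!keep])
}

#' Pearson correlation with two-sided t test
#'
#' Sample correlation and the two-sided p-value from
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, nonzero variance.
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-sided p-value for a correlation given only (r, n)
#'
#' The same t transform as [pearson_test], evaluated from summary values:
#' useful for checking a reported correlation against its reported p.
#'
#' @param r Correlation coefficient.
#' @param n Sample size (> 2).
#' @return Two-sided p-value.
#' @export
#' @examples
#' pearson_p_from_r(0.628, 69) # ~7.85e-9
pearson_p_from_r <- function(r, n) {
  stopifnot(abs(r) < 1, n > 2)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition across k groups; p from the
#' F(k - 1, N - k) distribution.
#'
#' @param groups List of numeric vectors.
#' @return A list with `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df_between = tab[1, "Df"], df_within = tab[2, "Df"])
}

#' Tukey--Kramer multiple comparisons
#'
#' All pairwise group comparisons after one-way ANOVA: the difference of
#' means is compared against
#' \eqn{q_{\alpha,k,\nu}\sqrt{(MSW/2)(1/n_i + 1/n_j)}}, with q the
#' studentized-range quantile (computed by numerical integration of the
#' studentized-range distribution, via [stats::qtukey]) and MSW the pooled
#' within-group mean square.
#'
#' @param groups List of numeric vectors (length k >= 2).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A data.frame with one row per pair: indices, mean difference,
#'   critical value, adjusted p, and significance flag.
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2, alpha > 0, alpha < 1)
  k <- length(groups)
  n <- lengths(groups)
  if (any(n < 2)) stop("each group needs at least 2 observations")
  means <- vapply(groups, mean, numeric(1))
  df_w <- sum(n) - k
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    df_w
  qcrit <- stats::qtukey(1 - alpha, nmeans = k, df = df_w)
  pairs <- utils::combn(k, 2)
  out <- data.frame(i = pairs[1, ], j = pairs[2, ])
  out$mean_diff <- means[out$i] - means[out$j]
  out$se <- sqrt(msw / 2 * (1 / n[out$i] + 1 / n[out$j]))
  out$critical <- qcrit * out$se
  out$p_adj <- stats::ptukey(abs(out$mean_diff) / out$se, nmeans = k,
                             df = df_w, lower.tail = FALSE)
  out$significant <- abs(out$mean_diff) > out$critical
  out
}

#' Nonparametric ROC analysis with Youden cutoff
#'
#' AUROC by the rank (Mann--Whitney) estimator with half credit for ties;
#' the operating cutoff maximizes the Youden index
#' (sensitivity + specificity - 1), ties resolved toward the lower cutoff;
#' the 95% CI uses the Hanley--McNeil standard error with a normal
#' approximation, clipped to `[0, 1]`. Higher scores are assumed to indicate
#' the positive class.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1 or logical), 1 = positive.
#' @return A `roc_result` list: `auroc`, `ci95`, `cutoff`, `sensitivity`,
#'   `specificity`, `youden`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  n_pos <- length(pos)
  n_neg <- length(neg)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  # rank estimator == Mann-Whitney U / (n_pos * n_neg)
  r <- rank(c(pos, neg), ties.method = "average")
  auroc <- (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  # Youden-optimal cutoff over observed scores (classify positive if >= c)
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(cc) mean(pos >= cc), numeric(1))
  spec <- vapply(cand, function(cc) mean(neg < cc), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]   # ties -> lower cutoff
  # Hanley-McNeil SE
  a <- auroc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
                (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
  ci <- pmin(pmax(a + c(-1, 1) * 1.96 * se, 0), 1)
  structure(list(auroc = auroc, ci95 = ci, cutoff = cand[best],
                 sensitivity = sens[best], specificity = spec[best],
                 youden = j[best], n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUROC %.3f (95%% CI %.4f-%.4f), cutoff %.3g, sens %.2f, spec %.2f (n+ %d, n- %d)\n",
    x$auroc, x$ci95[1], x$ci95[2], x$cutoff, x$sensitivity, x$specificity,
    x$n_pos, x$n_neg))
  invisible(x)
}

#' Welch two-sample t test between methods
#'
#' Convenience wrapper used for the per-stage SWE vs DMA comparisons
#' (two-tailed, unequal variances).
#'
#' @param x,y Numeric vectors.
#' @return A list with `t`, `p`, `df`.
#' @export
method_t_test <- function(x, y) {
  tt <- stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}
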
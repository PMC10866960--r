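# Statistical analyses over the experiment outputs: normality-routed
# omnibus and pairwise comparisons of per-iteration AUC distributions,
# biserial correlations of features (and size measures) with outcomes,
# bootstrap importance aggregation, and single-feature ROC reports.
# alpha = 0.05 throughout; all multiple-testing correction is Bonferroni.

#' Normality check by Lilliefors-corrected Kolmogorov-Smirnov test
#'
#' A one-sample KS test against a normal with moments estimated from the
#' sample; the Lilliefors correction accounts for the estimation (a
#' plain KS test with plugged-in moments would be anticonservative).
#' Constant samples are reported as not normal.
#'
#' @param values numeric sample, n >= 5.
#' @param alpha significance level (default 0.05).
#' @return `TRUE` iff the normality hypothesis is *not* rejected
#'   (p >= `alpha`).
#' @export
is_normal <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) stopf("normality test needs at least 5 values")
  if (stats::sd(values) == 0) return(FALSE)
  nortest::lillie.test(values)$p.value >= alpha
}

#' Omnibus + post-hoc comparison of several AUC distributions
#'
#' One-way ANOVA when every group passes [is_normal()], Kruskal-Wallis
#' otherwise; post-hoc pairwise comparisons (t-tests or rank-sum tests
#' respectively) are Bonferroni-multiplied by the number of pairs.
#'
#' @param groups named list of numeric vectors (e.g. one 500-AUC vector
#'   per ROI), each of length >= 2.
#' @param alpha significance level (default 0.05).
#' @return list of class `comparison_report`: `test`, `statistic`, `p`,
#'   `posthoc` (symmetric matrix of adjusted p), `normal` flags.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stopf("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stopf("every group needs at least 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  if (length(groups) == 2L) {
    two <- compare_two(groups[[1]], groups[[2]])
    ph <- matrix(two$p, 2, 2, dimnames = list(names(groups), names(groups)))
    diag(ph) <- NA_real_
    return(structure(
      list(test = two$test, statistic = two$statistic, p = two$p,
           posthoc = ph, normal = vapply(groups, is_normal, logical(1), alpha = alpha)),
      class = "comparison_report"
    ))
  }
  normal <- vapply(groups, is_normal, logical(1), alpha = alpha)
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (all(normal)) {
    fit <- stats::oneway.test(vals ~ g, var.equal = TRUE)
    test <- "anova"
    statistic <- unname(fit$statistic)
    p <- fit$p.value
    pair_p <- function(a, b) stats::t.test(a, b)$p.value
  } else {
    fit <- stats::kruskal.test(vals, g)
    test <- "kruskal-wallis"
    statistic <- unname(fit$statistic)
    p <- fit$p.value
    pair_p <- function(a, b) stats::wilcox.test(a, b, exact = FALSE)$p.value
  }
  k <- length(groups)
  m <- k * (k - 1) / 2
  ph <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    adj <- min(1, m * pair_p(groups[[i]], groups[[j]]))
    ph[i, j] <- adj
    ph[j, i] <- adj
  }
  structure(
    list(test = test, statistic = statistic, p = p, posthoc = ph, normal = normal),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s: statistic %.3g, p = %.3g\n", x$test, x$statistic, x$p))
  invisible(x)
}

#' Two-sample comparison routed by normality
#'
#' A t-test when both samples pass [is_normal()], a Wilcoxon test
#' otherwise; `paired = TRUE` uses the paired t / signed-rank variants
#' (for shared-seed experiment designs).
#'
#' @param a,b numeric samples.
#' @param paired logical.
#' @param alpha normality significance level.
#' @return list with `test`, `statistic`, `p`, `normal`.
#' @export
compare_two <- function(a, b, paired = FALSE, alpha = 0.05) {
  if (paired && length(a) != length(b)) stopf("paired samples must have equal length")
  normal <- c(is_normal(a, alpha), is_normal(b, alpha))
  if (all(normal)) {
    fit <- stats::t.test(a, b, paired = paired)
    test <- if (paired) "paired t-test" else "t-test"
  } else {
    fit <- stats::wilcox.test(a, b, paired = paired, exact = FALSE)
    test <- if (paired) "wilcoxon signed-rank" else "wilcoxon rank-sum"
  }
  list(test = test, statistic = unname(fit$statistic), p = fit$p.value, normal = normal)
}

#' Biserial correlation between a continuous variable and a binary outcome
#'
#' Point-biserial (Pearson r against 0/1 labels, with its t-test p) when
#' the values pass [is_normal()], rank-biserial otherwise. The
#' rank-biserial coefficient is `2 U / (n1 n0) - 1` from the
#' Mann-Whitney U of the positive class (equivalently Cliff's delta),
#' with the rank-sum p-value.
#'
#' @param values numeric vector.
#' @param labels binary labels (factor, positive = second level, or 0/1).
#' @param alpha normality significance level.
#' @return list with `r`, `p`, `type`.
#' @export
biserial <- function(values, labels, alpha = 0.05) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stopf("both outcome classes must be present")
  if (is_normal(values, alpha)) {
    ct <- stats::cor.test(values, y)
    list(r = unname(ct$estimate), p = ct$p.value, type = "point-biserial")
  } else {
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    U <- auc_stat(values, y) * n1 * n0
    wt <- stats::wilcox.test(values[y == 1L], values[y == 0L], exact = FALSE)
    list(r = 2 * U / (n1 * n0) - 1, p = wt$p.value, type = "rank-biserial")
  }
}

#' Aggregate per-iteration forest importances into a ranked signature
#'
#' Per iteration the raw importance scores are min-max normalized to
#' `[0, 1]` and features removed by a correlation filter in that
#' iteration are set to 0; the per-feature scores are then averaged
#' across iterations and the averages min-max normalized to `[0, 1]`
#' again, so the top feature always scores exactly 1. The reported top
#' set is every feature with a final score strictly above `threshold`.
#'
#' @param importance iterations x features matrix of raw (or already
#'   normalized) importances.
#' @param kept optional logical iterations x features matrix of
#'   filter-survival masks (`FALSE` zeroes that iteration's score).
#' @param threshold top-set cutoff (default 0.80).
#' @return list with `scores` (named, in `[0, 1]`), `ranked` (names in
#'   decreasing score order), `top` (names with score > threshold).
#' @export
aggregate_importance <- function(importance, kept = NULL, threshold = 0.80) {
  if (is.null(dim(importance))) importance <- matrix(importance, nrow = 1)
  if (nrow(importance) < 1L) stopf("need at least 1 iteration")
  norm01 <- function(v) {
    r <- range(v)
    if (diff(r) > 0) (v - r[1]) / diff(r) else rep(0, length(v))
  }
  normed <- t(apply(importance, 1, norm01))
  if (nrow(importance) == 1L) normed <- matrix(normed, nrow = 1)
  if (!is.null(kept)) normed[!kept] <- 0
  avg <- colMeans(normed)
  final <- norm01(avg)
  names(final) <- colnames(importance)
  if (all(avg == 0)) stopf("all importances are zero")
  list(
    scores = final,
    ranked = names(sort(final, decreasing = TRUE)),
    top = names(final)[final > threshold]
  )
}

#' Single-feature ROC report row
#'
#' Min-max normalizes the feature values and uses them as classifier
#' confidences; if the feature is anti-correlated with the outcome
#' (biserial r < 0) the labels are flipped (and flagged), so the
#' reported AUC is always >= 0.5 on the data at hand. Sensitivity and
#' specificity are taken at the upper-left-corner operating point.
#'
#' @param values feature values (non-constant).
#' @param labels binary outcome labels.
#' @param name feature name carried into the report.
#' @param alpha normality significance level for the correlation type.
#' @return one-row `data.frame`: `feature`, `type`, `r`, `p`, `auc`,
#'   `sensitivity`, `specificity`, `flipped`.
#' @export
single_feature_roc <- function(values, labels, name = "feature", alpha = 0.05) {
  if (stats::sd(values) == 0) stopf("feature is constant")
  y <- as_binary(labels)
  bs <- biserial(values, labels, alpha)
  flipped <- bs$r < 0
  if (flipped) y <- 1L - y
  conf <- (values - min(values)) / diff(range(values))
  thr <- upper_left_threshold(conf, y)
  ss <- sens_spec_at(conf, y, thr)
  data.frame(
    feature = name, type = bs$type, r = bs$r, p = bs$p,
    auc = auc_stat(conf, y),
    sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
    flipped = flipped, stringsAsFactors = FALSE
  )
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s).
#' @param m number of tests.
#' @return `min(1, m * p)`, vectorized.
#' @export
bonferroni <- function(p, m) pmin(1, m * p)
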
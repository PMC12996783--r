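#' Binomial margin of error for a phenotype frequency
#'
#' Half-width of the confidence interval around an observed phenotype
#' frequency k/n. The default is the Wald margin
#' `z * sqrt(p_hat (1 - p_hat) / n)`; note it degenerates to 0 at
#' `p_hat` of 0 or 1, so a Wilson margin is available via
#' `method = "wilson"`.
#'
#' @param k Affected count(s).
#' @param n Group size(s), >= 1.
#' @param confidence Confidence level (default 0.95).
#' @param method `"wald"` or `"wilson"`.
#' @return Tibble `k, n, p_hat, moe, method, confidence` with `p_hat` and
#'   `moe` as proportions.
#' @export
binomial_moe <- function(k, n, confidence = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (any(n < 1)) abort("`n` must be >= 1.")
  if (any(k < 0) || any(k > n)) abort("`k` must lie in [0, n].")
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  moe <- switch(method,
                wald = z * sqrt(p * (1 - p) / n),
                wilson = z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) /
                  (1 + z^2 / n))
  tibble(k = k, n = n, p_hat = p, moe = moe, method = method,
         confidence = confidence)
}

# significance stars at the conventional 0.05/0.01/0.001/0.0001 levels
p_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "n.s."))))
}

#' Two-group and multi-group comparisons with SEM reporting
#'
#' With two groups a two-tailed Welch (unequal-variance) t test is used;
#' with more than two a one-way ANOVA. Per-group summaries report mean
#' and SEM (`sd / sqrt(n)`). Stars follow the conventional levels
#' 0.05 / 0.01 / 0.001 / 0.0001. No multiple-testing correction is
#' applied by default; pass `bonferroni_m` to scale the p value by the
#' number of comparisons in a family.
#'
#' @param data Data frame with a grouping column and a value column.
#' @param value,group Column names (strings).
#' @param bonferroni_m Optional family size for a Bonferroni-adjusted p.
#' @return List:
#'   * `test`: one-row tibble `method, statistic, df, df2, p_value,
#'     stars` (`df2` is NA for the t test);
#'   * `groups`: tibble `group, n, mean, sem`.
#' @export
group_tests <- function(data, value = "value", group = "group",
                        bonferroni_m = NULL) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (is.null(v) || is.null(g)) abort("value/group columns not found.")
  counts <- table(g)
  if (length(counts) < 2) abort("need at least two groups.")
  if (any(counts < 2)) {
    abort(sprintf("group '%s' has fewer than 2 samples.",
                  names(counts)[which(counts < 2)[1]]))
  }
  groups <- dplyr::summarise(
    dplyr::group_by(tibble(g = g, v = v), .data$g),
    n = dplyr::n(), mean = mean(.data$v),
    sem = stats::sd(.data$v) / sqrt(dplyr::n()), .groups = "drop")
  names(groups)[1] <- "group"
  if (length(counts) == 2) {
    tt <- stats::t.test(v ~ g, var.equal = FALSE, alternative = "two.sided")
    test <- tibble(method = "Welch two-sample t test",
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), df2 = NA_real_,
                   p_value = tt$p.value)
  } else {
    fit <- stats::aov(v ~ g)
    an <- summary(fit)[[1]]
    test <- tibble(method = "one-way ANOVA",
                   statistic = an[["F value"]][1],
                   df = an[["Df"]][1], df2 = an[["Df"]][2],
                   p_value = an[["Pr(>F)"]][1])
  }
  if (!is.null(bonferroni_m)) {
    test$p_value <- pmin(1, test$p_value * bonferroni_m)
  }
  test$stars <- p_stars(test$p_value)
  list(test = test, groups = groups)
}
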
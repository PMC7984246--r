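#' F test between nested group-means models (one-way ANOVA)
#'
#' Compares the Gaussian linear model with a single categorical predictor
#' against the intercept-only model. For one categorical predictor the
#' likelihood-ratio ordering is identical to the classical one-way ANOVA F
#' test, which is what is computed: `df1 = a - 1`, `df2 = n - a`, p from the
#' F distribution. Two-sided by construction.
#'
#' @param values Numeric response vector.
#' @param groups Group label per value (>= 2 groups; `n > a`).
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p_value`.
#' @examples
#' lm_f_test(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
#' @export
lm_f_test <- function(values, groups) {
  groups <- factor(groups)
  a <- nlevels(groups)
  n <- length(values)
  if (a < 2) abort("need at least 2 groups", class = "gxediv_input_error")
  if (n <= a) abort("need more observations than groups",
                    class = "gxediv_input_error")
  ft <- tryCatch(
    oneway.test(values ~ groups, var.equal = TRUE),
    error = function(e) abort(
      "F statistic undefined: zero residual and between-group variance",
      class = "gxediv_stats_error"))
  if (!is.finite(ft$statistic) && var(values) == 0) {
    abort("F statistic undefined: zero residual and between-group variance",
          class = "gxediv_stats_error")
  }
  tibble(statistic = unname(ft$statistic),
         df1 = unname(ft$parameter[1]),
         df2 = unname(ft$parameter[2]),
         p_value = ft$p.value)
}

#' Two-sample rank-sum test (Wilcoxon / Mann-Whitney W)
#'
#' `W` is the rank sum of `x` (midranks under ties) minus
#' `n_x (n_x + 1) / 2`. The p value is exact for small untied samples and
#' uses the tie-corrected normal approximation otherwise; always two-sided.
#' For two groups this coincides with the two-sample Kruskal-Wallis test.
#'
#' @param x,y Numeric samples (non-empty).
#' @return A one-row tibble: `W`, `p_value`.
#' @examples
#' ranksum_w(c(1, 2), c(3, 4))  # W = 0
#' @export
ranksum_w <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be non-empty", class = "gxediv_input_error")
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  tibble(W = unname(wt$statistic), p_value = wt$p.value)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down Holm adjustment: order the p values increasingly, multiply the
#' i-th by `m - i + 1`, enforce monotonicity by cumulative maxima, cap at 1
#' and restore the original order. Controls the family-wise error rate
#' without the full Bonferroni penalty; adjusted values are never below the
#' raw ones.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values in the original order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p values must lie in [0, 1]", class = "gxediv_input_error")
  }
  p.adjust(p, method = "holm")
}
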
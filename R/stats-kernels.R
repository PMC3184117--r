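# Statistical primitives shared by all pipeline stages. These are thin,
# convention-fixing wrappers around the base stats routines; each result
# carries its method label into the report so the convention used is
# always traceable.

test_result <- function(statistic, p_value, method, sidedness) {
  structure(list(statistic = unname(statistic),
                 p_value = min(max(unname(p_value), 0), 1),
                 method = method, sidedness = sidedness),
            class = "test_result")
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) sv_stop("x and y must have equal length")
  if (length(x) < 3L) sv_stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    sv_stop("non-finite values in correlation input")
  }
  if (var(x) == 0 || var(y) == 0) {
    sv_stop("correlation undefined: zero variance",
            class = "spikeval_zero_variance")
  }
  cor(x, y)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value using the standard "sum of tables as or less
#' probable than the observed one" convention over the hypergeometric
#' distribution with fixed margins.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (`[[a, b], [c, d]]`).
#' @return a `test_result` (statistic is the sample odds ratio).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    sv_stop("cell counts must be non-negative integers")
  }
  if (sum(counts) == 0) {
    return(test_result(NA_real_, 1, "fisher_exact", "two"))
  }
  ft <- fisher.test(matrix(counts, nrow = 2, byrow = TRUE))
  or <- (a * d) / (b * c)
  test_result(or, ft$p.value, "fisher_exact", "two")
}

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' Two-sided. Uses the exact null distribution when the smaller sample
#' has at most `exact_max` observations and there are no ties; falls
#' back to the normal approximation with tie and continuity correction
#' otherwise.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_max switchover size for the exact distribution
#'   (default 8).
#' @return a `test_result` (statistic is the U statistic for `x`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y)) sv_stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE,
                alternative = "two.sided"))
  test_result(wt$statistic,
              wt$p.value,
              if (exact) "mann_whitney_exact" else "mann_whitney_normal",
              "two")
}

#' Variance-ratio (F) test
#'
#' Realizes the "variance comparison test": `F = s2_x / s2_y` with a
#' two-sided p-value from the F distribution.
#'
#' @param x,y numeric vectors with at least 2 observations each.
#' @return a `test_result` (statistic is the F ratio).
#' @export
variance_ratio_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    sv_stop("need at least 2 observations per sample")
  }
  if (var(y) == 0) {
    sv_stop("variance-ratio test undefined: zero variance in denominator",
            class = "spikeval_zero_variance")
  }
  vt <- var.test(x, y, alternative = "two.sided")
  test_result(vt$statistic, vt$p.value, "variance_ratio_F", "two")
}

#' Upper-tail count probability (Poisson or binomial)
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)` or `X ~ Binomial(n, p)`; the
#' one-sided tail used by the homology enrichment test.
#'
#' @param k observed count (>= 0).
#' @param lambda Poisson mean (mode `"poisson"`).
#' @param n,p binomial size and probability (mode `"binomial"`).
#' @param mode `"poisson"` or `"binomial"`.
#' @return the tail probability.
#' @export
count_tail <- function(k, lambda = NULL, n = NULL, p = NULL,
                       mode = c("poisson", "binomial")) {
  mode <- match.arg(mode)
  if (k < 0 || k != round(k)) sv_stop("k must be a non-negative integer")
  if (k == 0) return(1)
  if (mode == "poisson") {
    if (is.null(lambda) || lambda < 0) sv_stop("invalid lambda")
    ppois(k - 1, lambda, lower.tail = FALSE)
  } else {
    if (is.null(n) || is.null(p) || p < 0 || p > 1 || k > n) {
      sv_stop("invalid binomial parameters")
    }
    pbinom(k - 1, n, p, lower.tail = FALSE)
  }
}
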
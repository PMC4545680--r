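#' Bootstrap two-sample test on the t statistic
#'
#' Builds the null distribution of the two-sample t statistic by resampling
#' surrogate groups of the original sizes from the pooled sample, with
#' 10,000 iterations by default. `mode = "permutation"` (default) draws the
#' surrogate groups without replacement — a label permutation with exact
#' null guarantees; `mode = "independent"` draws both surrogate groups with
#' replacement from the pool, so a subject may enter both. The p value is
#' `(b + 1) / (B + 1)` where `b` counts surrogate statistics at least as
#' extreme as the observed one.
#'
#' @param x1,x2 Numeric vectors (each n >= 2, finite).
#' @param iterations Number of surrogate draws (default 10000).
#' @param mode `"permutation"` or `"independent"`.
#' @param alternative `"two.sided"` (default; compares `|t|`), `"greater"`
#'   or `"less"`.
#' @param seed Integer seed.
#' @return Object of class `bootstrap_result`: `observed_t`, `p_value`,
#'   `null_t`, `iterations`, `mode`, `alternative`, `seed`.
#' @export
bootstrap_two_sample <- function(x1, x2, iterations = 10000,
                                 mode = c("permutation", "independent"),
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 seed = 1) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  stopifnot(length(x1) >= 2, length(x2) >= 2,
            all(is.finite(x1)), all(is.finite(x2)))
  pooled <- c(x1, x2)
  if (stats::var(pooled) == 0) stop("zero pooled variance")
  obs <- two_sample_t(x1, x2)
  set.seed(seed)
  null_t <- cpp_resample_t(pooled, length(x1), as.integer(iterations),
                           if (mode == "permutation") 0L else 1L)
  b <- switch(alternative,
              two.sided = sum(abs(null_t) >= abs(obs)),
              greater = sum(null_t >= obs),
              less = sum(null_t <= obs))
  structure(list(observed_t = obs, p_value = (b + 1) / (iterations + 1),
                 null_t = null_t, iterations = iterations, mode = mode,
                 alternative = alternative, seed = seed),
            class = "bootstrap_result")
}

# Pooled-variance two-sample t statistic.
two_sample_t <- function(x1, x2) {
  n1 <- length(x1)
  n2 <- length(x2)
  sp <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  se <- sqrt(sp * (1 / n1 + 1 / n2))
  if (se == 0) return(0)
  (mean(x1) - mean(x2)) / se
}

#' One-sample t test
#'
#' Classical statistic with `df = n - 1` and a two-sided p value.
#'
#' @param x Numeric vector, n >= 2 with nonzero variance.
#' @param mu0 Null mean (default 0).
#' @return List with `t`, `df`, `p_value`, `mean`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  stopifnot(length(x) >= 2)
  if (stats::var(x) == 0) stop("zero variance")
  ht <- stats::t.test(x, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean = mean(x))
}

#' Pearson correlation with two-tailed p value
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Difference between two independent correlations (Fisher z test)
#'
#' Fisher-transforms both coefficients and compares them with a normal
#' statistic; `z > 0` when `r1 > r2`.
#'
#' @param r1,r2 Correlation coefficients (|r| < 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @return List with `z`, `p_value` (two-sided).
#' @export
corr_diff_z <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 >= 4, n2 >= 4)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni adjustment
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @param m Number of comparisons (default `length(p_values)`).
#' @param alpha Decision level (default 0.05).
#' @return List with `adjusted` (`min(1, m * p)`, order preserved) and
#'   `significant` (logical at `alpha`).
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values),
                              alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1), m >= length(p_values))
  adj <- stats::p.adjust(p_values, method = "bonferroni", n = m)
  list(adjusted = adj, significant = adj < alpha)
}
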
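# Scalar statistical procedures used by the cohort analysis: Spearman
# correlation with a Fisher-z CI, the Welch unequal-variance t test, the
# Fisher exact test for 2x2 tables, the two-way random-effects
# absolute-agreement ICC, and the exact Clopper-Pearson binomial interval.
# Written as self-contained implementations; base R equivalents serve as
# independent cross-checks in the test suite.

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' Pearson correlation of the (mid-)ranks; the 95% CI uses the Fisher z
#' transform with standard error `1/sqrt(n - 3)`.
#'
#' @param x,y Paired numeric vectors, `n >= 4`.
#' @return List with `r`, `ci_low`, `ci_high`, `n`.
#' @export
#' @examples
#' spearman_ci(1:10, (1:10)^2)
spearman_ci <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4 || length(y) != n) {
    abort("need >= 4 complete pairs", class = "hepafunc_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant vector",
          class = "hepafunc_input_error")
  }
  rx <- rank(x)
  ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  zr <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  half <- qnorm(0.975) / sqrt(n - 3)
  list(r = r, ci_low = tanh(zr - half), ci_high = tanh(zr + half), n = n)
}

#' Welch unequal-variance t test
#'
#' Two-sided t test with the Welch--Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric samples, each with `n >= 2`.
#' @return List with `t`, `df`, `p`, group means.
#' @export
#' @examples
#' welch_test(rnorm(10), rnorm(10, 1))
welch_test <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs n >= 2", class = "hepafunc_input_error")
  }
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  if (va + vb == 0) {
    t_stat <- 0
    df <- length(a) + length(b) - 2
  } else {
    t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  }
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df),
       mean_a = mean(a), mean_b = mean(b))
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass method: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2))
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    abort("`table` must be a 2x2 matrix of non-negative integer counts",
          class = "hepafunc_input_error")
  }
  m <- sum(table[1, ])        # row 1 margin
  n <- sum(table[2, ])        # row 2 margin
  k <- sum(table[, 1])        # column 1 margin
  if (m + n == 0) return(1)
  x <- table[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `k = 2` raters.
#' Absolute agreement penalizes systematic between-reader bias, so adding a
#' constant to one reader lowers the ICC below the Pearson correlation.
#'
#' @param reader1,reader2 Paired measurements of the same subjects, `n >= 3`.
#' @return ICC estimate.
#' @export
#' @examples
#' icc_agreement(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.2))
icc_agreement <- function(reader1, reader2) {
  ok <- is.finite(reader1) & is.finite(reader2)
  reader1 <- reader1[ok]
  reader2 <- reader2[ok]
  n <- length(reader1)
  if (n < 3 || length(reader2) != n) {
    abort("need >= 3 complete pairs", class = "hepafunc_input_error")
  }
  k <- 2
  Y <- cbind(reader1, reader2)
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  rater_means <- colMeans(Y)
  msr <- k * sum((subj_means - grand)^2) / (n - 1)
  msc <- n * sum((rater_means - grand)^2) / (k - 1)
  sse <- sum((Y - outer(subj_means, rep(1, k)) -
                outer(rep(1, n), rater_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Exact Clopper--Pearson binomial confidence interval
#'
#' 95% interval from beta quantiles: lower `qbeta(.025, x, n - x + 1)`,
#' upper `qbeta(.975, x + 1, n - x)`, with the conventional endpoints 0 and 1
#' at `x = 0` and `x = n`.
#'
#' @param successes Number of successes, `0 <= successes <= trials`.
#' @param trials Number of trials, `> 0`.
#' @param conf Confidence level.
#' @return Numeric vector `c(low, high)` of proportions.
#' @export
#' @examples
#' clopper_pearson(18, 22)
clopper_pearson <- function(successes, trials, conf = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials)) {
    abort("need integer 0 <= successes <= trials, trials >= 1",
          class = "hepafunc_input_error")
  }
  alpha <- 1 - conf
  low <- if (successes == 0) 0 else qbeta(alpha / 2, successes,
                                          trials - successes + 1)
  high <- if (successes == trials) 1 else qbeta(1 - alpha / 2, successes + 1,
                                                trials - successes)
  c(low = low, high = high)
}
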
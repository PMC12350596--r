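# ROC machinery: Mann-Whitney AUC, Youden cutoffs vs brute force, DeLong
# variance and paired comparison, binormal closed form, pROC cross-checks.

brute_force_auc <- function(neg, pos) {
  s <- 0
  for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

test_that("empirical AUC equals the pairwise count on small fixtures", {
  expect_equal(empirical_auc(c(1, 2), c(3, 4)), 1)
  expect_equal(empirical_auc(c(1, 3), c(2, 4)), 0.75)
  expect_equal(empirical_auc(1, 1), 0.5)
  expect_equal(empirical_auc(c(3, 4), c(1, 2), direction = "lower"), 1)
  expect_error(empirical_auc(numeric(0), 1), class = "hepafunc_input_error")
  set.seed(21)
  for (i in 1:25) {
    neg <- round(rnorm(sample(3:12, 1)), 1)
    pos <- round(rnorm(sample(3:12, 1), 0.5), 1)
    expect_equal(empirical_auc(neg, pos), brute_force_auc(neg, pos))
  }
})

test_that("AUC complement identity holds under group exchange", {
  set.seed(31)
  for (i in 1:50) {
    neg <- rnorm(sample(4:20, 1))
    pos <- rnorm(sample(4:20, 1), 0.8)
    expect_equal(empirical_auc(neg, pos) + empirical_auc(pos, neg), 1)
  }
})

test_that("Youden threshold separates separable groups and breaks ties as documented", {
  yt <- youden_threshold(c(1, 2), c(3, 4))
  expect_gt(yt$threshold, 2)
  expect_lt(yt$threshold, 3)
  expect_equal(yt$sens, 1)
  expect_equal(yt$spec, 1)
  # two cutpoints attain J = 0.5; tie-break prefers higher sensitivity
  yt2 <- youden_threshold(c(1, 3), c(2, 4))
  expect_equal(yt2$j, 0.5)
  expect_gt(yt2$threshold, 1)
  expect_lt(yt2$threshold, 2)
  expect_equal(yt2$sens, 1)
})

test_that("Youden result equals an exhaustive cutpoint scan", {
  set.seed(41)
  for (i in 1:200) {
    neg <- round(rnorm(sample(5:25, 1)), 1)
    pos <- round(rnorm(sample(5:25, 1), 0.7), 1)
    dir <- sample(c("higher", "lower"), 1)
    yt <- youden_threshold(neg, pos, dir)
    grid <- sort(unique(c(neg, pos)))
    cuts <- c(min(grid) - 1, grid, grid + c(diff(grid) / 2, 1))
    j_all <- vapply(cuts, function(ct) {
      if (dir == "higher") mean(pos > ct) + mean(neg <= ct) - 1
      else mean(pos <= ct) + mean(neg > ct) - 1
    }, numeric(1))
    expect_equal(yt$j, max(j_all), tolerance = 1e-12)
  }
})

test_that("DeLong self-comparison is null and AUCs agree with the empirical estimator", {
  set.seed(51)
  lab <- rep(c(FALSE, TRUE), c(30, 12))
  x <- rnorm(42, lab)
  dl <- delong_compare(x, x, lab)
  expect_equal(dl$z, 0)
  expect_equal(dl$p, 1)
  expect_equal(dl$auc_a, empirical_auc(x[!lab], x[lab]))
  y <- rnorm(42, 0.4 * lab)
  dl2 <- delong_compare(x, y, lab)
  expect_equal(dl2$auc_b, empirical_auc(y[!lab], y[lab]))
  expect_error(delong_compare(x, y[-1], lab), class = "hepafunc_input_error")
  expect_error(delong_compare(x, y, rep(TRUE, 42)),
               class = "hepafunc_input_error")
})

test_that("DeLong matches pROC on AUC, variance and paired comparison", {
  skip_if_not_installed("pROC")
  set.seed(61)
  lab <- rep(c(0, 1), c(40, 18))
  a <- rnorm(58, 1.1 * lab)
  b <- rnorm(58, 0.6 * lab)
  dl <- delong_compare(a, b, lab)
  ra <- pROC::roc(lab, a, direction = "<", quiet = TRUE)
  rb <- pROC::roc(lab, b, direction = "<", quiet = TRUE)
  expect_equal(dl$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  expect_equal(dl$var_a, pROC::var(ra, method = "delong"), tolerance = 1e-10)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(dl$p, ref$p.value, tolerance = 1e-10)
})

test_that("DeLong variance tracks a bootstrap oracle on a fixed small fixture", {
  set.seed(71)
  neg <- rnorm(30, 0, 1)
  pos <- rnorm(15, 1, 1.2)
  dl <- delong_variance(neg, pos)
  boot <- replicate(4000, {
    empirical_auc(sample(neg, replace = TRUE), sample(pos, replace = TRUE))
  })
  ratio <- dl$var / var(boot)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("binormal AUC closed form: null case, complement symmetry, known separations", {
  expect_equal(binormal_auc(5, 2, 5, 3), 0.5)
  expect_equal(binormal_auc(43.0, 12.4, 18.8, 20.2),
               pnorm(24.2 / sqrt(12.4^2 + 20.2^2)))
  expect_equal(binormal_auc(0, 1, 2, 1, signed = TRUE) +
                 binormal_auc(2, 1, 0, 1, signed = TRUE), 1)
  expect_error(binormal_auc(1, 0, 1, 0), class = "hepafunc_input_error")
})

test_that("roc_analysis assembles a coherent result object", {
  set.seed(81)
  lab <- rep(c(FALSE, TRUE), c(60, 25))
  x <- rnorm(85, 1.2 * lab)
  r <- roc_analysis(x, lab)
  expect_s3_class(r, "roc_result")
  expect_equal(r$auc, empirical_auc(x[!lab], x[lab]))
  expect_true(r$auc_ci[1] <= r$auc && r$auc <= r$auc_ci[2])
  yt <- youden_threshold(x[!lab], x[lab])
  expect_equal(r$threshold, yt$threshold)
  # curve is monotone: sensitivity falls as specificity rises
  cv <- dplyr::arrange(r$curve, threshold)
  expect_true(all(diff(cv$sens) <= 1e-12))
  expect_true(all(diff(cv$spec) >= -1e-12))
  td <- tidy(r)
  expect_equal(td$auc, r$auc)
  p <- ggplot2::autoplot(r)
  expect_s3_class(p, "ggplot")
})
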
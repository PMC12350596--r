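# ROC machinery: Mann-Whitney empirical AUC, Youden-optimal thresholds with
# midpoint candidate cutoffs, the DeLong structural-component variance
# estimator for single AUCs and paired comparisons, and the binormal
# closed-form AUC.
#
# Direction convention: `direction = "higher"` means higher scores indicate
# disease (positives); `direction = "lower"` flips the ordering, for markers
# (IWR, LV/BSA, LHL15) that fall with dysfunction.

check_groups <- function(neg_scores, pos_scores) {
  if (length(neg_scores) == 0 || length(pos_scores) == 0) {
    abort("both score groups must be non-empty", class = "hepafunc_input_error")
  }
  if (any(!is.finite(neg_scores)) || any(!is.finite(pos_scores))) {
    abort("scores must be finite", class = "hepafunc_input_error")
  }
}

#' Empirical (Mann--Whitney) AUC
#'
#' Fraction of (negative, positive) pairs ordered correctly, ties counted
#' one half: the probability that a random diseased subject scores above
#' (below, for `direction = "lower"`) a random non-diseased subject.
#'
#' @param neg_scores Scores of the non-diseased group.
#' @param pos_scores Scores of the diseased group.
#' @param direction `"higher"` if higher scores indicate disease, `"lower"`
#'   otherwise.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' empirical_auc(c(1, 3), c(2, 4))
empirical_auc <- function(neg_scores, pos_scores,
                          direction = c("higher", "lower")) {
  direction <- arg_match(direction)
  check_groups(neg_scores, pos_scores)
  if (direction == "lower") {
    neg_scores <- -neg_scores
    pos_scores <- -pos_scores
  }
  # rank-based Mann-Whitney statistic (ties -> midranks)
  m <- length(pos_scores)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(neg_scores))
}

# sensitivity/specificity at each candidate cutoff, for a given direction;
# positives are called when score > cutoff ("higher") or score <= cutoff
# ("lower"), matching the printed threshold notations "> x" and "<= x".
sens_spec_at <- function(neg, pos, cutoff, direction) {
  if (direction == "higher") {
    sens <- mean(pos > cutoff)
    spec <- mean(neg <= cutoff)
  } else {
    sens <- mean(pos <= cutoff)
    spec <- mean(neg > cutoff)
  }
  c(sens = sens, spec = spec)
}

#' Youden-optimal threshold
#'
#' Scans candidate cutoffs (midpoints between adjacent distinct pooled
#' scores, plus sentinels outside the data range) and returns the one
#' maximizing `J = sensitivity + specificity - 1`. Ties on J are broken
#' toward higher sensitivity, then toward the cutoff closest to the midpoint
#' between the two group medians (the group-overlap center), so the result
#' is deterministic.
#'
#' @inheritParams empirical_auc
#' @return List with `threshold`, `direction` (`">"` or `"<="`), `sens`,
#'   `spec`, `j`.
#' @export
#' @examples
#' youden_threshold(c(1, 2), c(3, 4))
youden_threshold <- function(neg_scores, pos_scores,
                             direction = c("higher", "lower")) {
  direction <- arg_match(direction)
  check_groups(neg_scores, pos_scores)
  pooled <- sort(unique(c(neg_scores, pos_scores)))
  eps <- max(1, max(abs(pooled))) * 1e-6
  cand <- c(pooled[1] - eps,
            if (length(pooled) > 1) (head(pooled, -1) + tail(pooled, -1)) / 2,
            pooled[length(pooled)] + eps)
  ss <- vapply(cand, function(ct) sens_spec_at(neg_scores, pos_scores, ct,
                                               direction), numeric(2))
  j <- ss["sens", ] + ss["spec", ] - 1
  best <- which(j > max(j) - 1e-12)
  if (length(best) > 1) {
    best <- best[ss["sens", best] > max(ss["sens", best]) - 1e-12]
  }
  if (length(best) > 1) {
    center <- (median(neg_scores) + median(pos_scores)) / 2
    best <- best[which.min(abs(cand[best] - center))]
  } else {
    best <- best[1]
  }
  list(threshold = cand[best],
       direction = if (direction == "higher") ">" else "<=",
       sens = unname(ss["sens", best]), spec = unname(ss["spec", best]),
       j = unname(j[best]))
}

# DeLong structural components: V10 (per positive) and V01 (per negative)
delong_components <- function(neg, pos, direction) {
  if (direction == "lower") {
    neg <- -neg
    pos <- -pos
  }
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance of a single empirical AUC
#'
#' @inheritParams empirical_auc
#' @return List with `auc` and `var`.
#' @export
delong_variance <- function(neg_scores, pos_scores,
                            direction = c("higher", "lower")) {
  direction <- arg_match(direction)
  check_groups(neg_scores, pos_scores)
  cmp <- delong_components(neg_scores, pos_scores, direction)
  m <- length(pos_scores)
  n <- length(neg_scores)
  v <- var(cmp$v10) / m + var(cmp$v01) / n
  list(auc = cmp$auc, var = v)
}

#' Compare two correlated AUCs with the DeLong method
#'
#' Both markers are measured on the same subjects (paired design). Estimates
#' each AUC, the DeLong variance--covariance of the pair from the structural
#' components, and a two-sided normal p-value for the AUC difference.
#'
#' @param scores_a,scores_b Paired score vectors (same subjects, same order).
#' @param labels Logical (or 0/1) disease indicator per subject.
#' @param direction_a,direction_b Direction flags for each marker.
#' @return List with `auc_a`, `auc_b`, `var_a`, `var_b`, `cov`, `z`, `p`.
#' @export
#' @examples
#' set.seed(1)
#' lab <- rep(c(FALSE, TRUE), each = 20)
#' a <- rnorm(40, lab); b <- rnorm(40, 0.5 * lab)
#' delong_compare(a, b, lab)$p
delong_compare <- function(scores_a, scores_b, labels,
                           direction_a = c("higher", "lower"),
                           direction_b = c("higher", "lower")) {
  direction_a <- arg_match(direction_a)
  direction_b <- arg_match(direction_b)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    abort("scores_a, scores_b and labels must have equal length (paired)",
          class = "hepafunc_input_error")
  }
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    abort("both classes must be present", class = "hepafunc_input_error")
  }
  ca <- delong_components(scores_a[!labels], scores_a[labels], direction_a)
  cb <- delong_components(scores_b[!labels], scores_b[labels], direction_b)
  m <- sum(labels)
  n <- sum(!labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  d <- ca$auc - cb$auc
  vd <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  z <- if (vd <= 0) 0 else d / sqrt(vd)
  list(auc_a = ca$auc, auc_b = cb$auc,
       var_a = S[1, 1], var_b = S[2, 2], cov = S[1, 2],
       z = z, p = 2 * pnorm(-abs(z)))
}

#' Closed-form binormal AUC
#'
#' AUC of a marker normally distributed within each class:
#' `Phi(|mu1 - mu0| / sqrt(sd0^2 + sd1^2))`, or the signed version when
#' `signed = TRUE` (then swapping the groups gives the complement).
#'
#' @param mu0,sd0 Mean and SD in the non-diseased class.
#' @param mu1,sd1 Mean and SD in the diseased class.
#' @param signed Use the signed separation `(mu1 - mu0)` instead of its
#'   absolute value.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' binormal_auc(43.0, 12.4, 18.8, 20.2)
binormal_auc <- function(mu0, sd0, mu1, sd1, signed = FALSE) {
  if (sd0 < 0 || sd1 < 0) abort_field("sd", "SDs must be >= 0")
  if (sd0 == 0 && sd1 == 0 && mu0 == mu1) {
    abort("binormal AUC undefined for identical degenerate groups",
          class = "hepafunc_input_error")
  }
  sep <- if (signed) (mu1 - mu0) else abs(mu1 - mu0)
  pnorm(sep / sqrt(sd0^2 + sd1^2))
}

#' Full ROC analysis of one marker
#'
#' Empirical ROC curve, Mann--Whitney AUC with a DeLong 95% CI (plain scale,
#' clipped to `[0, 1]`), the Youden-optimal threshold, and sensitivity and
#' specificity at that threshold with exact Clopper--Pearson 95% CIs.
#'
#' @param scores Numeric marker values, one per subject.
#' @param labels Logical (or 0/1) disease indicator.
#' @param direction `"higher"` if higher scores indicate disease.
#' @return An object of class `roc_result`.
#' @export
#' @examples
#' set.seed(1)
#' r <- roc_analysis(c(rnorm(50), rnorm(20, 1.5)),
#'                   rep(c(FALSE, TRUE), c(50, 20)))
#' r$auc
roc_analysis <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- arg_match(direction)
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length",
          class = "hepafunc_input_error")
  }
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    abort("both classes must be present", class = "hepafunc_input_error")
  }
  neg <- scores[!labels]
  pos <- scores[labels]
  check_groups(neg, pos)

  pooled <- sort(unique(scores))
  eps <- max(1, max(abs(pooled))) * 1e-6
  cand <- c(pooled[1] - eps,
            if (length(pooled) > 1) (head(pooled, -1) + tail(pooled, -1)) / 2,
            pooled[length(pooled)] + eps)
  ss <- vapply(cand, function(ct) sens_spec_at(neg, pos, ct, direction),
               numeric(2))
  curve <- tibble(threshold = cand, sens = ss["sens", ], spec = ss["spec", ]) |>
    arrange(dplyr::desc(.data$sens + .data$spec))

  dl <- delong_variance(neg, pos, direction)
  z <- qnorm(0.975)
  ci <- pmin(pmax(dl$auc + c(-1, 1) * z * sqrt(dl$var), 0), 1)
  yt <- youden_threshold(neg, pos, direction)
  m <- length(pos)
  n <- length(neg)
  sens_ci <- clopper_pearson(round(yt$sens * m), m)
  spec_ci <- clopper_pearson(round(yt$spec * n), n)
  structure(
    list(curve = curve, auc = dl$auc, auc_var = dl$var, auc_ci = ci,
         threshold = yt$threshold, threshold_direction = yt$direction,
         sens = yt$sens, sens_ci = sens_ci,
         spec = yt$spec, spec_ci = spec_ci,
         direction = direction, n_pos = m, n_neg = n),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f [%.3f, %.3f]; Youden cutoff %s %.4g (sens %.1f%%, spec %.1f%%)\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$threshold_direction, x$threshold,
    100 * x$sens, 100 * x$spec))
  invisible(x)
}

#' Tidy an ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return One-row tibble with the AUC, its CI, the Youden threshold, and
#'   sensitivity/specificity with CIs.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  tibble(
    auc = x$auc, auc_low = x$auc_ci[1], auc_high = x$auc_ci[2],
    threshold = x$threshold, threshold_direction = x$threshold_direction,
    sens = x$sens, sens_low = x$sens_ci[1], sens_high = x$sens_ci[2],
    spec = x$spec, spec_low = x$spec_ci[1], spec_high = x$spec_ci[2],
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Plot an ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- object$curve |> arrange(1 - .data$spec, .data$sens)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$spec, y = .data$sens)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::annotate("point", x = 1 - object$spec, y = object$sens,
                      shape = 4, size = 3) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.3f [%.3f, %.3f]", object$auc,
                      object$auc_ci[1], object$auc_ci[2])) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
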
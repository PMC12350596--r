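# The combined CT diagnostic model for severe liver dysfunction
# (ICG-R15 >= 20%), and a from-scratch multivariable logistic fitter (IRLS)
# for refitting on new cohorts. The published coefficients are stored to
# their printed precision as frozen constants; refitting never overwrites
# them.

#' Frozen coefficients of the combined CT diagnostic model
#'
#' Intercept and coefficients (logit scale) of the published model
#' `P = 1 / (1 + exp(-(11.869 - 0.1119*IWR + 0.0118*SpV/BSA - 0.0139*LV/BSA)))`.
#'
#' @return Named numeric vector `(intercept, iwr, spv_bsa, lv_bsa)`.
#' @export
combined_model_coefficients <- function() {
  c(intercept = 11.869, iwr = -0.1119, spv_bsa = 0.0118, lv_bsa = -0.0139)
}

#' Probability of severe liver dysfunction from the combined CT model
#'
#' Evaluates the frozen published model at the given biomarker values.
#' Strictly decreasing in IWR and LV/BSA, strictly increasing in SpV/BSA.
#'
#' @param iwr Iodine washout rate (%).
#' @param spv_bsa Spleen volume index (mL/m^2).
#' @param lv_bsa Liver volume index (mL/m^2).
#' @return Probability in (0, 1); vectorized.
#' @export
#' @examples
#' combined_model_probability(43.0, 117.3, 823.4)
combined_model_probability <- function(iwr, spv_bsa, lv_bsa) {
  if (any(!is.finite(iwr)) || any(!is.finite(spv_bsa)) ||
      any(!is.finite(lv_bsa))) {
    abort("combined model inputs must be finite",
          class = "hepafunc_input_error")
  }
  b <- combined_model_coefficients()
  stats::plogis(b[["intercept"]] + b[["iwr"]] * iwr +
                  b[["spv_bsa"]] * spv_bsa + b[["lv_bsa"]] * lv_bsa)
}

#' Classify severe liver dysfunction at the published threshold
#'
#' Positive iff the model probability strictly exceeds the threshold
#' (default 0.472, the published Youden-optimal cutoff).
#'
#' @param p Model probability in `[0, 1]`.
#' @param threshold Decision threshold.
#' @return Logical; vectorized.
#' @export
#' @examples
#' classify_severe_dysfunction(c(0.0473, 0.8565))
classify_severe_dysfunction <- function(p, threshold = 0.472) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort_field("p", "probabilities must lie in [0, 1]")
  }
  p > threshold
}

#' Fit a multivariable logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares, written as a self-contained fitter. Convergence requires the
#' maximum absolute score (gradient) below `1e-8` or a relative
#' log-likelihood change below `1e-10`. Odds ratios are `exp(coefficient)`
#' with Wald 95% confidence intervals from the observed information.
#' Complete or quasi-complete separation is detected (diverging coefficients
#' with vanishing residual deviance contribution) and reported as an error
#' naming the offending covariate.
#'
#' @param data Data frame with the covariates and outcome.
#' @param covariates Character vector of covariate column names.
#' @param outcome Name of the outcome column (logical or 0/1); both classes
#'   must be present.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `logistic_fit` with elements `coefficients`,
#'   `se`, `vcov`, `odds_ratios` (tibble with Wald CIs), `log_lik`,
#'   `iterations`, `converged`, `n`.
#' @export
#' @examples
#' coh <- add_biomarkers(sample_cohort(cohort_spec(), seed = 1))
#' coh$severe <- coh$icg_r15 >= 20
#' fit <- fit_logistic(coh, c("iwr", "lv_bsa", "spv_bsa"), "severe")
#' tidy(fit)
fit_logistic <- function(data, covariates, outcome, max_iter = 100L) {
  if (length(covariates) < 1) {
    abort_field("covariates", "need at least one covariate")
  }
  missing <- setdiff(c(covariates, outcome), names(data))
  if (length(missing)) {
    abort(paste("data is missing columns:", paste(missing, collapse = ", ")),
          class = "hepafunc_input_error")
  }
  y <- as.numeric(data[[outcome]])
  if (!all(y %in% c(0, 1))) {
    abort_field("outcome", "must be logical or 0/1")
  }
  if (length(unique(y)) < 2) {
    abort_field("outcome", "both outcome classes must be present")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(data)[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    abort("singular design matrix: covariates are collinear",
          class = "hepafunc_fit_error")
  }

  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    ll <- sum(y * eta - log1p(exp(eta)))
    if (max(abs(score)) < 1e-8 ||
        (is.finite(ll_old) && abs(ll - ll_old) < 1e-10 * (abs(ll_old) + 1e-10))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w_safe <- pmax(w, .Machine$double.eps)
    XtWX <- crossprod(X * sqrt(w_safe))
    step <- tryCatch(solve(XtWX, score),
                     error = function(e) {
                       abort("information matrix is singular during IRLS",
                             class = "hepafunc_fit_error")
                     })
    beta <- beta + step
    if (max(abs(beta)) > 1e3) break
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  # separation diagnostic: the likelihood has no finite maximum, the fitted
  # probabilities collapse onto the outcome and coefficients diverge (the
  # score can still vanish, so this must precede the convergence check)
  if (all(abs(y - mu) < 1e-4) && max(abs(beta)) > 10) {
    std_beta <- abs(beta[-1]) * apply(X[, -1, drop = FALSE], 2, sd)
    worst <- covariates[which.max(std_beta)]
    abort(sprintf(
      "complete or quasi-complete separation detected (covariate `%s`)",
      worst), class = "hepafunc_separation_error")
  }
  if (!converged) {
    abort("IRLS failed to converge", class = "hepafunc_fit_error")
  }
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  info <- crossprod(X * sqrt(w))
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  names(beta) <- colnames(X)
  z <- qnorm(0.975)
  or_tbl <- tibble(
    term = colnames(X),
    estimate = unname(beta),
    std_error = unname(se),
    odds_ratio = unname(exp(beta)),
    or_low = unname(exp(beta - z * se)),
    or_high = unname(exp(beta + z * se))
  )
  structure(
    list(coefficients = beta, se = se, vcov = vcov, odds_ratios = or_tbl,
         log_lik = sum(y * eta - log1p(exp(eta))),
         iterations = iter, converged = converged, n = n,
         covariates = covariates, outcome = outcome),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, logLik = %.3f, %d IRLS iterations%s\n",
              x$n, x$log_lik, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  print(x$odds_ratios)
  invisible(x)
}

#' Tidy a logistic fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `odds.ratio`, `conf.low`, `conf.high` (CI on the odds-ratio
#'   scale).
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  z <- x$coefficients / x$se
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z))),
    odds.ratio = unname(exp(x$coefficients)),
    conf.low = x$odds_ratios$or_low,
    conf.high = x$odds_ratios$or_high
  )
}

#' Glance at a logistic fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return One-row tibble with `logLik`, `AIC`, `nobs`, `iterations`,
#'   `converged`.
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  k <- length(x$coefficients)
  tibble(logLik = x$log_lik, AIC = 2 * k - 2 * x$log_lik, nobs = x$n,
         iterations = x$iterations, converged = x$converged)
}
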
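new_msm_estimate <- function(coef, vcov, method, variance, n_eff, weights,
                             extra = list()) {
  se <- sqrt(diag(vcov))
  ci <- cbind(lower = coef - stats::qnorm(0.975) * se,
              upper = coef + stats::qnorm(0.975) * se)
  rownames(ci) <- names(coef)
  structure(c(list(coef = coef, vcov = vcov, se = se, ci = ci,
                   method = method, variance = variance, n_eff = n_eff,
                   weight_summary = weights), extra),
            class = "msm_estimate")
}

#' @export
print.msm_estimate <- function(x, ...) {
  cat(sprintf("<msm_estimate> method = %s, variance = %s, n = %d\n",
              x$method, x$variance, x$n_eff))
  tab <- cbind(estimate = x$coef, se = x$se, x$ci)
  print(round(tab, 4))
  if (!is.null(x$weight_summary))
    cat(sprintf("  weights: mean %.3f, p99 %.3f, max %.3f\n",
                x$weight_summary[["mean"]], x$weight_summary[["p99"]],
                x$weight_summary[["max"]]))
  invisible(x)
}

#' @export
coef.msm_estimate <- function(object, ...) object$coef

#' @export
vcov.msm_estimate <- function(object, ...) object$vcov

summarize_weights <- function(w) {
  c(mean = mean(w), p99 = unname(stats::quantile(w, 0.99)), max = max(w))
}

#' Fit the weighted marginal structural model
#'
#' Weighted least squares of the end-of-study outcome on the treatment
#' history, `Y ~ A_0 + ... + A_{K-1}`, with the final stabilized weights.
#' The default variance is the heteroskedasticity-robust sandwich treating
#' the weights as known (the classic conservative choice); use
#' [bootstrap_ci()] to propagate weight-estimation uncertainty.
#'
#' @param panel a `panel_data` or wide data frame with one outcome row per
#'   subject.
#' @param weights a `weight_set` aligned by `id`, or `NULL` for unweighted
#'   OLS.
#' @param method label recorded on the estimate (e.g. `"full"`, `"cc"`).
#' @return An `msm_estimate` with coefficients `beta_int, beta_0, ...`,
#'   sandwich variance, 95\% CIs and a weight-distribution summary.
#' @export
fit_msm <- function(panel, weights = NULL, method = "full") {
  d <- if (inherits(panel, "panel_data")) panel$data else panel
  if (anyDuplicated(d$id))
    msmiss_abort("msmiss_config_error", "duplicate subject ids in outcome data")
  K <- sum(grepl("^A_", names(d)))
  w <- if (is.null(weights)) rep(1, nrow(d)) else {
    fw <- final_weights(weights)
    fw$weight[match(d$id, fw$id)]
  }
  if (anyNA(w))
    msmiss_abort("msmiss_config_error", "weights not aligned with panel ids")
  acols <- a_col(seq_len(K) - 1L)
  fml <- stats::reformulate(acols, response = "Y")
  fit <- stats::lm(fml, data = d, weights = w)
  if (fit$rank < K + 1L)
    msmiss_abort("msmiss_estimation_error",
                 "rank-deficient MSM design (collinear or degenerate treatment columns)")
  beta <- stats::coef(fit)
  names(beta) <- c("beta_int", paste0("beta_", seq_len(K) - 1L))
  V <- sandwich::vcovHC(fit, type = "HC0")
  dimnames(V) <- list(names(beta), names(beta))
  new_msm_estimate(beta, V, method, "sandwich", nrow(d), summarize_weights(w))
}

#' Contrast between two static treatment regimes
#'
#' Effect of following `regime_a` rather than `regime_b`:
#' `sum_k beta_k (a_k - b_k)`, with the standard error from the delta method
#' (linear combination of the coefficient covariance).
#'
#' @param est an `msm_estimate`.
#' @param regime_a,regime_b 0/1 vectors of length `K`.
#' @return List with `estimate`, `se` and `ci`.
#' @export
regime_contrast <- function(est, regime_a, regime_b) {
  K <- length(est$coef) - 1L
  if (length(regime_a) != K || length(regime_b) != K)
    msmiss_abort("msmiss_config_error",
                 sprintf("regimes must have length K = %d", K))
  cvec <- c(0, regime_a - regime_b)
  eff <- sum(cvec * est$coef)
  se <- sqrt(drop(t(cvec) %*% est$vcov %*% cvec))
  list(estimate = eff, se = se,
       ci = c(lower = eff - stats::qnorm(0.975) * se,
              upper = eff + stats::qnorm(0.975) * se))
}

## Subset a panel to a vector of (possibly repeated) subject ids, reassigning
## fresh ids so the uniqueness invariant holds inside resamples.
resample_panel <- function(panel, idx) {
  d <- panel$data[idx, , drop = FALSE]
  m <- panel$mask[idx, , drop = FALSE]
  d$id <- seq_len(nrow(d))
  m$id <- seq_len(nrow(m))
  rownames(d) <- rownames(m) <- NULL
  new_panel_data(d, m, panel$config, panel$mechanism)
}

#' Nonparametric bootstrap confidence intervals for an analysis pipeline
#'
#' Resamples subjects with replacement and reruns the full pipeline (weight
#' estimation, missing-data handling, MSM fit) inside each replicate, so the
#' intervals reflect weight-estimation uncertainty.  Percentile 95\%
#' intervals are returned.
#'
#' @param panel a `panel_data`.
#' @param pipeline function `panel -> named numeric vector` of coefficients.
#' @param B number of replicates (`>= 2`).
#' @param seed integer seed; the same seed reproduces the intervals exactly.
#' @return List with `ci` (matrix coefficient x (lower, upper)), `estimates`
#'   (B x p matrix of successful replicates) and `failures`.
#' @export
bootstrap_ci <- function(panel, pipeline, B = 200L, seed = 1L) {
  if (B < 2) msmiss_abort("msmiss_config_error", "'B' must be >= 2")
  n <- n_subjects(panel)
  res <- vector("list", B)
  failures <- 0L
  for (b in seq_len(B)) {
    set.seed(substream_seed(seed, 500L, b))
    idx <- sample.int(n, n, replace = TRUE)
    rp <- resample_panel(panel, idx)
    est <- tryCatch(pipeline(rp), error = function(e) NULL)
    if (is.null(est)) failures <- failures + 1L else res[[b]] <- est
  }
  if (failures > 0.05 * B)
    msmiss_abort("msmiss_bootstrap_error",
                 sprintf("pipeline failed in %d of %d bootstrap replicates",
                         failures, B))
  est <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  ci <- t(apply(est, 2L, stats::quantile, probs = c(0.025, 0.975)))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, estimates = est, failures = failures)
}
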
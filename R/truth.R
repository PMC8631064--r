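#' All static treatment regimes for K time points
#' @param n_times number of time points.
#' @return A `2^K x K` 0/1 matrix, one row per static regime.
#' @export
static_regimes <- function(n_times) {
  g <- expand.grid(rep(list(0:1), n_times))
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, paste0("a_", seq_len(n_times) - 1L))
  m
}

## Project 2^K counterfactual regime means onto the additive marginal model
## Y = beta_int + sum_k beta_k a_k with equal regime weights.
project_regime_means <- function(regimes, ybar, se = NULL) {
  X <- cbind(1, regimes)
  XtXi <- solve(crossprod(X))
  P <- XtXi %*% t(X)
  beta <- drop(P %*% ybar)
  names(beta) <- c("beta_int", paste0("beta_", seq_len(ncol(regimes)) - 1L))
  resid <- ybar - drop(X %*% beta)
  out <- list(beta = beta, residuals = resid)
  if (!is.null(se)) {
    V <- P %*% diag(se^2, length(se)) %*% t(P)
    out$mc_se <- sqrt(diag(V))
    names(out$mc_se) <- names(beta)
  }
  out
}

#' True marginal structural coefficients of a data-generating mechanism
#'
#' Computes the causal estimand targeted by the weighted MSM: the projection
#' of the `2^K` counterfactual regime means `E[Y | do(a)]` (static regimes,
#' equal weights) onto the additive model
#' `Y = beta_int + beta_0 a_0 + ... + beta_{K-1} a_{K-1}`.
#'
#' Two oracles are available.  The Monte-Carlo g-formula simulates `n_mc`
#' counterfactual trajectories per regime with treatment hard-set (confounder
#' dynamics still respond to the set treatments) and averages the outcome.
#' The closed form propagates means through the structural equations, which
#' is exact only when every equation is linear, i.e. for configurations built
#' with [dgm_config_linear()].
#'
#' @param config a [dgm_config()].
#' @param oracle `"gformula_mc"` or `"closed_form"`.
#' @param n_mc counterfactual trajectories per regime (Monte-Carlo oracle).
#' @param seed integer seed for the Monte-Carlo oracle.
#' @return An object of class `true_estimand` with elements `beta` (named
#'   vector `beta_int, beta_0, ...`), `mc_se` (zero for the closed form),
#'   `regime_means`, `regimes`, `additivity_gap` (max absolute deviation of
#'   the regime means from the fitted additive surface) and `oracle`.
#' @export
true_msm_coefficients <- function(config,
                                  oracle = c("gformula_mc", "closed_form"),
                                  n_mc = 200000L, seed = 1L) {
  oracle <- match.arg(oracle)
  K <- config$n_times
  regimes <- static_regimes(K)
  if (oracle == "closed_form") {
    if (config$l1_type != "gaussian")
      msmiss_abort("msmiss_oracle_error",
                   "closed-form oracle requires the all-linear-Gaussian variant (binary confounder dynamics are nonlinear)")
    ybar <- apply(regimes, 1L, function(a) closed_form_mean(config, a))
    proj <- project_regime_means(regimes, ybar)
    mc_se <- rep(0, K + 1L)
    names(mc_se) <- names(proj$beta)
  } else {
    n_mc <- as.integer(n_mc)
    ybar <- numeric(nrow(regimes)); se <- numeric(nrow(regimes))
    for (r in seq_len(nrow(regimes))) {
      set.seed(substream_seed(seed, 900L, r))
      A <- matrix(regimes[r, ], n_mc, K, byrow = TRUE)
      d <- simulate_core(config, n_mc, forced_A = A)
      ybar[r] <- mean(d$Y)
      se[r] <- stats::sd(d$Y) / sqrt(n_mc)
    }
    proj <- project_regime_means(regimes, ybar, se)
    mc_se <- proj$mc_se
  }
  structure(list(beta = proj$beta, mc_se = mc_se,
                 regime_means = ybar, regimes = regimes,
                 additivity_gap = max(abs(proj$residuals)),
                 oracle = oracle, n_mc = if (oracle == "gformula_mc") n_mc else NA_integer_),
            class = "true_estimand")
}

## Exact E[Y | do(a)] for the linear-Gaussian system: means propagate through
## the linear dynamics; the sticky carry-over multiplies innovation terms by
## (1 - sticky).
closed_form_mean <- function(config, a) {
  K <- config$n_times
  s <- config$sticky
  eL1 <- if (config$l1_type == "gaussian") 0 else config$p_L1
  eL2 <- config$L2_mean
  om <- config$out_model
  y <- om$intercept
  for (k in seq_len(K) - 1L) {
    if (k > 0L) {
      eL1 <- s * eL1 + (1 - s) * (config$L1_dyn[["intercept"]] +
                                    config$L1_dyn[["lag"]] * eL1 +
                                    config$L1_dyn[["trt"]] * a[k])
      eL2 <- s * eL2 + (1 - s) * (config$L2_dyn[["intercept"]] +
                                    config$L2_dyn[["lag"]] * eL2 +
                                    config$L2_dyn[["trt"]] * a[k])
    }
    y <- y + om$trt[k + 1L] * a[k + 1L] + om$L1[k + 1L] * eL1 +
      om$L2[k + 1L] * eL2
  }
  y
}

#' @export
print.true_estimand <- function(x, ...) {
  cat(sprintf("<true_estimand> oracle = %s\n", x$oracle))
  tab <- rbind(beta = x$beta, mc_se = x$mc_se)
  print(round(tab, 5))
  cat(sprintf("  additivity gap (max |regime mean - additive fit|): %.2g\n",
              x$additivity_gap))
  invisible(x)
}
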
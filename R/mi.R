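## Chained-equations imputation engine.
##
## Each partially observed confounder column is imputed from V, every
## treatment, the outcome and all other confounder columns: binary columns
## by logistic draws, continuous columns by predictive mean matching (type-1
## matching, 5 donors), both with approximate-Bayesian parameter draws so
## that between-imputation variability is properly generated.

ridge_solve <- function(A, b = NULL, eps = 1e-8) {
  A <- A + diag(eps * mean(diag(A)), nrow(A))
  if (is.null(b)) chol2inv(chol(A)) else solve(A, b)
}

## Linear model fit with posterior draws of (sigma, beta); returns predicted
## values for donors (beta_hat) and recipients (beta_star).
draw_lm_predictions <- function(X_obs, y_obs, X_mis) {
  p <- ncol(X_obs)
  n <- nrow(X_obs)
  XtX <- crossprod(X_obs)
  XtXi <- ridge_solve(XtX)
  beta_hat <- drop(XtXi %*% crossprod(X_obs, y_obs))
  resid <- y_obs - drop(X_obs %*% beta_hat)
  df <- max(n - p, 1L)
  sigma2_star <- sum(resid^2) / stats::rchisq(1L, df)
  cov_chol <- chol(sigma2_star * XtXi)
  beta_star <- beta_hat + drop(t(cov_chol) %*% stats::rnorm(p))
  list(yhat_obs = drop(X_obs %*% beta_hat),
       yhat_mis = drop(X_mis %*% beta_star))
}

## Predictive mean matching: for each recipient, sample one of the `donors`
## observed values whose donor prediction is closest to the recipient
## prediction.  Nearest donors are located through the sorted donor
## predictions, which is exact for the window size used.
pmm_match <- function(yhat_obs, y_obs, yhat_mis, donors = 5L) {
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  yv <- y_obs[ord]
  n <- length(ys)
  donors <- min(donors, n)
  m <- length(yhat_mis)
  pos <- findInterval(yhat_mis, ys)
  offs <- seq(-donors, donors + 1L)
  idx <- pmin(pmax(outer(pos, offs, `+`), 1L), n)
  dist <- abs(matrix(ys[idx], nrow = m) - yhat_mis)
  ## rows of idx are nondecreasing, so clamping duplicates are adjacent;
  ## a duplicated position must not be selectable twice
  dup <- cbind(FALSE, idx[, -1L, drop = FALSE] == idx[, -ncol(idx), drop = FALSE])
  dist[dup] <- Inf
  chosen <- matrix(0L, m, donors)
  for (s in seq_len(donors)) {
    jm <- max.col(-dist, ties.method = "first")
    chosen[, s] <- idx[cbind(seq_len(m), jm)]
    dist[cbind(seq_len(m), jm)] <- Inf
  }
  pick <- chosen[cbind(seq_len(m), sample.int(donors, m, replace = TRUE))]
  yv[pick]
}

## Lean Newton-Raphson logistic fit (fixed iteration budget) used inside the
## imputation sampler, where thousands of refits make glm()'s bookkeeping
## overhead material.
irls_logit <- function(X, y, maxit = 12L, tol = 1e-7) {
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XtWX <- crossprod(X * w, X)
    step <- ridge_solve(XtWX, crossprod(X, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, XtWX = XtWX)
}

## Logistic fit with an approximate-Bayesian coefficient draw; returns
## imputed 0/1 values.
draw_logit_imputes <- function(X_obs, y_obs, X_mis) {
  fit <- irls_logit(X_obs, y_obs)
  V <- ridge_solve(fit$XtWX)
  beta_star <- fit$beta + drop(t(chol(V)) %*% stats::rnorm(length(fit$beta)))
  p <- stats::plogis(drop(X_mis %*% beta_star))
  stats::rbinom(nrow(X_mis), 1L, p)
}

is_binary_col <- function(x) all(x[!is.na(x)] %in% c(0, 1))

## One completed data set from the chained-equations sampler.
impute_once <- function(obs, targets, predictors, cycles) {
  cur <- obs
  na_idx <- lapply(targets, function(col) which(is.na(obs[[col]])))
  names(na_idx) <- targets
  ## initialize by sampling from the observed margin
  for (col in targets) {
    mis <- na_idx[[col]]
    pool <- obs[[col]][!is.na(obs[[col]])]
    cur[[col]][mis] <- sample(pool, length(mis), replace = TRUE)
  }
  for (cycle in seq_len(cycles)) {
    for (col in targets) {
      mis <- na_idx[[col]]
      if (!length(mis)) next
      preds <- setdiff(predictors, col)
      X <- cbind(1, as.matrix(cur[preds]))
      X_obs <- X[-mis, , drop = FALSE]
      X_mis <- X[mis, , drop = FALSE]
      y_obs <- obs[[col]][-mis]
      if (is_binary_col(obs[[col]])) {
        cur[[col]][mis] <- draw_logit_imputes(X_obs, y_obs, X_mis)
      } else {
        pr <- draw_lm_predictions(X_obs, y_obs, X_mis)
        cur[[col]][mis] <- pmm_match(pr$yhat_obs, y_obs, pr$yhat_mis)
      }
    }
  }
  cur
}

#' Multiple imputation of partially observed confounders
#'
#' Chained-equations imputation cycling over every partially observed
#' confounder column.  Each imputation model conditions on the baseline risk
#' factor, every treatment, every confounder at every visit and the outcome.
#' Binary confounders are imputed by logistic draws, continuous confounders
#' by predictive mean matching (5 donors); columns are visited in order of
#' increasing missingness.  Each completed panel is analyzed by the standard
#' weighting-plus-MSM pipeline and the `M` estimates are pooled by Rubin's
#' rules.
#'
#' @param panel a `panel_data`.
#' @param M number of imputations (default 10, `>= 2`).
#' @param cycles chained-equation cycles per imputation.
#' @param seed integer seed.
#' @return An object of class `imputation_result`: `estimate` (pooled
#'   `msm_estimate` with total-variance covariance and t-based CIs),
#'   `per_imputation` (M x p coefficient matrix), `W`, `B`, `T_var`, `df`,
#'   `M`.
#' @export
mi_estimate <- function(panel, M = 10L, cycles = 5L, seed = 1L) {
  if (M < 2) msmiss_abort("msmiss_config_error", "'M' must be >= 2")
  obs <- observed_data(panel)
  K <- panel$n_times
  cells <- confounder_cells(K)
  all_cols <- paste0(cells$var, "_", cells$k)
  n_na <- vapply(all_cols, function(c) sum(is.na(obs[[c]])), integer(1))
  for (col in all_cols)
    if (n_na[[col]] == nrow(obs))
      msmiss_abort("msmiss_estimation_error",
                   sprintf("column %s has zero observed values; imputation model inestimable", col))
  targets <- all_cols[n_na > 0L]
  targets <- targets[order(n_na[targets])]
  predictors <- c("V", a_col(seq_len(K) - 1L), all_cols, "Y")
  coefs <- NULL; vcovs <- vector("list", M)
  for (m in seq_len(M)) {
    set.seed(substream_seed(seed, 300L, m))
    comp <- if (length(targets)) impute_once(obs, targets, predictors, cycles) else obs
    est <- msm_pipeline(comp, method = "mi")
    coefs <- rbind(coefs, est$coef)
    vcovs[[m]] <- est$vcov
  }
  Wbar <- Reduce(`+`, vcovs) / M
  pooled <- colMeans(coefs)
  Bmat <- if (M > 1) stats::cov(coefs) else 0 * Wbar
  Tmat <- Wbar + (1 + 1 / M) * Bmat
  W <- diag(Wbar); B <- diag(Bmat); Tv <- diag(Tmat)
  df <- ifelse(B > 0, (M - 1) * (1 + W / ((1 + 1 / M) * B))^2, Inf)
  se <- sqrt(Tv)
  tq <- stats::qt(0.975, df)
  ci <- cbind(lower = pooled - tq * se, upper = pooled + tq * se)
  est <- new_msm_estimate(pooled, Tmat, "mi", "rubin", nrow(obs), NULL)
  est$ci <- ci
  structure(list(estimate = est, per_imputation = coefs,
                 W = W, B = B, T_var = Tv, df = df, M = M),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> M = %d imputations\n", x$M))
  print(x$estimate)
  invisible(x)
}

#' Pool repeated-imputation estimates by Rubin's rules
#'
#' Pooled point estimate = mean of the per-imputation estimates; within
#' variance `W` = mean of the per-imputation variances; between variance `B`
#' = sample variance of the estimates; total variance `T = W + (1 + 1/M) B`.
#' The CI uses a t reference with the standard MI degrees of freedom
#' `(M - 1) (1 + W / ((1 + 1/M) B))^2`.
#'
#' @param point_estimates numeric vector of length `M >= 2`.
#' @param within_variances numeric vector of the same length.
#' @return List with `pooled`, `W`, `B`, `T`, `se`, `df`, `ci`.
#' @export
rubin_pool <- function(point_estimates, within_variances) {
  point_estimates <- as.numeric(point_estimates)
  within_variances <- as.numeric(within_variances)
  M <- length(point_estimates)
  if (M < 2 || length(within_variances) != M)
    msmiss_abort("msmiss_config_error",
                 "need M >= 2 estimates and as many within-imputation variances")
  pooled <- mean(point_estimates)
  W <- mean(within_variances)
  B <- stats::var(point_estimates)
  Tv <- W + (1 + 1 / M) * B
  df <- if (B > 0) (M - 1) * (1 + W / ((1 + 1 / M) * B))^2 else Inf
  se <- sqrt(Tv)
  tq <- stats::qt(0.975, df)
  list(pooled = pooled, W = W, B = B, T = Tv, se = se, df = df,
       ci = c(lower = pooled - tq * se, upper = pooled + tq * se))
}
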
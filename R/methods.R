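## The standard analysis pipeline every strategy funnels into: pooled
## logistic treatment models, stabilized weights, weighted MSM.
msm_pipeline <- function(data, method = "full", denominator_extra = character(0),
                         truncate = NULL) {
  models <- fit_treatment_models(data, denominator_extra)
  ws <- compute_stabilized_weights(data, models)
  if (!is.null(truncate)) ws <- truncate_weights(ws, truncate)
  fit_msm(data, ws, method = method)
}

#' Symmetric percentile truncation of stabilized weights
#'
#' Caps per-subject final weights at the given lower/upper percentiles of
#' their distribution.  Off by default throughout the package.
#'
#' @param ws a `weight_set`.
#' @param percentiles length-2 vector, e.g. `c(0.01, 0.99)`.
#' @return A `weight_set` with the last-visit cumulative weights truncated.
#' @export
truncate_weights <- function(ws, percentiles = c(0.01, 0.99)) {
  tab <- ws$table
  last <- tab$k == ws$n_times - 1L
  q <- stats::quantile(tab$cum[last], percentiles)
  tab$cum[last] <- pmin(pmax(tab$cum[last], q[1L]), q[2L])
  new_weight_set(tab, ws$n_times, ws$miss_table)
}

check_exposure_outcome <- function(obs, method) {
  acols <- grep("^A_", names(obs), value = TRUE)
  if (anyNA(obs[acols]) || anyNA(obs$Y))
    msmiss_abort("msmiss_unsupported_error",
                 sprintf("%s does not handle missing data on the exposure or outcome", method))
  invisible(obs)
}

subject_complete <- function(panel) {
  rowSums(as.matrix(panel$mask[-1L])) == 0L
}

#' Complete-case analysis
#'
#' Drops every subject with at least one missing confounder cell (at any
#' visit) and runs the standard weighting-plus-MSM pipeline on the rest.
#' Valid when missingness is completely at random.
#'
#' @param panel a `panel_data`.
#' @return List with `panel` (the retained subset), `estimate`
#'   (`msm_estimate`, method `"cc"`) and `n_dropped`.
#' @export
complete_case <- function(panel) {
  keep <- subject_complete(panel)
  obs <- observed_data(panel)
  keep <- keep & stats::complete.cases(obs)
  if (!any(keep))
    msmiss_abort("msmiss_empty_error", "no complete subjects for complete-case analysis")
  sub <- resample_panel(panel, which(keep))
  est <- msm_pipeline(sub$data, method = "cc")
  est$n_eff <- nrow(sub$data)
  list(panel = sub, estimate = est, n_dropped = sum(!keep))
}

#' Last observation carried forward
#'
#' Forward-fills each confounder from the most recent observed measurement;
#' subjects with a missing baseline value are dropped (nothing to carry).
#' The filled panel is analyzed as if complete, so the reported SE ignores
#' the single-imputation uncertainty.  Valid under the constant-value
#' mechanism, where a masked value always equals its previous measurement.
#'
#' @param panel a `panel_data`.
#' @return List with `panel` (the completed subset), `estimate` (method
#'   `"locf"`) and `n_dropped`.
#' @export
locf_impute <- function(panel) {
  filled <- locf_fill(panel)
  est <- msm_pipeline(filled$panel$data, method = "locf")
  list(panel = filled$panel, estimate = est, n_dropped = filled$n_dropped)
}

#' Forward-fill missing confounders without fitting anything
#'
#' The imputation step of [locf_impute()], exposed separately: each masked
#' confounder takes the most recent observed value; subjects with a missing
#' baseline are dropped.
#'
#' @param panel a `panel_data`.
#' @return List with `panel` (completed, re-indexed ids) and `n_dropped`.
#' @export
locf_fill <- function(panel) {
  obs <- observed_data(panel)
  check_exposure_outcome(obs, "LOCF")
  K <- panel$n_times
  drop <- is.na(obs$L1_0) | is.na(obs$L2_0)
  if (all(drop))
    msmiss_abort("msmiss_empty_error", "all subjects missing baseline confounders")
  obs <- obs[!drop, , drop = FALSE]
  for (k in seq_len(K - 1L))
    for (v in c("L1", "L2")) {
      col <- paste0(v, "_", k)
      prev <- paste0(v, "_", k - 1L)
      na <- is.na(obs[[col]])
      obs[[col]][na] <- obs[[prev]][na]
    }
  filled <- new_panel_data(transform(obs, id = seq_len(nrow(obs))),
                           empty_mask(nrow(obs), K), panel$config,
                           panel$mechanism)
  list(panel = filled, n_dropped = sum(drop))
}

## Missingness-pattern labels of person-time rows: which confounders are
## missing at the row's visit.
mpa_pattern_label <- function(pt) {
  m1 <- is.na(pt$L1); m2 <- is.na(pt$L2)
  ifelse(m1 & m2, "both", ifelse(m1, "L1", ifelse(m2, "L2", "none")))
}

mpa_covars <- function(label) {
  switch(label, none = c("L1", "L2"), L1 = "L2", L2 = "L1", both = character(0))
}

## Coarsening order used when a pattern is too sparse: drop one more
## covariate from the model (towards the intercept-only pattern).
mpa_coarser <- function(label) {
  switch(label, none = "L2", L1 = "both", L2 = "both", both = NA_character_)
}

#' Missingness pattern approach
#'
#' Person-time rows are partitioned, at each visit, by which confounders are
#' missing at that visit.  Within each pattern the denominator treatment
#' model is fitted (pooled over visits, with time-specific intercepts) using
#' only the covariates observed in that pattern; every subject is retained.
#' The numerator is a single pooled model in previous treatment only, shared
#' across patterns: a pattern-specific numerator would condition the
#' stabilized weights on pattern membership -- a descendant of earlier
#' confounders that is not part of the marginal model -- and leave treatment
#' associated with it in the pseudopopulation.  Patterns with fewer than
#' `min_pattern_size` person-time rows are merged into the nearest coarser
#' pattern (one more covariate dropped from the model).  Valid under
#' differential missingness, where a masked confounder no longer enters the
#' treatment decision.
#'
#' @param panel a `panel_data`; treatment and outcome must be fully observed.
#' @param min_pattern_size minimum person-time rows per pattern model.
#' @return List with `weights` (a `weight_set`), `estimate` (method
#'   `"mpa"`), `pattern_sizes` and `merges` (labels coarsened for sparsity).
#' @export
mpa_weights <- function(panel, min_pattern_size = 50L) {
  obs <- observed_data(panel)
  check_exposure_outcome(obs, "the missingness pattern approach")
  K <- panel$n_times
  pt <- person_time(obs, K)
  lab <- mpa_pattern_label(pt)
  sizes <- table(lab)
  ## coarsen sparse patterns until every fitted group is large enough
  group <- lab
  merges <- character(0)
  repeat {
    gs <- table(group)
    sparse <- names(gs)[gs < min_pattern_size]
    sparse <- sparse[!is.na(vapply(sparse, mpa_coarser, character(1)))]
    if (!length(sparse)) break
    g <- sparse[[1L]]
    coarser <- mpa_coarser(g)
    merges <- c(merges, sprintf("%s -> %s", g, coarser))
    group[group == g] <- coarser
  }
  num <- stats::glm(A ~ 0 + factor(k) + A_prev, family = stats::binomial(),
                    data = pt)
  num$data <- pt
  check_glm_fit(num, "numerator treatment")
  p_num <- received_prob(num$fitted.values, pt$A)
  p_den <- rep(NA_real_, nrow(pt))
  for (g in unique(group)) {
    rows <- group == g
    covars <- mpa_covars(g)
    sub <- pt[rows, , drop = FALSE]
    time_terms <- if (length(unique(sub$k)) > 1L) c("0", "factor(k)") else "1"
    den <- stats::glm(stats::reformulate(c(time_terms, covars, "A_prev"),
                                         response = "A"),
                      family = stats::binomial(), data = sub)
    den$data <- sub
    check_glm_fit(den, sprintf("pattern '%s' denominator", g))
    p_den[rows] <- received_prob(den$fitted.values, sub$A)
  }
  tab <- data.frame(id = pt$id, k = pt$k, p_num = p_num, p_den = p_den,
                    factor = p_num / p_den, pattern = lab)
  tab <- tab[order(tab$id, tab$k), ]
  tab$cum <- stats::ave(tab$factor, tab$id, FUN = cumprod)
  rownames(tab) <- NULL
  ws <- new_weight_set(tab, K)
  est <- fit_msm(obs, ws, method = "mpa")
  list(weights = ws, estimate = est, pattern_sizes = sizes, merges = merges)
}

#' Inverse-probability-of-missingness weighting
#'
#' Missingness is monotonized: each subject is censored at the first visit
#' with any missing confounder.  Pooled logistic models with time-specific
#' intercepts estimate the probability of remaining uncensored at each visit
#' given the previous treatment and confounders and the baseline risk factor
#' (denominator) or the previous treatment only (numerator).  The cumulative
#' missingness weight multiplies the treatment weight, and the MSM is fitted
#' on subjects uncensored through the last visit.
#'
#' @param panel a `panel_data`.
#' @return List with `estimate` (method `"ipmw"`), `weights` (a `weight_set`
#'   whose `miss_table` holds the censoring-weight factors) and
#'   `n_uncensored`.
#' @export
ipmw_estimate <- function(panel) {
  obs <- observed_data(panel)
  check_exposure_outcome(obs, "IPMW")
  K <- panel$n_times
  mm <- as.matrix(panel$mask[-1L])
  n <- nrow(obs)
  ## first visit with any missing confounder (K if fully observed)
  cens_time <- rep(K, n)
  for (k in rev(seq_len(K) - 1L)) {
    miss_k <- rowSums(mm[, mask_col(c("L1", "L2"), k), drop = FALSE]) > 0L
    cens_time[miss_k] <- k
  }
  ## censoring person-time: at risk at k when uncensored through k-1
  rows <- list()
  for (k in seq_len(K) - 1L) {
    at_risk <- cens_time >= k
    rows[[k + 1L]] <- data.frame(
      id = obs$id[at_risk], k = k,
      remain = as.integer(cens_time[at_risk] > k),
      A_prev = if (k == 0L) 0 else obs[[a_col(k - 1L)]][at_risk],
      L1_prev = if (k == 0L) 0 else obs[[l1_col(k - 1L)]][at_risk],
      L2_prev = if (k == 0L) 0 else obs[[l2_col(k - 1L)]][at_risk],
      V = obs$V[at_risk])
  }
  cpt <- do.call(rbind, rows)
  ks_with_cens <- sort(unique(cpt$k[cpt$remain == 0L]))
  cpt$p_den <- cpt$p_num <- 1
  if (length(ks_with_cens)) {
    fitrows <- cpt$k %in% ks_with_cens
    sub <- cpt[fitrows, , drop = FALSE]
    time_terms <- if (length(ks_with_cens) > 1L) c("0", "factor(k)") else "1"
    den <- stats::glm(stats::reformulate(c(time_terms, "A_prev", "L1_prev",
                                           "L2_prev", "V"),
                                         response = "remain"),
                      family = stats::binomial(), data = sub)
    num <- stats::glm(stats::reformulate(c(time_terms, "A_prev"),
                                         response = "remain"),
                      family = stats::binomial(), data = sub)
    if (any(den$fitted.values < 1e-12))
      msmiss_abort("msmiss_positivity_error",
                   "estimated remain-probability numerically zero")
    cpt$p_den[fitrows] <- den$fitted.values
    cpt$p_num[fitrows] <- num$fitted.values
  }
  cpt$factor <- cpt$p_num / cpt$p_den
  cpt <- cpt[order(cpt$id, cpt$k), ]
  cpt$cum <- stats::ave(cpt$factor, cpt$id, FUN = cumprod)
  uncens <- cens_time == K
  if (!any(uncens))
    msmiss_abort("msmiss_empty_error", "no subjects uncensored through all visits")
  ## treatment models on person-time of subjects still uncensored at k
  pt_full <- person_time(obs, K)
  pt_keep <- pt_full[cens_time[match(pt_full$id, obs$id)] > pt_full$k, ,
                     drop = FALSE]
  den_t <- stats::glm(A ~ 0 + factor(k) + L1 + L2 + A_prev,
                      family = stats::binomial(), data = pt_keep)
  num_t <- stats::glm(A ~ 0 + factor(k) + A_prev,
                      family = stats::binomial(), data = pt_keep)
  den_t$data <- pt_keep; num_t$data <- pt_keep
  check_glm_fit(den_t, "IPMW denominator treatment")
  sub_obs <- obs[uncens, , drop = FALSE]
  pt_sub <- person_time(sub_obs, K)
  p_den1 <- stats::predict(den_t, newdata = pt_sub, type = "response")
  p_num1 <- stats::predict(num_t, newdata = pt_sub, type = "response")
  tab <- data.frame(id = pt_sub$id, k = pt_sub$k,
                    p_num = received_prob(p_num1, pt_sub$A),
                    p_den = received_prob(p_den1, pt_sub$A))
  tab$factor <- tab$p_num / tab$p_den
  tab <- tab[order(tab$id, tab$k), ]
  tab$cum <- stats::ave(tab$factor, tab$id, FUN = cumprod)
  rownames(tab) <- NULL
  miss_tab <- cpt[cpt$id %in% sub_obs$id, c("id", "k", "p_num", "p_den",
                                            "factor", "cum")]
  rownames(miss_tab) <- NULL
  ws <- new_weight_set(tab, K, miss_tab)
  est <- fit_msm(sub_obs, ws, method = "ipmw")
  list(estimate = est, weights = ws, n_uncensored = sum(uncens),
       censor_person_time = cpt)
}

#' Analyze a panel with one of the missing-data strategies
#'
#' Dispatcher over the full-data analysis and the five missing-confounder
#' strategies; every route ends in the same stabilized-weight MSM fit.
#'
#' @param panel a `panel_data`.
#' @param method one of `"full"`, `"cc"`, `"locf"`, `"mpa"`, `"mi"`,
#'   `"ipmw"`.
#' @param M imputations for `"mi"`.
#' @param min_pattern_size pattern floor for `"mpa"`.
#' @param truncate optional weight-truncation percentiles, e.g.
#'   `c(0.01, 0.99)`.
#' @param seed seed for stochastic methods (`"mi"`).
#' @return An `msm_estimate` (for `"mi"`, the Rubin-pooled estimate; the
#'   full `imputation_result` is attached as attribute `"detail"`).
#' @export
analyze_panel <- function(panel,
                          method = c("full", "cc", "locf", "mpa", "mi", "ipmw"),
                          M = 10L, min_pattern_size = 50L, truncate = NULL,
                          seed = 1L) {
  method <- match.arg(method)
  res <- switch(method,
                full = {
                  obs <- observed_data(panel)
                  if (anyNA(obs))
                    msmiss_abort("msmiss_unsupported_error",
                                 "full-data analysis requires a fully observed panel")
                  list(estimate = msm_pipeline(obs, method = "full",
                                               truncate = truncate))
                },
                cc = complete_case(panel),
                locf = locf_impute(panel),
                mpa = mpa_weights(panel, min_pattern_size),
                mi = mi_estimate(panel, M = M, seed = seed),
                ipmw = ipmw_estimate(panel))
  est <- if (inherits(res, "imputation_result")) res$estimate else res$estimate
  attr(est, "detail") <- res
  est
}
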
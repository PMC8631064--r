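## Stack a wide panel into person-time rows (one row per subject per visit),
## the layout used by pooled logistic regression.
person_time <- function(d, n_times) {
  out <- lapply(seq_len(n_times) - 1L, function(k) {
    data.frame(id = d$id, k = k,
               A = d[[a_col(k)]],
               L1 = d[[l1_col(k)]],
               L2 = d[[l2_col(k)]],
               A_prev = if (k == 0L) rep(0, nrow(d)) else d[[a_col(k - 1L)]],
               V = d$V)
  })
  do.call(rbind, out)
}

check_glm_fit <- function(fit, label) {
  if (!fit$converged)
    msmiss_abort("msmiss_estimation_error",
                 sprintf("%s model did not converge", label))
  p <- fit$fitted.values
  if (any(p < 1e-10 | p > 1 - 1e-10)) {
    bad <- which(p < 1e-10 | p > 1 - 1e-10)
    ks <- unique(fit$data$k[bad])
    msmiss_abort("msmiss_estimation_error",
                 sprintf("%s model separated (fitted probabilities at 0/1) at time point(s) %s",
                         label, paste(ks, collapse = ", ")))
  }
  fit
}

#' Fit pooled logistic treatment models for stabilized weights
#'
#' Stacks the panel into person-time rows and fits, by pooled logistic
#' regression with time-specific intercepts, the denominator model
#' `A_k ~ L1_k + L2_k + A_{k-1}` and the numerator model `A_k ~ A_{k-1}`
#' (`A_{-1} = 0`).  Extra covariate terms for the denominator can be supplied
#' through `denominator_extra` (e.g. `"L1:L2"` for an interaction).
#'
#' @param panel a `panel_data` with no missingness among model covariates, or
#'   a wide data frame of the same layout.
#' @param denominator_extra character vector of extra formula terms for the
#'   denominator model.
#' @return An object of class `treatment_models` with elements `denominator`,
#'   `numerator` (fitted `glm`s) and `pt` (the person-time frame).
#' @export
fit_treatment_models <- function(panel, denominator_extra = character(0)) {
  d <- if (inherits(panel, "panel_data")) {
    if (any(as.matrix(panel$mask[-1L]) != 0L))
      msmiss_abort("msmiss_estimation_error",
                   "panel has missing confounder cells; handle missingness before fitting treatment models")
    panel$data
  } else panel
  K <- sum(grepl("^A_", names(d)))
  pt <- person_time(d, K)
  if (anyNA(pt[c("A", "L1", "L2", "A_prev")]))
    msmiss_abort("msmiss_estimation_error",
                 "missing values among treatment-model covariates")
  den_terms <- c("0", "factor(k)", "L1", "L2", "A_prev", denominator_extra)
  den <- stats::glm(stats::reformulate(den_terms, response = "A"),
                    family = stats::binomial(), data = pt)
  den$data <- pt
  num <- stats::glm(A ~ 0 + factor(k) + A_prev, family = stats::binomial(),
                    data = pt)
  num$data <- pt
  check_glm_fit(den, "denominator treatment")
  check_glm_fit(num, "numerator treatment")
  structure(list(denominator = den, numerator = num, pt = pt, n_times = K),
            class = "treatment_models")
}

## Probability of the *received* treatment given the fitted probability of
## treatment 1.
received_prob <- function(p1, a) a * p1 + (1 - a) * (1 - p1)

new_weight_set <- function(tab, n_times, miss_tab = NULL) {
  structure(list(table = tab, n_times = n_times, miss_table = miss_tab),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  w <- final_weights(x)$weight
  cat(sprintf("<weight_set> %d subjects x %d times; final weight mean %.3f, max %.3f, p99 %.3f\n",
              length(w), x$n_times, mean(w), max(w),
              stats::quantile(w, 0.99)))
  invisible(x)
}

#' Final analysis weights of a weight set
#' @param ws a `weight_set`.
#' @return Data frame `id, weight` (cumulative product through the last
#'   visit, times any missingness weight).
#' @export
final_weights <- function(ws) {
  tab <- ws$table
  last <- tab[tab$k == ws$n_times - 1L, c("id", "cum")]
  names(last)[2L] <- "weight"
  if (!is.null(ws$miss_table)) {
    mlast <- ws$miss_table[ws$miss_table$k == ws$n_times - 1L, c("id", "cum")]
    last$weight <- last$weight * mlast$cum[match(last$id, mlast$id)]
  }
  last
}

#' Compute stabilized inverse-probability-of-treatment weights
#'
#' Per-visit stabilized factor = `P_num(observed A_k) / P_den(observed A_k)`;
#' the analysis weight is the cumulative product over visits.  Deterministic
#' given the fitted models.
#'
#' @param panel a `panel_data` or wide data frame (the data the models were
#'   fitted on, or compatible).
#' @param models a `treatment_models` object.
#' @return A `weight_set` whose `table` holds, per subject and visit, the
#'   numerator and denominator probabilities of the received treatment, the
#'   per-visit factor and the cumulative weight.
#' @export
compute_stabilized_weights <- function(panel, models) {
  d <- if (inherits(panel, "panel_data")) panel$data else panel
  K <- models$n_times
  pt <- person_time(d, K)
  p_den1 <- stats::predict(models$denominator, newdata = pt, type = "response")
  p_num1 <- stats::predict(models$numerator, newdata = pt, type = "response")
  p_den <- received_prob(p_den1, pt$A)
  p_num <- received_prob(p_num1, pt$A)
  if (any(p_den < 1e-12 | p_den > 1 - 1e-12)) {
    bad <- which(p_den < 1e-12 | p_den > 1 - 1e-12)
    msmiss_abort("msmiss_positivity_error",
                 sprintf("denominator probability numerically 0/1 for %d person-time row(s), e.g. id %s at k = %s",
                         length(bad), pt$id[bad[1L]], pt$k[bad[1L]]))
  }
  tab <- data.frame(id = pt$id, k = pt$k, p_num = p_num, p_den = p_den,
                    factor = p_num / p_den)
  tab <- tab[order(tab$id, tab$k), ]
  tab$cum <- stats::ave(tab$factor, tab$id, FUN = cumprod)
  rownames(tab) <- NULL
  new_weight_set(tab, K)
}

weighted_mean_var <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / sw
  c(mean = m, var = v)
}

#' Confounder balance diagnostics on the weighted pseudopopulation
#'
#' Standardized mean differences (SMD) of each confounder between treatment
#' groups at each visit, computed in the inverse-probability-weighted
#' pseudopopulation (cumulative product of inverse denominator
#' probabilities through the visit), with unweighted SMDs alongside.
#' Unstabilized weights are used here because stabilization deliberately
#' preserves the dependence of treatment on treatment history, which
#' confounders correlate with through feedback; balance in the sense of
#' "treatment independent of confounders" holds in the fully weighted
#' pseudopopulation.  The SMD denominator is the pooled (across arms)
#' standard deviation computed under the same weights.
#'
#' @param panel a `panel_data` or wide data frame.
#' @param weights a `weight_set`, or `NULL` for unit weights.
#' @return Data frame with columns `time, variable, smd_unweighted,
#'   smd_weighted`; `NA` marks a visit with an empty treatment arm.
#' @export
balance_diagnostics <- function(panel, weights = NULL) {
  d <- if (inherits(panel, "panel_data")) panel$data else panel
  K <- sum(grepl("^A_", names(d)))
  out <- list()
  for (k in seq_len(K) - 1L) {
    a <- d[[a_col(k)]]
    w <- if (is.null(weights)) rep(1, nrow(d)) else {
      tab <- weights$table[order(weights$table$id, weights$table$k), ]
      tab$inv_cum <- stats::ave(1 / tab$p_den, tab$id, FUN = cumprod)
      wk <- tab[tab$k == k, c("id", "inv_cum")]
      wk$inv_cum[match(d$id, wk$id)]
    }
    for (v in c("L1", "L2")) {
      x <- d[[paste0(v, "_", k)]]
      smd <- function(wt) {
        if (!any(a == 1L) || !any(a == 0L)) return(NA_real_)
        m1 <- weighted_mean_var(x[a == 1L], wt[a == 1L])
        m0 <- weighted_mean_var(x[a == 0L], wt[a == 0L])
        (m1[["mean"]] - m0[["mean"]]) / sqrt((m1[["var"]] + m0[["var"]]) / 2)
      }
      out[[length(out) + 1L]] <- data.frame(
        time = k, variable = v,
        smd_unweighted = smd(rep(1, nrow(d))),
        smd_weighted = smd(w))
    }
  }
  do.call(rbind, out)
}
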
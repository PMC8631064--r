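#' Configuration of the longitudinal data-generating mechanism
#'
#' Describes a sequential structural model for an observational study with a
#' baseline risk factor `V`, two time-varying confounders `L1` (binary by
#' default) and `L2` (continuous), a binary treatment `A_k` at each of
#' `n_times` visits, and an end-of-study continuous outcome `Y`.  Generation
#' order is `V -> L_0 -> A_0 -> L_1 -> A_1 -> ... -> Y`, so earlier treatment
#' feeds back into later confounders (treatment-confounder feedback) and
#' current confounders drive treatment assignment.
#'
#' The default coefficients encode moderate-to-strong confounding: treatment
#' log-odds slopes of about `log(2)` on each confounder, non-zero
#' treatment-to-confounder feedback at every lag, and confounder effects on
#' the outcome at every visit.
#'
#' @param n_times number of treatment time points `K` (visits `k = 0..K-1`).
#' @param p_L1 baseline probability that the binary confounder `L1_0` is 1
#'   (ignored when `l1_type = "gaussian"`, where `L1_0 ~ N(0, 1)`).
#' @param L2_mean,L2_sd mean and SD of the baseline continuous confounder.
#' @param L1_dyn named vector `c(intercept, lag, trt)`: logistic model for
#'   `L1_k` given `L1_{k-1}` and `A_{k-1}` (linear-Gaussian when
#'   `l1_type = "gaussian"`).
#' @param L2_dyn named vector `c(intercept, lag, trt)`: linear model for
#'   `L2_k` given `L2_{k-1}` and `A_{k-1}`.
#' @param L2_noise_sd Gaussian innovation SD of the `L2` dynamics.
#' @param L1_noise_sd innovation SD of `L1` dynamics when `l1_type =
#'   "gaussian"`.
#' @param sticky carry-over probability: at each visit `k >= 1` each
#'   confounder independently repeats its previous value exactly with this
#'   probability instead of being redrawn.  Needed for the constant-value
#'   missingness mechanism to be well defined on a continuous confounder.
#' @param trt_model named vector `c(intercept, L1, L2, lag_trt)`: pooled
#'   logistic treatment model for `A_k` given current confounders and
#'   previous treatment (`A_{-1} = 0`).
#' @param out_model list with elements `intercept`, `trt` (length `n_times`,
#'   direct effects of each `A_k`), `L1`, `L2` (length `n_times` outcome
#'   coefficients per visit) and `V`.
#' @param out_sd Gaussian outcome noise SD.
#' @param l1_type `"binary"` (default) or `"gaussian"`; the all-Gaussian
#'   variant makes the whole structural system linear so that true marginal
#'   coefficients have a closed form.
#' @return An object of class `dgm_config`.
#' @seealso [simulate_full_data()], [true_msm_coefficients()]
#' @export
dgm_config <- function(n_times = 3L,
                       p_L1 = 0.5,
                       L2_mean = 0, L2_sd = 1,
                       L1_dyn = c(intercept = 0, lag = 0.3, trt = 0.6),
                       L2_dyn = c(intercept = 0, lag = 0.4, trt = 0.6),
                       L2_noise_sd = 0.9,
                       L1_noise_sd = 0.6,
                       sticky = 0.3,
                       trt_model = c(intercept = -0.3, L1 = 0.7, L2 = 0.7,
                                     lag_trt = 0.4),
                       out_model = list(intercept = 1,
                                        trt = rep(0.4, n_times),
                                        L1 = rep(0.6, n_times),
                                        L2 = rep(0.6, n_times),
                                        V = 0.8),
                       out_sd = 1,
                       l1_type = c("binary", "gaussian")) {
  l1_type <- match.arg(l1_type)
  if (!is.numeric(n_times) || length(n_times) != 1L || !is.finite(n_times) ||
      n_times < 2)
    msmiss_abort("msmiss_config_error", "'n_times' must be an integer >= 2")
  n_times <- as.integer(n_times)
  check_scalar_prob(p_L1, "p_L1")
  check_scalar_prob(sticky, "sticky")
  check_finite(L2_mean, "L2_mean")
  check_pos_scalar(L2_sd, "L2_sd")
  check_pos_scalar(L2_noise_sd, "L2_noise_sd")
  check_pos_scalar(L1_noise_sd, "L1_noise_sd")
  check_pos_scalar(out_sd, "out_sd")
  for (nm in c("intercept", "lag", "trt")) {
    check_finite(L1_dyn[[nm]], paste0("L1_dyn$", nm))
    check_finite(L2_dyn[[nm]], paste0("L2_dyn$", nm))
  }
  for (nm in c("intercept", "L1", "L2", "lag_trt"))
    check_finite(trt_model[[nm]], paste0("trt_model$", nm))
  check_finite(out_model$intercept, "out_model$intercept")
  check_finite(out_model$V, "out_model$V")
  for (nm in c("trt", "L1", "L2")) {
    check_finite(out_model[[nm]], paste0("out_model$", nm))
    if (length(out_model[[nm]]) != n_times)
      msmiss_abort("msmiss_config_error",
                   sprintf("'out_model$%s' must have length n_times = %d",
                           nm, n_times))
  }
  structure(list(n_times = n_times, p_L1 = p_L1,
                 L2_mean = L2_mean, L2_sd = L2_sd,
                 L1_dyn = L1_dyn, L2_dyn = L2_dyn,
                 L2_noise_sd = L2_noise_sd, L1_noise_sd = L1_noise_sd,
                 sticky = sticky, trt_model = trt_model,
                 out_model = out_model, out_sd = out_sd,
                 l1_type = l1_type),
            class = "dgm_config")
}

#' Linear-Gaussian variant of the data-generating mechanism
#'
#' Convenience wrapper around [dgm_config()] with both confounders continuous
#' and all structural equations linear, so that the true marginal structural
#' coefficients can be obtained in closed form by path tracing.
#'
#' @param ... overrides passed to [dgm_config()].
#' @return A `dgm_config` with `l1_type = "gaussian"`.
#' @export
dgm_config_linear <- function(...) {
  args <- list(...)
  args$l1_type <- "gaussian"
  if (is.null(args$sticky)) args$sticky <- 0
  do.call(dgm_config, args)
}

#' @export
print.dgm_config <- function(x, ...) {
  cat(sprintf("<dgm_config> K = %d time points, L1 %s, sticky = %.2f\n",
              x$n_times, x$l1_type, x$sticky))
  cat(sprintf("  treatment model: logit P(A_k=1) = %.2f + %.2f L1_k + %.2f L2_k + %.2f A_{k-1}\n",
              x$trt_model[["intercept"]], x$trt_model[["L1"]],
              x$trt_model[["L2"]], x$trt_model[["lag_trt"]]))
  cat(sprintf("  outcome: direct treatment effects (%s), noise SD %.2f\n",
              paste(format(x$out_model$trt), collapse = ", "), x$out_sd))
  invisible(x)
}

new_panel_data <- function(data, mask, config, mechanism = "none") {
  structure(list(data = data, mask = mask, n_times = config$n_times,
                 config = config, mechanism = mechanism),
            class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  miss <- mean(as.matrix(x$mask[-1L]))
  cat(sprintf("<panel_data> %d subjects, K = %d, mechanism = %s, %.1f%% confounder cells missing\n",
              nrow(x$data), x$n_times, x$mechanism, 100 * miss))
  invisible(x)
}

#' Number of subjects in a panel
#' @param panel a `panel_data` object.
#' @return Integer subject count.
#' @export
n_subjects <- function(panel) nrow(panel$data)

#' Observed (masked) view of a panel
#'
#' Returns the wide data frame with every confounder cell whose missingness
#' flag is 1 replaced by `NA`.  A cell is present if and only if its flag is
#' 0 (flag coding: `M = 1` means missing).
#'
#' @param panel a `panel_data` object.
#' @return A wide `data.frame` (`id, V, L1_0, L2_0, A_0, ..., Y`).
#' @export
observed_data <- function(panel) {
  d <- panel$data
  cells <- confounder_cells(panel$n_times)
  for (i in seq_len(nrow(cells))) {
    col <- paste0(cells$var[i], "_", cells$k[i])
    m <- panel$mask[[mask_col(cells$var[i], cells$k[i])]] == 1L
    d[[col]][m] <- NA
  }
  d
}

## Internal simulator core.  `forced_A`: NULL, or an n x K 0/1 matrix of
## hard-set treatments (g-formula regimes).  `trt_fun`: optional function
## (k, L1k, L2k, Aprev) -> n-vector of treatment probabilities, used by the
## differential missingness generator to drop masked confounders from the
## treatment decision.
simulate_core <- function(config, n, forced_A = NULL, trt_fun = NULL,
                          baseline = NULL) {
  K <- config$n_times
  if (is.null(baseline)) {
    V <- stats::rnorm(n)
    if (config$l1_type == "binary") {
      L1 <- stats::rbinom(n, 1L, config$p_L1)
    } else {
      L1 <- stats::rnorm(n)
    }
    L2 <- stats::rnorm(n, config$L2_mean, config$L2_sd)
  } else {
    V <- baseline$V; L1 <- baseline$L1; L2 <- baseline$L2
  }
  tm <- config$trt_model
  d <- data.frame(id = seq_len(n), V = V)
  L1k <- L1; L2k <- L2; Aprev <- rep(0, n)
  L1_all <- matrix(0, n, K); L2_all <- matrix(0, n, K); A_all <- matrix(0L, n, K)
  for (k in seq_len(K) - 1L) {
    if (k > 0L) {
      ## sticky carry-over, independent per confounder
      rep1 <- stats::runif(n) < config$sticky
      rep2 <- stats::runif(n) < config$sticky
      if (config$l1_type == "binary") {
        p1 <- stats::plogis(config$L1_dyn[["intercept"]] +
                              config$L1_dyn[["lag"]] * L1k +
                              config$L1_dyn[["trt"]] * Aprev)
        new1 <- stats::rbinom(n, 1L, p1)
      } else {
        new1 <- config$L1_dyn[["intercept"]] + config$L1_dyn[["lag"]] * L1k +
          config$L1_dyn[["trt"]] * Aprev + stats::rnorm(n, 0, config$L1_noise_sd)
      }
      new2 <- config$L2_dyn[["intercept"]] + config$L2_dyn[["lag"]] * L2k +
        config$L2_dyn[["trt"]] * Aprev + stats::rnorm(n, 0, config$L2_noise_sd)
      L1k <- ifelse(rep1, L1k, new1)
      L2k <- ifelse(rep2, L2k, new2)
    }
    L1_all[, k + 1L] <- L1k
    L2_all[, k + 1L] <- L2k
    if (!is.null(forced_A)) {
      Ak <- forced_A[, k + 1L]
    } else if (!is.null(trt_fun)) {
      Ak <- stats::rbinom(n, 1L, trt_fun(k, L1k, L2k, Aprev))
    } else {
      pA <- stats::plogis(tm[["intercept"]] + tm[["L1"]] * L1k +
                            tm[["L2"]] * L2k + tm[["lag_trt"]] * Aprev)
      Ak <- stats::rbinom(n, 1L, pA)
    }
    A_all[, k + 1L] <- Ak
    Aprev <- Ak
  }
  om <- config$out_model
  Y <- om$intercept + om$V * V + stats::rnorm(n, 0, config$out_sd)
  for (k in seq_len(K)) {
    Y <- Y + om$trt[k] * A_all[, k] + om$L1[k] * L1_all[, k] +
      om$L2[k] * L2_all[, k]
  }
  for (k in seq_len(K) - 1L) {
    d[[l1_col(k)]] <- L1_all[, k + 1L]
    d[[l2_col(k)]] <- L2_all[, k + 1L]
    d[[a_col(k)]] <- A_all[, k + 1L]
  }
  d$Y <- Y
  d
}

empty_mask <- function(n, n_times) {
  cells <- confounder_cells(n_times)
  m <- data.frame(id = seq_len(n))
  for (i in seq_len(nrow(cells)))
    m[[mask_col(cells$var[i], cells$k[i])]] <- 0L
  m
}

#' Simulate a fully observed longitudinal panel
#'
#' Draws `n` independent subjects from the structural model in `config` in
#' sequential order `V -> L_0 -> A_0 -> L_1 -> A_1 -> ... -> Y`.  The result
#' has every missingness flag 0; overlay a mechanism afterwards with
#' [apply_missingness()].
#'
#' @param config a [dgm_config()].
#' @param n number of subjects (`>= 1`).
#' @param seed integer seed; identical `(config, n, seed)` give bit-identical
#'   panels.
#' @return A `panel_data` object.
#' @export
simulate_full_data <- function(config, n, seed) {
  if (!inherits(config, "dgm_config"))
    msmiss_abort("msmiss_config_error", "'config' must be a dgm_config")
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    msmiss_abort("msmiss_config_error", "'n' must be >= 1")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  d <- simulate_core(config, n)
  new_panel_data(d, empty_mask(n, config$n_times), config)
}
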
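#' Supported missingness mechanisms
#' @export
MISSINGNESS_MECHANISMS <- c("MCAR", "MAR_AL", "MAR_ALY", "MAR_ALV",
                            "CONSTANT", "DIFFERENTIAL")

mechanism_slope_names <- function(mechanism) {
  switch(mechanism,
         MCAR = character(0),
         CONSTANT = character(0),
         MAR_AL = c("A", "L1", "L2"),
         DIFFERENTIAL = c("A", "L1", "L2"),
         MAR_ALY = c("A", "L1", "L2", "Y"),
         MAR_ALV = c("A", "L1", "L2", "V"))
}

#' Configuration of a confounder missingness mechanism
#'
#' Describes how missingness flags `M` (coded `1 = missing`) are drawn for
#' the confounder cells of a panel.  MCAR, the MAR variants and DIFFERENTIAL
#' draw one record-level indicator per subject and visit (the `R_k` of the
#' mechanism's causal graph) that masks every target confounder at that
#' visit; CONSTANT is per variable, since each value's own repeat status
#' decides its missingness.  Mechanisms:
#' \describe{
#'   \item{MCAR}{intercept-only Bernoulli masking at every visit.}
#'   \item{MAR_AL}{logistic in the previous treatment and confounders
#'     (`A_{k-1}, L1_{k-1}, L2_{k-1}`), visits `k >= 1`.}
#'   \item{MAR_ALY}{MAR_AL predictors plus the end-of-study outcome `Y`.}
#'   \item{MAR_ALV}{MAR_AL predictors plus the baseline risk factor `V`.}
#'   \item{CONSTANT}{a value can be missing only when it exactly equals its
#'     previous measurement (probability `plogis(intercept)` given a repeat,
#'     0 otherwise), so carrying the last observation forward reconstructs
#'     the truth exactly.}
#'   \item{DIFFERENTIAL}{masks drawn as under MAR_AL but *before* the
#'     treatment decision at each visit; the treatment model drops any
#'     confounder masked at that visit, severing the link between a missing
#'     value and the contemporaneous treatment.}
#' }
#' Only MCAR masks baseline (`k = 0`) cells; the history-dependent mechanisms
#' start at `k = 1` because their predictors are lagged.
#'
#' @param mechanism one of `r paste(MISSINGNESS_MECHANISMS, collapse = ", ")`.
#' @param intercept logistic intercept of the masking model; leave `NA` and
#'   call [calibrate_missingness()] to hit a target proportion.
#' @param slopes named numeric vector of slopes on the mechanism's allowed
#'   predictors (subset of `A`, `L1`, `L2`, `Y`, `V`); predictors not allowed
#'   for the mechanism must be absent.
#' @param target nominal missingness proportion among maskable cells, used by
#'   calibration (main scenario 0.40, secondary scenario 0.05).
#' @param targets which confounders may be masked (default both).
#' @return An object of class `missingness_config`.
#' @export
missingness_config <- function(mechanism, intercept = NA_real_,
                               slopes = NULL, target = 0.40,
                               targets = c("L1", "L2")) {
  mechanism <- match.arg(mechanism, MISSINGNESS_MECHANISMS)
  allowed <- mechanism_slope_names(mechanism)
  if (is.null(slopes)) slopes <- default_mechanism_slopes(mechanism)
  if (length(slopes) && is.null(names(slopes)))
    msmiss_abort("msmiss_config_error", "'slopes' must be named")
  extra <- setdiff(names(slopes), allowed)
  if (length(extra))
    msmiss_abort("msmiss_config_error",
                 sprintf("mechanism %s does not admit slopes on: %s",
                         mechanism, paste(extra, collapse = ", ")))
  if (length(slopes)) check_finite(slopes, "slopes")
  if (!is.na(intercept)) check_finite(intercept, "intercept")
  check_scalar_prob(target, "target")
  if (target <= 0 || target >= 1)
    msmiss_abort("msmiss_config_error", "'target' must lie strictly in (0, 1)")
  targets <- match.arg(targets, c("L1", "L2"), several.ok = TRUE)
  structure(list(mechanism = mechanism, intercept = intercept,
                 slopes = slopes, target = target, targets = targets),
            class = "missingness_config")
}

default_mechanism_slopes <- function(mechanism) {
  switch(mechanism,
         MCAR = numeric(0),
         CONSTANT = numeric(0),
         MAR_AL = c(A = 0.5, L1 = 0.5, L2 = 0.5),
         DIFFERENTIAL = c(A = 0.5, L1 = 0.5, L2 = 0.5),
         MAR_ALY = c(A = 0.5, L1 = 0.5, L2 = 0.5, Y = 0.4),
         MAR_ALV = c(A = 0.5, L1 = 0.5, L2 = 0.5, V = 0.6))
}

#' @export
print.missingness_config <- function(x, ...) {
  cat(sprintf("<missingness_config> %s, target %.0f%%, intercept %s\n",
              x$mechanism, 100 * x$target,
              if (is.na(x$intercept)) "uncalibrated" else format(x$intercept)))
  if (length(x$slopes))
    cat("  slopes:", paste(names(x$slopes), format(x$slopes), sep = " = ",
                           collapse = ", "), "\n")
  invisible(x)
}

## Visits at which a mechanism may mask cells.
maskable_times <- function(mechanism, n_times) {
  if (mechanism == "MCAR") seq_len(n_times) - 1L else seq_len(n_times - 1L)
}

#' Realized missingness among a mechanism's maskable cells
#'
#' Proportion of the confounder cells the mechanism is allowed to mask (all
#' visits for MCAR, visits `k >= 1` otherwise) whose flags are set.  This is
#' the quantity [calibrate_missingness()] drives to its target.
#'
#' @param panel a `panel_data`.
#' @param mconfig the [missingness_config()] that was applied.
#' @return A proportion in `[0, 1]`.
#' @export
realized_missingness <- function(panel, mconfig) {
  ks <- maskable_times(mconfig$mechanism, panel$n_times)
  cols <- unlist(lapply(ks, function(k) mask_col(mconfig$targets, k)))
  mean(as.matrix(panel$mask[cols]))
}

#' Overlay a missingness mechanism on a fully observed panel
#'
#' Draws missingness flags for the confounder cells according to `mconfig`.
#' True values are retained alongside the flags (the masked view is obtained
#' with [observed_data()]).  The one documented exception to the mask-only
#' contract is the DIFFERENTIAL mechanism, which re-draws treatments (and,
#' consequently, downstream confounders and the outcome) so that a masked
#' confounder no longer enters the contemporaneous treatment decision.
#'
#' @param panel a fully observed `panel_data` (pre-existing missingness is an
#'   error).
#' @param mconfig a calibrated [missingness_config()].
#' @param seed integer seed.
#' @return A `panel_data` with flags set.
#' @export
apply_missingness <- function(panel, mconfig, seed) {
  if (!inherits(panel, "panel_data"))
    msmiss_abort("msmiss_config_error", "'panel' must be a panel_data")
  if (any(as.matrix(panel$mask[-1L]) != 0L))
    msmiss_abort("msmiss_config_error",
                 "panel already contains missingness; apply_missingness needs a fully observed panel")
  if (is.na(mconfig$intercept))
    msmiss_abort("msmiss_config_error",
                 "missingness intercept is NA; run calibrate_missingness() first")
  if (mconfig$mechanism == "CONSTANT" && panel$config$sticky == 0)
    msmiss_abort("msmiss_config_error",
                 "CONSTANT mechanism requires sticky dynamics (sticky > 0): a continuous confounder repeats exactly with probability zero otherwise")
  set.seed(as.integer(seed))
  switch(mconfig$mechanism,
         MCAR = mask_mcar(panel, mconfig),
         CONSTANT = mask_constant(panel, mconfig),
         MAR_AL = mask_mar(panel, mconfig),
         MAR_ALY = mask_mar(panel, mconfig),
         MAR_ALV = mask_mar(panel, mconfig),
         DIFFERENTIAL = mask_differential(panel, mconfig))
}

## MCAR, MAR and DIFFERENTIAL draw one record-level missingness indicator
## per subject and visit, applied to every target confounder (the R_k of the
## mechanism's causal graph); the CONSTANT mechanism is per variable because
## each value's own repeat status decides its missingness.
mask_mcar <- function(panel, mconfig) {
  n <- n_subjects(panel)
  p <- stats::plogis(mconfig$intercept)
  mask <- panel$mask
  for (k in seq_len(panel$n_times) - 1L) {
    m <- as.integer(stats::runif(n) < p)
    for (v in mconfig$targets)
      mask[[mask_col(v, k)]] <- m
  }
  new_panel_data(panel$data, mask, panel$config, mconfig$mechanism)
}

mask_constant <- function(panel, mconfig) {
  n <- n_subjects(panel)
  p <- stats::plogis(mconfig$intercept)
  mask <- panel$mask
  d <- panel$data
  for (k in seq_len(panel$n_times - 1L))
    for (v in mconfig$targets) {
      cur <- d[[paste0(v, "_", k)]]
      prev <- d[[paste0(v, "_", k - 1L)]]
      rep_ <- cur == prev
      mask[[mask_col(v, k)]] <- as.integer(rep_ & stats::runif(n) < p)
    }
  new_panel_data(panel$data, mask, panel$config, mconfig$mechanism)
}

## Linear predictor of the masking model at visit k, built from lagged
## treatment and confounders (a lagged confounder contributes only while its
## own cell is unmasked, so the mechanism depends on observed data only).
mar_linear_predictor <- function(d, mask, k, mconfig) {
  sl <- mconfig$slopes
  lp <- rep(mconfig$intercept, nrow(d))
  lp <- lp + sl[["A"]] * d[[a_col(k - 1L)]]
  for (v in c("L1", "L2")) {
    obs <- if (k - 1L == 0L) rep(TRUE, nrow(d)) else
      mask[[mask_col(v, k - 1L)]] == 0L
    lp <- lp + ifelse(obs, sl[[v]] * d[[paste0(v, "_", k - 1L)]], 0)
  }
  if ("Y" %in% names(sl)) lp <- lp + sl[["Y"]] * d$Y
  if ("V" %in% names(sl)) lp <- lp + sl[["V"]] * d$V
  lp
}

mask_mar <- function(panel, mconfig) {
  n <- n_subjects(panel)
  mask <- panel$mask
  d <- panel$data
  for (k in seq_len(panel$n_times - 1L)) {
    lp <- mar_linear_predictor(d, mask, k, mconfig)
    m <- as.integer(stats::runif(n) < stats::plogis(lp))
    for (v in mconfig$targets)
      mask[[mask_col(v, k)]] <- m
  }
  new_panel_data(panel$data, mask, panel$config, mconfig$mechanism)
}

## DIFFERENTIAL: per-visit generation order is L_k -> M_k -> A_k.  Baseline
## variables and A_0 are kept from the input panel (masks start at k = 1);
## later confounders, treatments and the outcome are re-drawn because the
## modified treatment decisions feed forward.
mask_differential <- function(panel, mconfig) {
  config <- panel$config
  n <- n_subjects(panel)
  K <- panel$n_times
  tm <- config$trt_model
  d <- panel$data
  mask <- empty_mask(n, K)
  L1k <- d$L1_0; L2k <- d$L2_0; Aprev <- d$A_0
  L1_all <- matrix(0, n, K); L2_all <- matrix(0, n, K); A_all <- matrix(0L, n, K)
  L1_all[, 1L] <- L1k; L2_all[, 1L] <- L2k; A_all[, 1L] <- Aprev
  work <- d
  for (k in seq_len(K - 1L)) {
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
    work[[l1_col(k)]] <- L1k
    work[[l2_col(k)]] <- L2k
    ## record-level mask depends on lagged treatment/confounders, drawn
    ## before the treatment decision at k
    lp <- mar_linear_predictor(work, mask, k, mconfig)
    m <- as.integer(stats::runif(n) < stats::plogis(lp))
    m1 <- if ("L1" %in% mconfig$targets) m else rep(0L, n)
    m2 <- if ("L2" %in% mconfig$targets) m else rep(0L, n)
    mask[[mask_col("L1", k)]] <- m1
    mask[[mask_col("L2", k)]] <- m2
    ## treatment decision uses only observed confounders at k
    pA <- stats::plogis(tm[["intercept"]] +
                          tm[["L1"]] * L1k * (1 - m1) +
                          tm[["L2"]] * L2k * (1 - m2) +
                          tm[["lag_trt"]] * Aprev)
    Ak <- stats::rbinom(n, 1L, pA)
    work[[a_col(k)]] <- Ak
    L1_all[, k + 1L] <- L1k; L2_all[, k + 1L] <- L2k; A_all[, k + 1L] <- Ak
    Aprev <- Ak
  }
  om <- config$out_model
  Y <- om$intercept + om$V * d$V + stats::rnorm(n, 0, config$out_sd)
  for (k in seq_len(K))
    Y <- Y + om$trt[k] * A_all[, k] + om$L1[k] * L1_all[, k] +
      om$L2[k] * L2_all[, k]
  work$Y <- Y
  new_panel_data(work, mask, config, mconfig$mechanism)
}

#' Calibrate a missingness mechanism to a target proportion
#'
#' Adjusts the masking intercept by monotone root finding so that the
#' realized proportion of missing cells among the mechanism's maskable cells
#' (all visits for MCAR; visits `k >= 1` otherwise) matches `target` on
#' large simulated panels.  Slopes are untouched.  For MCAR the intercept is
#' `qlogis(target)` analytically.
#'
#' @param mconfig a [missingness_config()].
#' @param config the [dgm_config()] the mechanism will be applied to.
#' @param target proportion in (0, 1); defaults to `mconfig$target`.
#' @param seed integer seed for the calibration panel.
#' @param n_cal subjects in the calibration panel.
#' @return `mconfig` with the intercept set (and `target` updated).
#' @export
calibrate_missingness <- function(mconfig, config, target = mconfig$target,
                                  seed = 1L, n_cal = 20000L) {
  if (!is.numeric(target) || target <= 0 || target >= 1)
    msmiss_abort("msmiss_config_error", "'target' must lie in (0, 1)")
  mconfig$target <- target
  if (mconfig$mechanism == "MCAR") {
    mconfig$intercept <- stats::qlogis(target)
    return(mconfig)
  }
  panel <- simulate_full_data(config, n_cal, substream_seed(seed, 701L))
  mask_seed <- substream_seed(seed, 702L)
  realized <- function(intercept) {
    m <- mconfig
    m$intercept <- intercept
    realized_missingness(apply_missingness(panel, m, mask_seed), m)
  }
  lo <- -20; hi <- 20
  r_lo <- realized(lo); r_hi <- realized(hi)
  if (target < r_lo || target > r_hi)
    msmiss_abort("msmiss_calibration_error",
                 sprintf("target %.3f unreachable for mechanism %s; achievable range is [%.3f, %.3f]",
                         target, mconfig$mechanism, r_lo, r_hi))
  root <- stats::uniroot(function(b) realized(b) - target, c(lo, hi),
                         tol = 1e-4)
  mconfig$intercept <- root$root
  mconfig
}

#' Shipped missingness scenarios
#'
#' The main scenario masks about 40\% of maskable confounder cells; the
#' secondary scenario about 5\%.  Both use the MAR_AL mechanism by default
#' (missingness predicted by the previous treatment and confounders) with the
#' package's standard slope values; the intercept is calibrated against
#' `config` at construction.
#'
#' @param config a [dgm_config()]; defaults to the package default.
#' @param mechanism mechanism name, default `"MAR_AL"`.
#' @param seed calibration seed.
#' @return A calibrated `missingness_config`.
#' @export
main_scenario_config <- function(config = dgm_config(), mechanism = "MAR_AL",
                                 seed = 1L) {
  calibrate_missingness(missingness_config(mechanism, target = 0.40),
                        config, seed = seed)
}

#' @rdname main_scenario_config
#' @export
secondary_scenario_config <- function(config = dgm_config(),
                                      mechanism = "MAR_AL", seed = 1L) {
  calibrate_missingness(missingness_config(mechanism, target = 0.05),
                        config, seed = seed)
}

#' Missingness summary of a panel
#'
#' @param panel a `panel_data`.
#' @return A list with `by_cell` (per variable and visit missing
#'   proportions), `overall` (proportion over all confounder cells),
#'   `patterns` (counts of distinct missingness patterns over all confounder
#'   cells; counts sum to the number of subjects) and `n`.
#' @export
missingness_summary <- function(panel) {
  cells <- confounder_cells(panel$n_times)
  props <- vapply(seq_len(nrow(cells)), function(i)
    mean(panel$mask[[mask_col(cells$var[i], cells$k[i])]]), numeric(1))
  by_cell <- data.frame(variable = cells$var, time = cells$k,
                        prop_missing = props)
  mm <- as.matrix(panel$mask[-1L])
  lab <- apply(mm, 1L, function(r) {
    miss <- colnames(mm)[r == 1L]
    if (!length(miss)) "complete" else paste(sub("^M_", "", miss), collapse = "+")
  })
  tab <- sort(table(lab), decreasing = TRUE)
  patterns <- data.frame(pattern = names(tab), count = as.integer(tab),
                         row.names = NULL)
  list(by_cell = by_cell, overall = mean(mm), patterns = patterns,
       n = nrow(mm))
}
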
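#' Specify a simulation scenario
#'
#' Bundles a data-generating configuration, a missingness mechanism, the
#' methods to compare, the sample size, the replication count and a root
#' seed.  Replicates use independent substreams keyed by replicate index, so
#' results are invariant to execution order.
#'
#' @param dgm a [dgm_config()].
#' @param mconfig a calibrated [missingness_config()], or `NULL` to analyze
#'   fully observed data.
#' @param methods character vector of methods (see [analyze_panel()]).
#' @param n subjects per replicate.
#' @param R replications (`>= 1`).
#' @param seed root seed.
#' @param truth optional `true_estimand`; computed from `dgm` by the
#'   g-formula oracle when `NULL`.
#' @param M imputations for `"mi"`.
#' @param id scenario identifier.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(dgm, mconfig = NULL, methods = "full",
                          n = 10000L, R = 200L, seed = 1L, truth = NULL,
                          M = 10L, id = NULL) {
  if (!length(methods))
    msmiss_abort("msmiss_config_error", "'methods' must be non-empty")
  if (R < 1) msmiss_abort("msmiss_config_error", "'R' must be >= 1")
  if (is.null(id))
    id <- paste0(if (is.null(mconfig)) "FULL" else mconfig$mechanism,
                 "_n", n)
  structure(list(dgm = dgm, mconfig = mconfig, methods = methods,
                 n = as.integer(n), R = as.integer(R),
                 seed = as.integer(seed), truth = truth, M = as.integer(M),
                 id = id),
            class = "scenario_spec")
}

#' Performance metrics of replicate estimates against the truth
#'
#' @param estimates replicate x coefficient matrix of point estimates.
#' @param truth a `true_estimand` (or named vector of true coefficients).
#' @param ses optional matrix of model SEs (same shape).
#' @param cis optional list of per-replicate CI matrices (`lower`, `upper`).
#' @return Data frame with one row per coefficient: `bias`, `mcse_bias`
#'   (empirical SD / sqrt(R)), `empirical_sd`, `mean_model_se`, `coverage`,
#'   `mean_abs_bias`, `R`.
#' @export
performance_metrics <- function(estimates, truth, ses = NULL, cis = NULL) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 2)
    msmiss_abort("msmiss_empty_error",
                 "need at least 2 successful replicates for performance metrics")
  tr <- if (inherits(truth, "true_estimand")) truth$beta else truth
  tr <- tr[colnames(estimates)]
  R <- nrow(estimates)
  bias <- colMeans(estimates) - tr
  esd <- apply(estimates, 2L, stats::sd)
  cov <- if (!is.null(cis)) {
    hit <- vapply(seq_along(cis), function(r)
      cis[[r]][, "lower"] <= tr & tr <= cis[[r]][, "upper"],
      logical(ncol(estimates)))
    rowMeans(matrix(hit, ncol = length(cis)))
  } else rep(NA_real_, ncol(estimates))
  data.frame(coefficient = colnames(estimates),
             truth = unname(tr), bias = unname(bias),
             mcse_bias = unname(esd / sqrt(R)),
             empirical_sd = unname(esd),
             mean_model_se = if (is.null(ses)) NA_real_ else
               unname(colMeans(ses)),
             coverage = unname(cov),
             mean_abs_bias = unname(colMeans(abs(sweep(estimates, 2L, tr)))),
             R = R, row.names = NULL)
}

#' Run a method-by-mechanism simulation scenario
#'
#' For each replicate: simulate a fresh panel, overlay the missingness
#' mechanism, analyze with every requested method, and collect the
#' coefficient estimates.  Replicate-level failures are logged and excluded;
#' more than 10\% failures for any method aborts the scenario.
#'
#' @param spec a [scenario_spec()].
#' @param n_mc_truth trajectories per regime for the g-formula truth when
#'   `spec$truth` is `NULL`.
#' @return An object of class `simulation_summary`: `metrics` (per method x
#'   coefficient data frame), `abs_bias` (replicate-level absolute biases for
#'   box plots), `failures`, `truth`, `spec`.
#' @export
run_scenario <- function(spec, n_mc_truth = 200000L) {
  truth <- spec$truth %||%
    true_msm_coefficients(spec$dgm, "gformula_mc", n_mc = n_mc_truth,
                          seed = substream_seed(spec$seed, 999L))
  methods <- spec$methods
  est <- stats::setNames(vector("list", length(methods)), methods)
  ses <- stats::setNames(vector("list", length(methods)), methods)
  cis <- stats::setNames(lapply(methods, function(m) list()), methods)
  failures <- stats::setNames(integer(length(methods)), methods)
  for (r in seq_len(spec$R)) {
    panel <- simulate_full_data(spec$dgm, spec$n,
                                substream_seed(spec$seed, 1L, r))
    if (!is.null(spec$mconfig))
      panel <- apply_missingness(panel, spec$mconfig,
                                 substream_seed(spec$seed, 2L, r))
    for (m in methods) {
      fit <- tryCatch(
        analyze_panel(panel, m, M = spec$M,
                      seed = substream_seed(spec$seed, 3L, r)),
        error = function(e) NULL)
      if (is.null(fit)) {
        failures[m] <- failures[m] + 1L
      } else {
        est[[m]] <- rbind(est[[m]], fit$coef)
        ses[[m]] <- rbind(ses[[m]], fit$se)
        cis[[m]][[length(cis[[m]]) + 1L]] <- fit$ci
      }
    }
  }
  if (any(failures > 0.1 * spec$R))
    msmiss_abort("msmiss_instability_error",
                 sprintf("method(s) %s failed in >10%% of replicates",
                         paste(names(failures)[failures > 0.1 * spec$R],
                               collapse = ", ")))
  metrics <- list()
  abs_bias <- list()
  tr <- truth$beta
  for (m in methods) {
    pm <- performance_metrics(est[[m]], truth, ses[[m]], cis[[m]])
    pm <- cbind(method = m, pm)
    metrics[[m]] <- pm
    ab <- abs(sweep(est[[m]], 2L, tr[colnames(est[[m]])]))
    for (cf in colnames(ab))
      abs_bias[[paste(m, cf, sep = ".")]] <- ab[, cf]
  }
  structure(list(metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
                 abs_bias = abs_bias, failures = failures, truth = truth,
                 spec = spec, estimates = est),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("<simulation_summary> scenario %s: n = %d, R = %d\n",
              x$spec$id, x$spec$n, x$spec$R))
  df <- x$metrics
  df[] <- lapply(df, function(c) if (is.numeric(c)) round(c, 4) else c)
  print(df)
  invisible(x)
}

#' Export scenario results to tidy CSV files
#'
#' Writes `summary.csv` (one row per method x coefficient x metric),
#' `absolute_bias.csv` (one column per method x coefficient, `R` rows, for
#' box plots) and `manifest.json` (scenario settings, seed, package version)
#' into `dir`.
#'
#' @param summary a `simulation_summary`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_results <- function(summary, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) msmiss_abort("msmiss_io_error", sprintf("cannot create '%s'", dir))
  mets <- c("bias", "mcse_bias", "empirical_sd", "mean_model_se",
            "coverage", "mean_abs_bias")
  tidy <- do.call(rbind, lapply(mets, function(m)
    data.frame(method = summary$metrics$method,
               coefficient = summary$metrics$coefficient,
               metric = m, value = summary$metrics[[m]])))
  tidy <- cbind(scenario = summary$spec$id, tidy)
  rownames(tidy) <- NULL
  spath <- file.path(dir, "summary.csv")
  utils::write.csv(tidy, spath, row.names = FALSE)
  ab <- as.data.frame(summary$abs_bias)
  apath <- file.path(dir, "absolute_bias.csv")
  utils::write.csv(ab, apath, row.names = FALSE)
  manifest <- list(schema_version = "1",
                   scenario = summary$spec$id,
                   n = summary$spec$n, R = summary$spec$R,
                   seed = summary$spec$seed,
                   methods = summary$spec$methods,
                   mechanism = if (is.null(summary$spec$mconfig)) "none" else
                     summary$spec$mconfig$mechanism,
                   failures = as.list(summary$failures),
                   truth = as.list(round(summary$truth$beta, 8)),
                   package_version = as.character(utils::packageVersion("msmiss")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(summary = spath, absolute_bias = apath, manifest = mpath))
}

#' Re-import an exported tidy summary
#' @param dir directory written by [export_results()].
#' @return The tidy summary data frame.
#' @export
import_results <- function(dir) {
  utils::read.csv(file.path(dir, "summary.csv"), stringsAsFactors = FALSE)
}
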
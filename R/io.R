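#' Write a panel to CSV
#'
#' Wide dialect: one row per subject with columns
#' `id, V, L1_0, L2_0, A_0, ..., L1_{K-1}, L2_{K-1}, A_{K-1}, Y`; masked
#' cells are written as empty fields.  Long dialect: one row per
#' `(id, k)` with columns `id, k, V, L1, L2, A, Y` (`V` and `Y` repeated).
#' Column order is deterministic.  UTF-8, comma separator, `.` decimal.
#'
#' @param panel a `panel_data`.
#' @param path output file.
#' @param dialect `"wide"` or `"long"`.
#' @param true_path optional path for a companion file holding the unmasked
#'   true values (simulation audits).
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path, dialect = c("wide", "long"),
                        true_path = NULL) {
  dialect <- match.arg(dialect)
  obs <- observed_data(panel)[wide_columns(panel$n_times)]
  emit <- function(d, p) {
    if (dialect == "long") d <- wide_to_long(d, panel$n_times)
    ok <- tryCatch({
      utils::write.csv(d, p, row.names = FALSE, na = "")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) msmiss_abort("msmiss_io_error", sprintf("cannot write '%s'", p))
  }
  emit(obs, path)
  if (!is.null(true_path))
    emit(panel$data[wide_columns(panel$n_times)], true_path)
  invisible(path)
}

wide_to_long <- function(d, K) {
  do.call(rbind, lapply(seq_len(K) - 1L, function(k)
    data.frame(id = d$id, k = k, V = d$V,
               L1 = d[[l1_col(k)]], L2 = d[[l2_col(k)]],
               A = d[[a_col(k)]], Y = d$Y)))[order(rep(d$id, K)), ]
}

#' Read a panel from CSV
#'
#' Inverse of [write_panel()]: empty cells become missing confounder flags.
#' Validation is strict: the header must match the documented dialect
#' exactly (order-independent), treatments must be 0/1, ids unique.
#' True values for masked cells are unknown to a file-read panel, so its
#' internal data holds `NA` there; all estimation methods work from the
#' observed view only.
#'
#' @param path CSV file.
#' @param dialect `"wide"` or `"long"`.
#' @param config optional `dgm_config` to attach (needed only to re-derive
#'   truth or apply further simulation steps).
#' @return A `panel_data`.
#' @export
read_panel <- function(path, dialect = c("wide", "long"), config = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    msmiss_abort("msmiss_io_error", sprintf("file '%s' does not exist", path))
  d <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  if (dialect == "long") {
    need <- c("id", "k", "V", "L1", "L2", "A", "Y")
    unknown <- setdiff(names(d), need)
    if (length(unknown))
      msmiss_abort("msmiss_schema_error",
                   sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")))
    if (!all(need %in% names(d)))
      msmiss_abort("msmiss_schema_error",
                   sprintf("missing column(s): %s",
                           paste(setdiff(need, names(d)), collapse = ", ")))
    d <- long_to_wide(d)
  }
  K <- sum(grepl("^A_", names(d)))
  if (K < 2)
    msmiss_abort("msmiss_schema_error", "need treatment columns A_0, A_1, ...")
  need <- wide_columns(K)
  unknown <- setdiff(names(d), need)
  if (length(unknown))
    msmiss_abort("msmiss_schema_error",
                 sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")))
  if (!all(need %in% names(d)))
    msmiss_abort("msmiss_schema_error",
                 sprintf("missing column(s): %s",
                         paste(setdiff(need, names(d)), collapse = ", ")))
  d <- d[need]
  if (anyDuplicated(d$id))
    msmiss_abort("msmiss_schema_error",
                 sprintf("duplicate id: %s", d$id[anyDuplicated(d$id)]))
  for (k in seq_len(K) - 1L) {
    a <- d[[a_col(k)]]
    bad <- which(!is.na(a) & !(a %in% c(0, 1)))
    if (length(bad))
      msmiss_abort("msmiss_schema_error",
                   sprintf("non-binary treatment value in column %s, row %d",
                           a_col(k), bad[1L]))
  }
  cfg <- config %||% dgm_config(n_times = K)
  n <- nrow(d)
  mask <- empty_mask(n, K)
  cells <- confounder_cells(K)
  for (i in seq_len(nrow(cells))) {
    col <- paste0(cells$var[i], "_", cells$k[i])
    mask[[mask_col(cells$var[i], cells$k[i])]] <-
      as.integer(is.na(d[[col]]))
  }
  new_panel_data(d, mask, cfg, "file")
}

long_to_wide <- function(d) {
  d <- d[order(d$id, d$k), ]
  ids <- unique(d$id)
  ks <- sort(unique(d$k))
  out <- data.frame(id = ids)
  first <- d[!duplicated(d$id), ]
  out$V <- first$V[match(ids, first$id)]
  for (k in ks) {
    dk <- d[d$k == k, ]
    m <- match(ids, dk$id)
    out[[l1_col(k)]] <- dk$L1[m]
    out[[l2_col(k)]] <- dk$L2[m]
    out[[a_col(k)]] <- dk$A[m]
  }
  out$Y <- first$Y[match(ids, first$id)]
  out
}
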
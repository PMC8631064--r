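#' @keywords internal
"_PACKAGE"

## Structured conditions: every user-facing failure carries a subclass so the
## CLI can map it onto an exit code and tests can assert on the class.
msmiss_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "msmiss_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a root seed
#'
#' All randomness in the package flows from one root seed; independent stages
#' (data generation, masking, oracle, bootstrap and scenario replicates) use
#' substreams so that adding a stage never perturbs another stage's draws.
#'
#' @param seed integer root seed.
#' @param ... one or more non-negative integer offsets identifying the stream.
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed) %% 2147483647
  for (o in offs) {
    s <- (s * 48271 + as.double(o) * 8191 + 1) %% 2147483647
  }
  as.integer(s)
}

## column helpers for the wide layout
l1_col <- function(k) paste0("L1_", k)
l2_col <- function(k) paste0("L2_", k)
a_col  <- function(k) paste0("A_", k)
mask_col <- function(var, k) paste0("M_", var, "_", k)

wide_columns <- function(n_times) {
  c("id", "V",
    unlist(lapply(seq_len(n_times) - 1L,
                  function(k) c(l1_col(k), l2_col(k), a_col(k)))),
    "Y")
}

confounder_cells <- function(n_times) {
  expand.grid(var = c("L1", "L2"), k = seq_len(n_times) - 1L,
              stringsAsFactors = FALSE)
}

check_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    msmiss_abort("msmiss_config_error",
                 sprintf("'%s' must be a probability in [0, 1]", name))
  invisible(x)
}

check_pos_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    msmiss_abort("msmiss_config_error",
                 sprintf("'%s' must be a finite positive number", name))
  invisible(x)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    msmiss_abort("msmiss_config_error",
                 sprintf("'%s' must be finite numeric", name))
  invisible(x)
}
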
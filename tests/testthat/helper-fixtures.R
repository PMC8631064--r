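# Shared fixtures and independent brute-force oracles used across the suite.

# Small DGM used where speed matters more than realism.
tiny_dgm <- function(...) dgm_config(...)

# A DGM with every causal pathway from treatment switched off.
null_effect_dgm <- function() {
  dgm_config(L1_dyn = c(intercept = -0.2, lag = 1.0, trt = 0),
             L2_dyn = c(intercept = 0, lag = 0.7, trt = 0),
             out_model = list(intercept = 1, trt = c(0, 0, 0),
                              L1 = rep(0.6, 3), L2 = rep(0.6, 3), V = 0.8))
}

# A DGM whose treatment is randomized (no confounder enters assignment).
randomized_dgm <- function() {
  dgm_config(trt_model = c(intercept = -0.1, L1 = 0, L2 = 0, lag_trt = 0.3))
}

# Build a panel_data from an inline wide CSV string (goes through the
# public reader, so masks come from empty cells).
panel_from_csv <- function(txt) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(txt, path)
  read_panel(path)
}

# Brute-force weighted least squares via the normal equations.
wls_oracle <- function(X, y, w) {
  solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% y)[, 1]
}

# Brute-force weighted standardized mean difference (pooled weighted SD).
smd_oracle <- function(x, a, w) {
  wm <- function(v, wt) sum(wt * v) / sum(wt)
  wv <- function(v, wt) sum(wt * (v - wm(v, wt))^2) / sum(wt)
  (wm(x[a == 1], w[a == 1]) - wm(x[a == 0], w[a == 0])) /
    sqrt((wv(x[a == 1], w[a == 1]) + wv(x[a == 0], w[a == 0])) / 2)
}

expect_panels_equal <- function(p1, p2) {
  expect_equal(p1$data, p2$data)
  expect_equal(p1$mask, p2$mask)
}
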
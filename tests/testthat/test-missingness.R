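test_that("degenerate MCAR leaves the panel untouched", {
  p <- simulate_full_data(dgm_config(), 500, 1)
  mc <- missingness_config("MCAR", intercept = -50)
  out <- apply_missingness(p, mc, 2)
  expect_identical(out$data, p$data)
  expect_true(all(as.matrix(out$mask[-1L]) == 0L))
})

test_that("masking mechanisms set flags without altering true values", {
  cfg <- dgm_config()
  p <- simulate_full_data(cfg, 2000, 5)
  for (mech in c("MCAR", "MAR_AL", "MAR_ALY", "MAR_ALV", "CONSTANT")) {
    mc <- missingness_config(mech, intercept = -0.5)
    out <- apply_missingness(p, mc, 31)
    expect_identical(out$data, p$data)
    expect_gt(sum(as.matrix(out$mask[-1L])), 0)
    # observed view is NA exactly where flags are 1
    obs <- observed_data(out)
    for (k in 0:2) for (v in c("L1", "L2"))
      expect_identical(is.na(obs[[paste0(v, "_", k)]]),
                       out$mask[[paste0("M_", v, "_", k)]] == 1L)
    # deterministic under the same seed
    expect_identical(apply_missingness(p, mc, 31)$mask, out$mask)
    # history-dependent mechanisms never mask baseline
    if (mech != "MCAR")
      expect_true(all(out$mask$M_L1_0 == 0L & out$mask$M_L2_0 == 0L))
  }
  expect_error(apply_missingness(apply_missingness(p,
    missingness_config("MCAR", intercept = 0), 1),
    missingness_config("MCAR", intercept = 0), 2),
    class = "msmiss_config_error")
})

test_that("constant mechanism masks only exact repeats", {
  cfg <- dgm_config()
  p <- simulate_full_data(cfg, 5000, 8)
  mc <- missingness_config("CONSTANT", intercept = 5)
  out <- apply_missingness(p, mc, 9)
  d <- p$data
  for (k in 1:2) for (v in c("L1", "L2")) {
    changed <- d[[paste0(v, "_", k)]] != d[[paste0(v, "_", k - 1)]]
    expect_true(all(out$mask[[paste0("M_", v, "_", k)]][changed] == 0L))
  }
  # with a high masking probability nearly every repeat is masked
  rep2 <- d$L2_1 == d$L2_0
  expect_gt(mean(out$mask$M_L2_1[rep2]), 0.95)
  # continuous confounders without sticky dynamics never repeat exactly
  p0 <- simulate_full_data(dgm_config(sticky = 0), 100, 1)
  expect_error(apply_missingness(p0, mc, 1), class = "msmiss_config_error")
})

test_that("calibration hits 40% and 5% targets on fresh panels", {
  cfg <- dgm_config()
  main <- calibrate_missingness(missingness_config("MAR_AL"), cfg, 0.40,
                                seed = 4)
  fresh <- simulate_full_data(cfg, 20000, 1234)
  r <- realized_missingness(apply_missingness(fresh, main, 77), main)
  expect_gt(r, 0.38); expect_lt(r, 0.42)

  low <- calibrate_missingness(missingness_config("MAR_AL"), cfg, 0.05,
                               seed = 4)
  r2 <- realized_missingness(apply_missingness(fresh, low, 78), low)
  expect_gt(r2, 0.03); expect_lt(r2, 0.07)

  # intercept-only mechanism calibrates analytically
  mcar <- calibrate_missingness(missingness_config("MCAR"), cfg, 0.40)
  expect_identical(mcar$intercept, qlogis(0.40))

  expect_error(calibrate_missingness(missingness_config("MAR_AL"), cfg, 1.2),
               class = "msmiss_config_error")
})

test_that("realized MAR missingness recovers the configured slopes", {
  cfg <- dgm_config()
  mc <- calibrate_missingness(missingness_config("MAR_AL"), cfg, 0.40,
                              seed = 4)
  p <- apply_missingness(simulate_full_data(cfg, 40000, 13), mc, 14)
  d <- p$data
  fit <- glm(p$mask$M_L1_1 ~ d$A_0 + d$L1_0 + d$L2_0, family = binomial())
  sm <- summary(fit)$coefficients
  for (i in 2:4)
    expect_lt(abs(sm[i, "Estimate"] - 0.5), 3 * sm[i, "Std. Error"])
  expect_lt(abs(sm[1, "Estimate"] - mc$intercept), 3 * sm[1, "Std. Error"])
})

test_that("differential mechanism severs the masked-confounder edge", {
  cfg <- dgm_config()
  mc <- calibrate_missingness(missingness_config("DIFFERENTIAL"), cfg, 0.40,
                              seed = 4)
  p <- apply_missingness(simulate_full_data(cfg, 60000, 17), mc, 18)
  d <- p$data
  for (k in 1:2) {
    masked <- p$mask[[paste0("M_L1_", k)]] == 1L
    unmasked <- !masked
    f <- reformulate(c(paste0("L1_", k), paste0("L2_", k), paste0("A_", k - 1)),
                     response = paste0("A_", k))
    sm_m <- summary(glm(f, binomial(), d[masked, ]))$coefficients
    sm_u <- summary(glm(f, binomial(), d[unmasked, ]))$coefficients
    # among masked records the true values no longer predict treatment
    expect_lt(abs(sm_m[2, "Estimate"]), 3.5 * sm_m[2, "Std. Error"])
    expect_lt(abs(sm_m[3, "Estimate"]), 3.5 * sm_m[3, "Std. Error"])
    # among observed records the treatment-model slopes are recovered
    expect_lt(abs(sm_u[2, "Estimate"] - 0.7), 3.5 * sm_u[2, "Std. Error"])
    expect_lt(abs(sm_u[3, "Estimate"] - 0.7), 3.5 * sm_u[3, "Std. Error"])
  }
  # treatments are re-drawn: this mechanism is exempt from the mask-only rule
  expect_false(identical(p$data, simulate_full_data(cfg, 60000, 17)$data))
  # but reproducible under the same seed
  q <- apply_missingness(simulate_full_data(cfg, 60000, 17), mc, 18)
  expect_identical(q$data, p$data)
  expect_identical(q$mask, p$mask)
})

test_that("missingness summaries enumerate patterns", {
  p <- simulate_full_data(dgm_config(), 400, 3)
  s <- missingness_summary(p)
  expect_equal(s$patterns$pattern, "complete")
  expect_equal(s$patterns$count, 400)
  expect_true(all(s$by_cell$prop_missing == 0))

  # two confounders maskable at one visit -> at most 4 patterns
  cfg2 <- dgm_config(n_times = 2,
                     out_model = list(intercept = 1, trt = c(0.4, 0.4),
                                      L1 = c(0.6, 0.6), L2 = c(0.6, 0.6),
                                      V = 0.8))
  p2 <- simulate_full_data(cfg2, 3000, 5)
  m2 <- apply_missingness(p2, missingness_config("MAR_AL", intercept = 0), 6)
  s2 <- missingness_summary(m2)
  expect_lte(nrow(s2$patterns), 4)
  expect_equal(sum(s2$patterns$count), 3000)

  # two confounders at two visits -> at most 16 patterns
  m3 <- apply_missingness(p2, missingness_config("MCAR", intercept = 0), 7)
  s3 <- missingness_summary(m3)
  expect_lte(nrow(s3$patterns), 16)
  expect_equal(sum(s3$patterns$count), 3000)
})
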
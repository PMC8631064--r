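test_that("all five strategies collapse onto the full-data fit when nothing is missing", {
  p <- simulate_full_data(dgm_config(), 600, 21)
  full <- analyze_panel(p, "full")
  for (m in c("cc", "locf", "mpa", "ipmw", "mi")) {
    est <- analyze_panel(p, m, M = 3)
    expect_equal(unname(est$coef), unname(full$coef), tolerance = 1e-10)
  }
  # MI on complete data has zero between-imputation variance
  mi <- attr(analyze_panel(p, "mi", M = 3), "detail")
  expect_equal(unname(mi$B), rep(0, 4))
  expect_equal(mi$T_var, mi$W, tolerance = 1e-12)
})

test_that("complete-case analysis keeps exactly the unmasked subjects", {
  p <- simulate_full_data(dgm_config(), 300, 19)
  p$mask$M_L2_1[c(10, 20)] <- 1L
  p$mask$M_L1_2[c(20, 30)] <- 1L
  res <- complete_case(p)
  expect_equal(n_subjects(res$panel), 297)
  expect_equal(res$n_dropped, 3)
  expect_s3_class(res$estimate, "msm_estimate")
  all_masked <- p
  all_masked$mask$M_L1_0 <- 1L
  expect_error(complete_case(all_masked), class = "msmiss_empty_error")
})

test_that("LOCF carries the most recent observed value forward", {
  p <- panel_from_csv(paste(
    "id,V,L1_0,L2_0,A_0,L1_1,L2_1,A_1,L1_2,L2_2,A_2,Y",
    "1,0.1,1,2.0,1,0,,0,1,,1,3.1",
    "2,-0.2,0,1.0,0,,0.5,1,,0.9,0,2.0",
    "3,0.3,,2.5,1,1,2.0,1,1,2.2,0,4.2",
    "4,0.0,0,0.5,0,1,0.7,1,0,0.8,1,1.1",
    "5,0.5,1,1.8,0,1,1.7,1,0,1.5,0,3.3",
    "6,-0.3,0,1.2,1,0,1.4,0,1,1.0,1,2.5", sep = "\n"))
  res <- locf_fill(p)
  # subject 3 has a missing baseline and is dropped
  expect_equal(res$n_dropped, 1)
  expect_equal(n_subjects(res$panel), 5)
  d <- res$panel$data
  # subject 1: L2 trajectory (2.0, ., .) -> (2.0, 2.0, 2.0)
  expect_equal(unlist(d[1, c("L2_0", "L2_1", "L2_2")], use.names = FALSE),
               c(2.0, 2.0, 2.0))
  # subject 2: L1 trajectory (0, ., .) -> (0, 0, 0)
  expect_equal(unlist(d[2, c("L1_0", "L1_1", "L1_2")], use.names = FALSE),
               c(0, 0, 0))
  expect_false(anyNA(observed_data(res$panel)))
  # the full LOCF analysis runs end to end on a realistic panel
  cfg <- dgm_config()
  mc <- calibrate_missingness(missingness_config("MCAR"), cfg, 0.3)
  pm <- apply_missingness(simulate_full_data(cfg, 800, 23), mc, 24)
  full <- locf_impute(pm)
  expect_false(anyNA(observed_data(full$panel)))
  expect_equal(full$n_dropped + n_subjects(full$panel), 800)
})

test_that("Rubin pooling reproduces hand-computed values and identities", {
  r <- rubin_pool(c(1, 1, 1), c(0.5, 0.5, 0.5))
  expect_equal(r$pooled, 1)
  expect_equal(r$B, 0)
  expect_equal(r$T, 0.5)
  expect_equal(r$df, Inf)

  r2 <- rubin_pool(c(1, 2, 3), c(0.5, 0.5, 0.5))
  expect_equal(r2$pooled, 2)
  expect_equal(r2$W, 0.5)
  expect_equal(r2$B, 1)
  expect_equal(r2$T, 0.5 + (4 / 3) * 1, tolerance = 1e-12)

  # scaling all within variances by c scales W and T - (1 + 1/M) B by c
  cmul <- 3.7
  r3 <- rubin_pool(c(1, 2, 3), cmul * c(0.5, 0.5, 0.5))
  expect_equal(r3$W, cmul * r2$W, tolerance = 1e-12)
  expect_equal(r3$T - (1 + 1 / 3) * r3$B, cmul * (r2$T - (1 + 1 / 3) * r2$B),
               tolerance = 1e-12)

  expect_error(rubin_pool(1, 0.5), class = "msmiss_config_error")

  # exact identity T = W + (1 + 1/M) B on arbitrary inputs
  set.seed(1)
  for (i in 1:20) {
    M <- sample(2:12, 1)
    est <- rnorm(M); wv <- rexp(M)
    r <- rubin_pool(est, wv)
    expect_identical(r$T, r$W + (1 + 1 / M) * r$B)
    expect_identical(r$pooled, mean(est))
  }
})

test_that("imputation engine respects types and draws from observed donors", {
  cfg <- dgm_config()
  mc <- calibrate_missingness(missingness_config("MAR_AL"), cfg, 0.4, seed = 2)
  p <- apply_missingness(simulate_full_data(cfg, 1500, 31), mc, 32)
  res <- attr(analyze_panel(p, "mi", M = 3, seed = 5), "detail")
  expect_s3_class(res, "imputation_result")
  expect_equal(nrow(res$per_imputation), 3)
  # Rubin identity holds coefficient-wise
  expect_equal(res$T_var, res$W + (1 + 1 / 3) * res$B, tolerance = 1e-12)
  # pooled point estimate is the mean of the per-imputation estimates
  expect_equal(unname(res$estimate$coef),
               unname(colMeans(res$per_imputation)), tolerance = 1e-12)
  # a column with no observed values is inestimable
  p2 <- p
  p2$mask$M_L1_1 <- 1L
  expect_error(mi_estimate(p2, M = 2), class = "msmiss_estimation_error")
})

test_that("predictive mean matching picks among the nearest donors", {
  set.seed(4)
  yhat_obs <- c(1, 2, 3, 10, 11)
  y_obs <- c(101, 102, 103, 110, 111)
  out <- replicate(200, msmiss:::pmm_match(yhat_obs, y_obs, c(2.1, 10.4),
                                           donors = 2))
  # recipient near 2.1 can only receive donors with predictions 2 or 3
  expect_true(all(out[1, ] %in% c(102, 103)))
  expect_true(all(out[2, ] %in% c(110, 111)))
  expect_gt(length(unique(out[1, ])), 1)
})

test_that("MPA weights come from saturated within-pattern models", {
  set.seed(77)
  n <- 40
  d <- data.frame(id = 1:n, V = 0,
                  L1_0 = rbinom(n, 1, 0.5), L2_0 = rbinom(n, 1, 0.5))
  d$A_0 <- rbinom(n, 1, 0.25 + 0.4 * d$L2_0)
  d$L1_1 <- rbinom(n, 1, 0.5); d$L2_1 <- rbinom(n, 1, 0.5)
  d$A_1 <- rbinom(n, 1, 0.3 + 0.2 * d$A_0 + 0.2 * d$L2_1)
  d$Y <- rnorm(n) + d$A_0 + d$L2_1
  cfg <- dgm_config(n_times = 2,
                    out_model = list(intercept = 0, trt = c(1, 0),
                                     L1 = c(0, 0), L2 = c(0, 1), V = 0))
  mask <- msmiss:::empty_mask(n, 2)
  mask$M_L1_0[1:20] <- 1L
  panel <- msmiss:::new_panel_data(d, mask, cfg)
  res <- mpa_weights(panel, min_pattern_size = 1)
  tab <- res$weights$table
  rows <- tab$k == 0 & tab$id <= 20
  # denominator: saturated logistic in binary L2 within the pattern
  # equals the empirical cell frequency of the received treatment
  for (id in 1:20) {
    l2 <- d$L2_0[id]; a <- d$A_0[id]
    cell <- mean(d$A_0[1:20][d$L2_0[1:20] == l2])
    expect_equal(tab$p_den[tab$id == id & tab$k == 0],
                 if (a == 1) cell else 1 - cell, tolerance = 1e-8)
    # numerator: marginal treatment frequency at k = 0 over all subjects
    marg <- mean(d$A_0)
    expect_equal(tab$p_num[tab$id == id & tab$k == 0],
                 if (a == 1) marg else 1 - marg, tolerance = 1e-8)
  }
  expect_true(all(sort(unique(tab$pattern)) %in% c("L1", "none")))
})

test_that("MPA merges sparse patterns and rejects masked exposures", {
  cfg <- dgm_config()
  # the constant mechanism masks per variable, producing single-variable
  # patterns that can fall below the pattern floor
  mc <- calibrate_missingness(missingness_config("CONSTANT"), cfg, 0.10)
  p <- apply_missingness(simulate_full_data(cfg, 400, 41), mc, 42)
  res <- mpa_weights(p, min_pattern_size = 400)
  expect_gt(length(res$merges), 0)
  expect_s3_class(res$estimate, "msm_estimate")

  masked_a <- panel_from_csv(paste(
    "id,V,L1_0,L2_0,A_0,L1_1,L2_1,A_1,Y",
    "1,0.1,1,2.0,1,0,1.5,,3.1",
    "2,-0.2,0,1.0,0,1,0.5,1,2.0", sep = "\n"))
  expect_error(mpa_weights(masked_a), class = "msmiss_unsupported_error")
  expect_error(locf_impute(masked_a), class = "msmiss_unsupported_error")
})

test_that("IPMW censors at the first missing visit and multiplies weights", {
  cfg <- dgm_config()
  p <- simulate_full_data(cfg, 2000, 51)
  # subject 7: L2 missing at k = 1, observed again at k = 2 (nonmonotone);
  # a few more censored subjects keep the remain models estimable
  p$mask$M_L2_1[c(7, 101:130)] <- 1L
  p$mask$M_L1_2[201:230] <- 1L
  res <- ipmw_estimate(p)
  cpt <- res$censor_person_time
  # censored at k = 1: at risk at 0 and 1, never at 2
  expect_equal(sort(cpt$k[cpt$id == 7]), c(0, 1))
  expect_equal(cpt$remain[cpt$id == 7 & cpt$k == 1], 0L)
  expect_equal(res$n_uncensored, 2000 - 61)
  # subject 7 contributes nothing to the fitted MSM
  expect_false(7 %in% final_weights(res$weights)$id)
  # cumulative missingness weight is the running product of its factors
  m <- res$weights$miss_table
  for (id in c(1, 900)) {
    rows <- m[m$id == id, ]
    expect_equal(rows$cum, cumprod(rows$factor), tolerance = 1e-12)
  }
})

test_that("analyze_panel rejects full-data analysis of masked panels", {
  cfg <- dgm_config()
  mc <- calibrate_missingness(missingness_config("MCAR"), cfg, 0.4)
  p <- apply_missingness(simulate_full_data(cfg, 200, 61), mc, 62)
  expect_error(analyze_panel(p, "full"), class = "msmiss_unsupported_error")
})
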
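test_that("wide CSV round-trips values and masks", {
  cfg <- dgm_config()
  mc <- calibrate_missingness(missingness_config("MCAR"), cfg, 0.3)
  p <- apply_missingness(simulate_full_data(cfg, 150, 71), mc, 72)
  path <- withr::local_tempfile(fileext = ".csv")
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, path, true_path = tpath)
  q <- read_panel(path)
  expect_equal(q$mask, p$mask)
  expect_equal(observed_data(q), observed_data(p), tolerance = 1e-12)
  # the audit companion retains the unmasked truth
  tq <- read.csv(tpath)
  expect_false(anyNA(tq))
  expect_equal(tq$L1_1, p$data$L1_1)
  # empty cells appear exactly where flags are set
  raw <- readLines(path)
  expect_equal(sum(grepl(",,", raw)) > 0, TRUE)
})

test_that("a panel without missingness writes no empty cells", {
  p <- simulate_full_data(dgm_config(), 50, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, path)
  expect_false(any(grepl(",,|,$", readLines(path))))
})

test_that("long dialect reshapes correctly", {
  txt <- paste(
    "id,k,V,L1,L2,A,Y",
    "1,0,0.5,1,2.0,1,3.4",
    "1,1,0.5,0,1.5,0,3.4",
    "1,2,0.5,1,1.0,1,3.4",
    "2,0,-0.1,0,0.8,0,2.1",
    "2,1,-0.1,1,,1,2.1",
    "2,2,-0.1,0,0.4,0,2.1", sep = "\n")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, path)
  p <- read_panel(path, dialect = "long")
  expect_equal(p$n_times, 3)
  expect_equal(p$data$L2_0, c(2.0, 0.8))
  expect_equal(p$mask$M_L2_1, c(0L, 1L))
  expect_equal(p$data$Y, c(3.4, 2.1))
  # long round trip
  out <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, out, dialect = "long")
  p2 <- read_panel(out, dialect = "long")
  expect_equal(p2$data, p$data)
  expect_equal(p2$mask, p$mask)
})

test_that("schema violations are reported with names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("id,V,L1_0,L2_0,A_0,L1_1,L2_1,A_1,Y,extra",
                   "1,0,1,2,1,0,1,0,3,9", sep = "\n"), path)
  expect_error(read_panel(path), "extra", class = "msmiss_schema_error")

  writeLines(paste("id,V,L1_0,L2_0,A_0,L1_1,L2_1,A_1,Y",
                   "1,0,1,2,2,0,1,0,3", sep = "\n"), path)
  expect_error(read_panel(path), "A_0", class = "msmiss_schema_error")

  writeLines(paste("id,V,L1_0,L2_0,A_0,L1_1,L2_1,A_1,Y",
                   "1,0,1,2,1,0,1,0,3",
                   "1,0,0,1,0,1,2,1,4", sep = "\n"), path)
  expect_error(read_panel(path), "duplicate", class = "msmiss_schema_error")

  expect_error(read_panel("/nonexistent/file.csv"),
               class = "msmiss_io_error")
})

test_that("cli simulate is byte-deterministic and validates usage", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.csv"); f2 <- file.path(dir, "b.csv")
  expect_equal(msmiss_cli(c("simulate", "--n", "100", "--seed", "1",
                            "--out", f1)), 0L)
  expect_equal(msmiss_cli(c("simulate", "--n", "100", "--seed", "1",
                            "--out", f2)), 0L)
  expect_identical(readLines(f1), readLines(f2))

  expect_equal(msmiss_cli(c("frobnicate")), 2L)
  expect_equal(msmiss_cli(character(0)), 2L)
  expect_equal(suppressWarnings(msmiss_cli(c("simulate", "--bogus-flag", "1"))), 2L)
})

test_that("cli analyze writes results with a manifest", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "panel.csv")
  msmiss_cli(c("simulate", "--n", "400", "--seed", "3", "--out", csv,
               "--mechanism", "MAR_AL", "--target", "0.2"))
  out <- file.path(dir, "res.json")
  code <- msmiss_cli(c("analyze", "--in", csv, "--method", "mi",
                       "--imputations", "3", "--seed", "2", "--out", out))
  expect_equal(code, 0L)
  res <- jsonlite::read_json(out)
  expect_equal(res$method, "mi")
  expect_equal(res$manifest$counts$imputations, 3)
  expect_named(res$coefficients, c("beta_int", "beta_0", "beta_1", "beta_2"))

  # a masked exposure is a structured analysis failure for the MPA
  bad <- file.path(dir, "bad.csv")
  writeLines(paste("id,V,L1_0,L2_0,A_0,L1_1,L2_1,A_1,Y",
                   "1,0.1,1,2.0,1,0,1.5,,3.1",
                   "2,-0.2,0,1.0,0,1,0.5,1,2.0", sep = "\n"), bad)
  expect_equal(msmiss_cli(c("analyze", "--in", bad, "--method", "mpa")), 1L)
})

test_that("cli experiment and report run end to end", {
  dir <- withr::local_tempdir()
  scen <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(list(schema_version = "1", id = "demo",
                        mechanism = "MCAR", target = 0.2,
                        methods = list("cc"), n = 300, R = 4,
                        n_mc_truth = 5000), scen)
  out <- file.path(dir, "results")
  expect_equal(msmiss_cli(c("experiment", "--scenario", scen, "--seed", "4",
                            "--out", out)), 0L)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$scenario, "demo")
  expect_equal(man$R, 4)
  expect_true(nchar(man$config_hashes$scenario) == 32)
  expect_output(expect_equal(msmiss_cli(c("report", "--in", out)), 0L),
                "bias")
})
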
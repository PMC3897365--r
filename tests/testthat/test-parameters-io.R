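test_that("bundled fixtures reproduce the canonical parameter set", {
  for (ext in c("json", "yaml")) {
    path <- system.file("extdata", paste0("params_4t1.", ext),
                        package = "angiomet")
    pars <- load_parameters(path)
    expect_s3_class(pars, "sia_parameters")
    expect_equal(unclass(pars), unclass(default_parameters()),
                 tolerance = 1e-12)
  }
})

test_that("parameter validation names the offending key", {
  good <- unclass(default_parameters())
  bad <- good; bad$k <- NULL
  expect_error(do.call(model_parameters, bad), "\\bk\\b")
  expect_error(angiomet:::validate_parameters(c(good, list(zz = 1))),
               "zz")
  bad <- good; bad$alpha <- 1.5
  expect_error(do.call(model_parameters, bad), "alpha")
  bad <- good; bad$k <- 0
  expect_error(do.call(model_parameters, bad), "'k'")
  bad <- good; bad$V0 <- 2; bad$Vm <- 1
  expect_error(do.call(model_parameters, bad), "Vm")
})

test_that("parameter files round-trip through JSON and YAML", {
  pars <- default_parameters()
  for (ext in c("json", "yaml")) {
    tmp <- tempfile(fileext = paste0(".", ext))
    write_parameters(pars, tmp)
    expect_equal(unclass(load_parameters(tmp)), unclass(pars),
                 tolerance = 1e-9)
    unlink(tmp)
  }
  expect_error(load_parameters("no/such/file.json"), "not found")
  expect_error(write_parameters(pars, tempfile(fileext = ".txt")),
               "extension")
})

test_that("trajectory outputs round-trip through CSV and JSON", {
  tr <- run_scenario("huang", dt = 0.25)
  prefix <- file.path(tempdir(), "huangtest")
  paths <- write_outputs(tr, prefix)
  expect_true(all(file.exists(paths)))

  ts <- read_timeseries(paths[["timeseries"]])
  expect_equal(ts$time, tr$times)
  expect_equal(ts$M, tr$M, tolerance = 1e-12)
  expect_equal(ts$V_p, tr$V_p, tolerance = 1e-12)

  sm <- read_summary(paths[["summary"]])
  n <- length(tr$times)
  expect_equal(sm$N, tr$N[n], tolerance = 1e-12)
  expect_equal(sm$parameters$b_p, 16.7)
  expect_true(is.null(sm$stop_time) || is.na(sm$stop_time))
  unlink(paths)
})

test_that("a stopped history run records its stop time in the summary", {
  tr <- run_scenario("history", dt = 0.25)
  prefix <- file.path(tempdir(), "histtest")
  paths <- write_outputs(tr, prefix)
  sm <- read_summary(paths[["summary"]])
  expect_equal(sm$stop_time, tr$stop_time, tolerance = 1e-12)
  expect_equal(sm$stop_burden, 5000)
  unlink(paths)
})

test_that("command-line interface runs end to end on small problems", {
  cli <- system.file("cli", "angiomet.R", package = "angiomet")
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  env <- c(paste0("R_LIBS=", shQuote(libs)))

  out <- suppressWarnings(system2(rscript, c(cli, "derive"),
                                  stdout = TRUE, stderr = TRUE, env = env))
  expect_match(paste(out, collapse = "\n"), "8.33333e-06")
  expect_match(paste(out, collapse = "\n"), "0.0716*")

  prefix <- file.path(tempdir(), "clirun")
  out2 <- suppressWarnings(system2(
    rscript,
    c(cli, "simulate", "--scenario", "custom", "--T", "4", "--dt", "0.2",
      "--no-sia", "--Vp0", "0.1", "--Kp0", "200", "--out", prefix),
    stdout = TRUE, stderr = TRUE, env = env))
  expect_true(file.exists(paste0(prefix, "_summary.json")))
  sm <- read_summary(paste0(prefix, "_summary.json"))
  expect_equal(sm$final_time, 4)

  status <- suppressWarnings(system2(rscript, c(cli, "bogus"),
                                     stdout = FALSE, stderr = FALSE,
                                     env = env))
  expect_equal(status, 2)
})
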
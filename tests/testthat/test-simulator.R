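test_that("per-step number balance holds to machine precision", {
  pars <- default_parameters()
  tr <- simulate_system(pars, V_p0 = 0.1, K_p0 = 200, T = 12, dt = 0.1,
                        sia = TRUE)
  n <- length(tr$times)
  dN <- diff(tr$N)
  expected <- tr$emission[-1] * tr$dt - tr$outflux[-1]
  expect_equal(dN, expected, tolerance = 1e-12)
})

test_that("balance law survives removal through the outflow boundary", {
  # start with a large circulating inhibitor load and no production:
  # carrying capacities collapse and cohorts die by nutrient deprivation
  pars <- unclass(default_parameters())
  pars$p <- 0
  pars <- do.call(model_parameters, pars)
  tr <- simulate_system(pars, V_p0 = 500, K_p0 = 1000, T = 25, dt = 0.05,
                        I0 = 5, sia = TRUE)
  expect_gt(sum(tr$outflux), 0) # some cohorts were removed
  dN <- diff(tr$N)
  expect_equal(dN, tr$emission[-1] * tr$dt - tr$outflux[-1],
               tolerance = 1e-12)
  # removed cohorts no longer carry count or burden
  n <- length(tr$times)
  expect_equal(tr$N[n], sum(tr$cohorts$weight[tr$cohorts$alive]) * tr$dt)
})

test_that("no dissemination means no metastases", {
  pars <- unclass(default_parameters())
  pars$m <- 0
  pars <- do.call(model_parameters, pars)
  tr <- simulate_system(pars, V_p0 = 0.1, K_p0 = 200, T = 10, dt = 0.1,
                        sia = FALSE)
  expect_true(all(tr$N == 0))
  expect_true(all(tr$M == 0))
  expect_true(all(tr$emission == 0))
})

test_that("no emission occurs while every lesion sits below the threshold", {
  pars <- default_parameters()
  # primary starts at one cell: nothing can emit before it reaches Vm
  tr <- simulate_system(pars, V_p0 = pars$V0, K_p0 = 1, T = 10, dt = 0.05,
                        sia = TRUE)
  below <- tr$V_p < pars$Vm
  expect_true(all(tr$emission[below] == 0))
  expect_true(any(!below) || all(tr$N == 0))
})

test_that("without dissemination and inhibition, N is flat and the primary approaches its Gompertz plateau", {
  pars <- unclass(default_parameters())
  pars$m <- 0
  pars$p <- 0
  pars$e <- 0
  pars <- do.call(model_parameters, pars)
  tr <- simulate_system(pars, V_p0 = 1, K_p0 = 1, T = 250, dt = 0.05,
                        sia = FALSE)
  n <- length(tr$times)
  V_star <- (pars$b_p / pars$d_p)^(3 / 2)
  expect_equal(tr$V_p[n], V_star, tolerance = 0.01)
  expect_true(all(diff(tr$N) >= 0))
})

test_that("with p = 0 the metastasis count never decreases and the burden eventually grows", {
  pars <- unclass(default_parameters())
  pars$p <- 0
  pars <- do.call(model_parameters, pars)
  tr <- simulate_system(pars, V_p0 = 0.1, K_p0 = 200, T = 20, dt = 0.1,
                        sia = TRUE)
  expect_true(all(diff(tr$N) >= -1e-12))
  n <- length(tr$times)
  expect_true(all(diff(tr$M[(n - 50):n]) > 0))
})

test_that("inhibitor relaxes exponentially to p * V / k when the tumor volume is frozen", {
  # freeze the primary at its no-inhibition fixed point and turn off
  # dissemination and inhibitor efficacy so nothing feeds back
  base <- unclass(default_parameters())
  base$m <- 0
  base$e <- 0
  pars <- do.call(model_parameters, base)
  V_star <- (pars$b_p / pars$d_p)^(3 / 2)
  tr <- simulate_system(pars, V_p0 = V_star, K_p0 = V_star, T = 15,
                        dt = 0.01, sia = TRUE)
  I_expected <- pars$p * V_star / pars$k * (1 - exp(-pars$k * tr$times))
  expect_equal(tr$I, I_expected, tolerance = 1e-3)
  expect_true(all(tr$I >= 0))
})

test_that("visible count honors its threshold and the size histogram conserves mass", {
  tr <- run_scenario("huang", dt = 0.1)
  n <- length(tr$times)
  # a threshold at the newborn size counts everything
  expect_equal(count_visible(tr, min_volume = 1e-6), tr$N[n])
  expect_lt(count_visible(tr, min_volume = 1e-5), tr$N[n])
  expect_lt(count_visible(tr, min_volume = 10),
            count_visible(tr, min_volume = 1e-5))
  dist <- size_distribution(tr, breaks = 10^seq(-7, 4, by = 0.5))
  expect_equal(sum(dist$count), tr$N[n], tolerance = 1e-12)
  expect_error(size_distribution(tr, breaks = c(1, 0.1)), "increasing")
})

test_that("burden stopping rule reports an interpolated crossing time", {
  tr <- run_scenario("history", dt = 0.1)
  n <- length(tr$times)
  expect_false(is.na(tr$stop_time))
  expect_gte(tr$M[n], 5000)
  expect_lt(tr$M[n - 1], 5000)
  expect_true(tr$stop_time <= tr$times[n] && tr$stop_time >= tr$times[n - 1])
})

test_that("degenerate arguments are rejected", {
  pars <- default_parameters()
  expect_error(simulate_system(pars, 0.1, 200, T = 10, dt = 0), "dt")
  expect_error(simulate_system(pars, 0.1, 200, T = -1), "T")
  expect_error(simulate_system(pars, -0.1, 200, T = 10), "primary")
  expect_error(count_visible(run_scenario("huang", dt = 0.5),
                             min_volume = 0), "min_volume")
})
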
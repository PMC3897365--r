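test_that("coefficient of determination matches its definition", {
  y <- c(1, 5, 2, 8)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(rep(mean(y), 4), y), 0)
  expect_equal(r_squared(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_error(r_squared(c(1, 2), c(3, 3)), "constant")
  expect_error(r_squared(1, 1), "2 data points")
  expect_error(r_squared(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("primary fit recovers generating parameters from a noiseless curve", {
  spec <- synthetic_spec(noise_sd = 0, seed = 1)
  curve <- generate_growth_curve(spec)
  fit <- fit_primary(curve)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$par[["a_p"]], 0.154), 0.01)
  expect_lt(rel_err(fit$par[["b_p"]], 16.7), 0.01)
  expect_gt(fit$r_squared, 0.9999)
})

test_that("a constant growth curve is flagged non-identifiable instead of fitted", {
  flat <- data.frame(time = c(5, 10, 15, 20), volume = rep(200, 4))
  fit <- fit_primary(flat)
  expect_false(fit$identifiable)
  expect_false(fit$converged)
  expect_true(is.na(fit$par[["a_p"]]))
  expect_match(fit$message, "unidentifiable")
})

test_that("growth-curve data are validated", {
  expect_error(fit_primary(data.frame(time = 1, volume = 2)), "2 data")
  expect_error(fit_primary(data.frame(time = c(2, 1), volume = c(1, 2))),
               "increasing")
  expect_error(fit_primary(data.frame(time = c(1, 2), volume = c(1, -2))),
               "positive")
  expect_error(fit_primary(data.frame(t = c(1, 2), v = c(1, 2))),
               "columns")
})

test_that("metastatic fit recovers (b, m) exactly when targets are model outputs", {
  ep <- generate_endpoints(synthetic_spec(noise_sd = 0), dt = 0.1)
  fit <- fit_metastatic(count = ep$count, mean_size = ep$mean_size,
                        dt = 0.1)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$par[["b"]], 12.5), 1e-4)
  expect_lt(rel_err(fit$par[["m"]], 0.0229), 1e-4)
  expect_lt(fit$rss, 1e-12)
})

test_that("metastatic optimum beats 50 deterministic pseudo-random restarts", {
  ep <- generate_endpoints(synthetic_spec(noise_sd = 0), dt = 0.1)
  fit <- fit_metastatic(count = ep$count, mean_size = ep$mean_size,
                        dt = 0.1)
  objective <- function(b, m) {
    pp <- unclass(default_parameters())
    pp$b <- b; pp$m <- m
    pp <- do.call(model_parameters, pp)
    tr <- simulate_system(pp, V_p0 = 0.1, K_p0 = 200, T = 32, dt = 0.1,
                          sia = FALSE)
    nvis <- count_visible(tr)
    ms <- if (nvis > 0) tail(tr$M, 1) / nvis else 0
    (nvis / ep$count - 1)^2 + (ms / ep$mean_size - 1)^2
  }
  set.seed(99)
  draws <- cbind(b = 10^runif(50, -1, 2), m = 10^runif(50, -4, 1))
  obj_draws <- apply(draws, 1, function(x) objective(x[1], x[2]))
  expect_true(all(fit$rss <= obj_draws + 1e-12))
})

test_that("full pipeline round-trips: generate, fit both stages, re-simulate", {
  spec <- synthetic_spec(noise_sd = 0.05, seed = 7)
  curve <- generate_growth_curve(spec)
  pfit <- fit_primary(curve)
  expect_true(pfit$converged)
  expect_lt(rel_err(pfit$par[["a_p"]], 0.154), 0.25)
  expect_lt(rel_err(pfit$par[["b_p"]], 16.7), 0.25)

  ep <- generate_endpoints(synthetic_spec(noise_sd = 0), dt = 0.1)
  pars <- unclass(default_parameters())
  pars$a_p <- pfit$par[["a_p"]]
  pars$b_p <- pfit$par[["b_p"]]
  pars$a <- pfit$par[["a_p"]] # metastatic proliferation tied to primary
  pars <- do.call(model_parameters, pars)
  mfit <- fit_metastatic(count = ep$count, mean_size = ep$mean_size,
                         pars = pars, dt = 0.1)
  expect_true(mfit$converged)
  # predicted observables reproduce the targets within the noise scale
  expect_lt(rel_err(mfit$fitted_values[["count"]], ep$count), 0.05)
  expect_lt(rel_err(mfit$fitted_values[["mean_size"]], ep$mean_size), 0.05)
})
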
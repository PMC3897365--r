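#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - f)^2) / sum((y - mean(y))^2)`, the goodness-of-fit
#' score reported for the growth-curve fits.
#'
#' @param model_values fitted model values `f`.
#' @param data_values observed values `y`.
#' @return A single number `<= 1` (negative when the model fits worse than
#'   the data mean).
#' @export
#' @examples
#' r_squared(c(1, 2, 4), c(1, 2, 3))
r_squared <- function(model_values, data_values) {
  if (length(model_values) != length(data_values))
    stop("'model_values' and 'data_values' must have equal length",
         call. = FALSE)
  if (length(data_values) < 2L)
    stop("need at least 2 data points", call. = FALSE)
  ss_tot <- sum((data_values - mean(data_values))^2)
  if (ss_tot == 0)
    stop("R^2 is undefined for constant data", call. = FALSE)
  1 - sum((data_values - model_values)^2) / ss_tot
}

new_fit <- function(par, rss, r2 = NA_real_, converged, identifiable = TRUE,
                    message = "", bounds = NULL, fitted_values = NULL) {
  structure(list(par = par, rss = rss, r_squared = r2,
                 converged = converged, identifiable = identifiable,
                 message = message, bounds = bounds,
                 fitted_values = fitted_values),
            class = "sia_fit")
}

#' @export
print.sia_fit <- function(x, ...) {
  cat("Least-squares calibration result\n")
  for (nm in names(x$par))
    cat(sprintf("  %-4s = %.6g\n", nm, x$par[[nm]]))
  cat(sprintf("  RSS = %.6g", x$rss))
  if (!is.na(x$r_squared)) cat(sprintf("   R^2 = %.4f", x$r_squared))
  cat(sprintf("   converged: %s\n", x$converged))
  if (!x$identifiable) cat("  WARNING: non-identifiable fit --", x$message, "\n")
  invisible(x)
}

#' Fit primary-tumor growth parameters
#'
#' First stage of the two-stage calibration: estimate the proliferation
#' rate `a_p` and angiogenic stimulation `b_p` from a primary growth curve
#' by minimizing the sum of squared errors between the solved growth model
#' and the measured volumes. Systemic inhibition is negligible over such
#' experiments, so the model is integrated with `I = 0`; the local
#' inhibition coefficient `d_p` is held fixed (it is derived
#' biophysically, see [derive_local_inhibition()], which removes an
#' indeterminacy from the estimation). Minimization uses the
#' Levenberg-Marquardt trust-region algorithm (`minpack.lm::nls.lm`) with
#' box constraints and a deterministic list of log-spaced multi-starts to
#' avoid local minima.
#'
#' A growth curve lying on a constant trajectory (`V = K` throughout)
#' makes `a_p` unidentifiable (the Gompertz factor `log(K/V)` vanishes);
#' such data are detected and returned flagged rather than fitted.
#'
#' @param data data.frame with columns `time` (days, strictly increasing)
#'   and `volume` (mm^3, positive); an optional `se` column is ignored by
#'   the unweighted fit.
#' @param d_p fixed local inhibition coefficient (mm^-2 day^-1).
#' @param V_p0,K_p0 initial condition of the growth model (mm^3).
#' @param lower,upper bounds on `(a_p, b_p)`.
#' @param starts number of deterministic log-spaced starting points.
#' @return An object of class `"sia_fit"` with elements `par` (named
#'   `a_p`, `b_p`), `rss`, `r_squared`, `converged`, `identifiable` and
#'   `fitted_values`.
#' @export
#' @examples
#' curve <- generate_growth_curve(synthetic_spec(noise_sd = 0, seed = 1))
#' fit_primary(curve)
fit_primary <- function(data, d_p = 0.0717, V_p0 = 0.1, K_p0 = 200,
                        lower = c(a_p = 1e-3, b_p = 0.1),
                        upper = c(a_p = 10, b_p = 100), starts = 5) {
  data <- validate_growth_curve(data)
  if (max(abs(data$volume - mean(data$volume))) <
        1e-8 * max(data$volume)) {
    return(new_fit(par = c(a_p = NA_real_, b_p = NA_real_), rss = NA_real_,
                   converged = FALSE, identifiable = FALSE,
                   message = "constant volumes: 'a_p' is unidentifiable (log(K/V) = 0 trajectory)"))
  }
  times <- data$time
  grid <- if (times[1] > 0) c(0, times) else times
  keep <- if (times[1] > 0) -1L else TRUE

  model_vols <- function(par) {
    sol <- try(solve_primary(grid, V0 = V_p0, K0 = K_p0,
                             a = par[1], b = par[2], d = d_p),
               silent = TRUE)
    if (inherits(sol, "try-error")) return(rep(1e6, length(times)))
    sol$V[keep]
  }
  resid_fun <- function(par) model_vols(par) - data$volume

  start_a <- 10^seq(log10(0.02), log10(1), length.out = starts)
  start_b <- 10^seq(log10(1), log10(60), length.out = starts)
  best <- NULL
  for (s in seq_len(starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = c(start_a[s], start_b[s]), lower = unname(lower),
      upper = unname(upper), fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(new_fit(par = c(a_p = NA_real_, b_p = NA_real_), rss = NA_real_,
                   converged = FALSE, identifiable = TRUE,
                   message = "optimizer failed from every start"))
  par <- setNames(coef(best), c("a_p", "b_p"))
  fitted <- model_vols(par)
  new_fit(par = par, rss = best$deviance,
          r2 = r_squared(fitted, data$volume),
          converged = best$info %in% 1:3, bounds = list(lower = lower,
                                                        upper = upper),
          fitted_values = fitted)
}

validate_growth_curve <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("time", "volume") %in% names(data)))
    stop("growth-curve data need columns 'time' and 'volume'",
         call. = FALSE)
  if (nrow(data) < 2L) stop("need at least 2 data points", call. = FALSE)
  if (any(diff(data$time) <= 0))
    stop("'time' must be strictly increasing", call. = FALSE)
  if (any(data$volume <= 0)) stop("volumes must be positive", call. = FALSE)
  data
}

#' Fit metastatic parameters to endpoint summaries
#'
#' Second stage of the calibration: with the growth parameters of the
#' primary fixed (and the metastatic proliferation rate `a` set equal to
#' the fitted `a_p`, differences in growth being attributed to the
#' microenvironment via `b`), estimate the metastatic stimulation `b` and
#' the colonization coefficient `m` from two endpoint observables: the
#' number of metastases above the visibility threshold and their mean
#' size at the end time. Two free parameters for two observables; the fit
#' minimizes the 2-vector of relative residuals with the same
#' trust-region algorithm and deterministic multi-starts as
#' [fit_primary()]. The model is simulated with systemic inhibition off,
#' matching the regime of the data.
#'
#' @param count observed number of visible metastases at `end_time`.
#' @param mean_size observed mean volume of visible metastases (mm^3).
#' @param pars parameter set supplying everything but `b` and `m`
#'   (including the already-fitted `a_p`, `b_p`, and `a`).
#' @param end_time endpoint (days).
#' @param visible_volume visibility threshold (mm^3).
#' @param V_p0,K_p0 initial primary state of the emulated experiment.
#' @param dt simulator step used inside the objective (days).
#' @param lower,upper bounds on `(b, m)`.
#' @param starts number of deterministic log-spaced starting points.
#' @return An `"sia_fit"` with `par` (named `b`, `m`), `rss` (sum of
#'   squared relative residuals), predicted observables in
#'   `fitted_values`, and convergence flags.
#' @export
fit_metastatic <- function(count, mean_size, pars = default_parameters(),
                           end_time = 32, visible_volume = 1e-5,
                           V_p0 = 0.1, K_p0 = 200, dt = 0.1,
                           lower = c(b = 0.1, m = 1e-4),
                           upper = c(b = 100, m = 10), starts = 5) {
  if (count < 0) stop("'count' must be >= 0", call. = FALSE)
  if (mean_size <= 0) stop("'mean_size' must be > 0", call. = FALSE)

  predict_endpoints <- function(b, m) {
    pp <- unclass(pars)
    pp$b <- b
    pp$m <- m
    pp <- validate_parameters(pp)
    traj <- simulate_system(pp, V_p0 = V_p0, K_p0 = K_p0, T = end_time,
                            dt = dt, sia = FALSE,
                            visible_volume = visible_volume)
    nvis <- count_visible(traj, visible_volume)
    M <- tail(traj$M, 1)
    c(count = nvis, mean_size = if (nvis > 0) M / nvis else 0)
  }
  resid_fun <- function(par) {
    pred <- try(predict_endpoints(par[1], par[2]), silent = TRUE)
    if (inherits(pred, "try-error")) return(c(1e6, 1e6))
    c(pred[["count"]] / count - 1, pred[["mean_size"]] / mean_size - 1)
  }

  start_b <- 10^seq(log10(1), log10(60), length.out = starts)
  start_m <- 10^seq(-3, -0.5, length.out = starts)
  best <- NULL
  for (s in seq_len(starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = c(start_b[s], start_m[s]), lower = unname(lower),
      upper = unname(upper), fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (!is.null(best) && best$deviance < 1e-16) break
  }
  if (is.null(best))
    return(new_fit(par = c(b = NA_real_, m = NA_real_), rss = NA_real_,
                   converged = FALSE, identifiable = TRUE,
                   message = "optimizer failed from every start"))
  par <- setNames(coef(best), c("b", "m"))
  new_fit(par = par, rss = best$deviance,
          converged = best$info %in% 1:3,
          bounds = list(lower = lower, upper = upper),
          fitted_values = predict_endpoints(par[["b"]], par[["m"]]))
}
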
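#' Solve the primary-tumor growth ODE
#'
#' Integrates the two-variable lesion model for a single (primary) tumor
#' with an adaptive high-accuracy ODE method (`deSolve::lsoda`). The
#' inhibitor amount may be a constant (default 0, i.e. systemic inhibition
#' off, the regime in which calibration is performed) or a function of
#' time.
#'
#' @param times strictly increasing output times (days); the integration
#'   starts at `times[1]`.
#' @param V0,K0 initial volume and carrying capacity (mm^3).
#' @param a,b,d growth parameters (see [volume_rate()], [capacity_rate()]).
#' @param e inhibitor efficacy (mg^-1 day^-1).
#' @param I inhibitor amount: a single number or a function of time
#'   returning mg.
#' @param floor_V lower clamp on volume, one cell by default (mm^3).
#' @return A data.frame with columns `time`, `V`, `K`.
#' @export
#' @examples
#' pars <- default_parameters()
#' solve_primary(c(0, 10, 32), V0 = 0.1, K0 = 200,
#'               a = pars$a_p, b = pars$b_p, d = pars$d_p)
solve_primary <- function(times, V0, K0, a, b, d, e = 0, I = 0,
                          floor_V = 1e-6) {
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be strictly increasing with length >= 2",
         call. = FALSE)
  if (V0 <= 0 || K0 <= 0) stop("initial V0, K0 must be > 0", call. = FALSE)
  I_fun <- if (is.function(I)) I else function(t) I
  deriv <- function(t, y, parms) {
    V <- max(y[1], floor_V)
    K <- max(y[2], 1e-300)
    It <- I_fun(t)
    dV <- a * V * log(K / V)
    dK <- b * V - (d * V^(2 / 3) + e * It) * K
    list(c(dV, dK))
  }
  sol <- deSolve::lsoda(c(V = V0, K = K0), times, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-12)
  out <- as.data.frame(sol)
  names(out) <- c("time", "V", "K")
  out$V <- pmax(out$V, floor_V)
  out
}
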
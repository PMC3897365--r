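#' Lesion-level rate laws
#'
#' The instantaneous rates of change of a lesion's volume and carrying
#' capacity, and the dissemination and inhibitor balance laws. These pure
#' functions are shared by the cohort simulator and the independent
#' renewal-equation solver, so the two numerical routes differ only in
#' discretization, never in model content. All are vectorized over states.
#'
#' `volume_rate` is Gompertz growth toward the current carrying capacity:
#' `a * V * log(K / V)`. `capacity_rate` balances angiogenic stimulation
#' `b * V` against local inhibition `d * V^(2/3) * K` and systemic
#' inhibition `e * I * K`, where `I` is the circulating inhibitor amount.
#'
#' @param V,K lesion volume and carrying capacity (mm^3).
#' @param a proliferation rate (day^-1).
#' @param b angiogenic stimulation coefficient (day^-1).
#' @param d local angiogenic inhibition coefficient (mm^-2 day^-1).
#' @param e inhibitor efficacy (mg^-1 day^-1).
#' @param I circulating inhibitor amount (mg).
#' @return Rate in mm^3/day.
#' @export
#' @examples
#' volume_rate(100, 200, a = 0.154) # 0.154 * 100 * log(2)
#' capacity_rate(1, 1, b = 12.5, d = 0.0717) # stimulation-dominated
volume_rate <- function(V, K, a) {
  if (any(V <= 0) || any(K <= 0))
    stop("volume_rate requires V > 0 and K > 0", call. = FALSE)
  if (a <= 0) stop("proliferation rate 'a' must be > 0", call. = FALSE)
  a * V * log(K / V)
}

#' @rdname volume_rate
#' @export
capacity_rate <- function(V, K, b, d, e = 0, I = 0) {
  if (any(V < 0) || any(K < 0) || any(I < 0))
    stop("capacity_rate requires V, K, I >= 0", call. = FALSE)
  if (b < 0 || d < 0 || e < 0)
    stop("capacity_rate requires b, d, e >= 0", call. = FALSE)
  b * V - (d * V^(2 / 3) + e * I) * K
}

#' Metastatic emission rate
#'
#' Per-lesion rate of successful dissemination, `beta(V) = m * V^alpha` for
#' `V >= Vm` and 0 below the threshold. `Vm` is the volume of the
#' angiogenic switch (~1 mm^3): pre-angiogenic lesions have no access to
#' the circulation and do not spread.
#'
#' @param V lesion volume (mm^3), vectorized.
#' @param m colonization coefficient (mm^-3alpha day^-1).
#' @param alpha fractal exponent in `[0, 1]`.
#' @param Vm emission threshold volume (mm^3).
#' @return Emission rate in metastases/day.
#' @export
#' @examples
#' emission_rate(200, m = 0.0229, alpha = 2 / 3) # ~0.78 per day
emission_rate <- function(V, m, alpha, Vm = 1) {
  if (any(V < 0)) stop("emission_rate requires V >= 0", call. = FALSE)
  if (m < 0) stop("'m' must be >= 0", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]",
                                   call. = FALSE)
  ifelse(V >= Vm, m * V^alpha, 0)
}

#' Inhibitor balance
#'
#' Rate of change of the total circulating inhibitor amount `I` (mg):
#' production `p` per unit of total tumor volume (primary plus the whole
#' metastatic burden) minus first-order elimination `k * I`. The steady
#' state at frozen total volume is `p * total_volume / k`.
#'
#' @param I circulating inhibitor amount (mg).
#' @param total_volume total tumor volume, primary + metastases (mm^3).
#' @param p production rate (mg mm^-3 day^-1).
#' @param k elimination rate (day^-1).
#' @return Rate in mg/day.
#' @export
#' @examples
#' inhibitor_rate(0, 1500, p = 8.3e-6, k = 0.38)
inhibitor_rate <- function(I, total_volume, p, k) {
  if (any(I < 0) || any(total_volume < 0))
    stop("inhibitor_rate requires I >= 0 and total_volume >= 0",
         call. = FALSE)
  if (p < 0 || k <= 0)
    stop("inhibitor_rate requires p >= 0 and k > 0", call. = FALSE)
  p * total_volume - k * I
}
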
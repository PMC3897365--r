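#' Local inhibition coefficient from the intra-tumor diffusion analysis
#'
#' The local term `d * V^(2/3) * K` of the carrying-capacity law follows
#' from a quasi-steady diffusion analysis inside a spherical lesion of
#' radius `R`. With uniform volumetric production `p`, negligible
#' intra-tumor clearance and surface concentration equal to the systemic
#' level `i`, the internal concentration solves
#' `D2 * (1/r^2) d/dr(r^2 dn/dr) = -p` with `n(R) = i`, giving
#' `n(r) = i + p (R^2 - r^2) / (6 D2)`. The volume-mean excess over the
#' systemic level is `p R^2 / (15 D2)`; substituting
#' `R^2 = (3 V / (4 pi))^(2/3)` and weighting by the systemic efficacy
#' `e * Vd` (the efficacy acts on amount = concentration x distribution
#' volume) yields the coefficient of `V^(2/3) * K`:
#'
#' `d = e * Vd * p * (3 / (4 pi))^(2/3) / (15 * D2)`
#'
#' With the canonical angiostatin values (e = 7.5, Vd = 7000, p = 8.3e-6,
#' D2 = 0.156) this evaluates to ~0.0717 mm^-2 day^-1. The coefficient is
#' linear in each of `e`, `Vd` and `p` and inversely proportional to `D2`,
#' so a higher inhibitor production rate proportionally raises local
#' inhibition as well.
#'
#' @param e inhibitor efficacy (mg^-1 day^-1).
#' @param Vd distribution volume (mm^3).
#' @param p inhibitor production rate (mg mm^-3 day^-1).
#' @param D2 inhibitor diffusion coefficient (mm^2 day^-1).
#' @return `d` in mm^-2 day^-1.
#' @export
#' @examples
#' derive_local_inhibition(e = 7.5, Vd = 7000, p = 8.3e-6, D2 = 0.156)
derive_local_inhibition <- function(e, Vd, p, D2) {
  if (e < 0 || Vd <= 0 || p < 0)
    stop("require e >= 0, Vd > 0, p >= 0", call. = FALSE)
  if (D2 <= 0) stop("diffusion coefficient 'D2' must be > 0", call. = FALSE)
  e * Vd * p * (3 / (4 * pi))^(2 / 3) / (15 * D2)
}

#' Inhibitor production rate from an equivalent daily dose
#'
#' A daily injection of `daily_dose` mg of inhibitor that reproduces the
#' systemic inhibition exerted by a tumor of `reference_volume` mm^3
#' implies a per-volume production rate `p = daily_dose / reference_volume`.
#' The canonical value comes from 12.5 ug/day of recombinant angiostatin
#' standing in for a 1500 mm^3 primary.
#'
#' @param daily_dose mg/day.
#' @param reference_volume mm^3.
#' @return `p` in mg mm^-3 day^-1.
#' @export
#' @examples
#' derive_production_rate(0.0125, 1500) # ~8.3e-6
derive_production_rate <- function(daily_dose, reference_volume) {
  if (daily_dose < 0) stop("'daily_dose' must be >= 0", call. = FALSE)
  if (reference_volume <= 0)
    stop("'reference_volume' must be > 0", call. = FALSE)
  daily_dose / reference_volume
}

#' Half-life of the circulating inhibitor
#'
#' First-order elimination at rate `k` gives half-life `log(2) / k`;
#' k = 0.38/day corresponds to ~1.8 days (angiostatin).
#'
#' @param k elimination rate (day^-1).
#' @return Half-life in days.
#' @export
#' @examples
#' half_life_from_k(0.38)
half_life_from_k <- function(k) {
  if (k <= 0) stop("elimination rate 'k' must be > 0", call. = FALSE)
  log(2) / k
}

#' Sphere diameter/volume conversions
#'
#' Experimental metastasis sizes are often reported as diameters;
#' `diameter_to_volume()` applies `V = (pi/6) diam^3` and
#' `volume_to_diameter()` inverts it.
#'
#' @param diameter diameter (mm).
#' @param volume volume (mm^3).
#' @return Volume (mm^3) or diameter (mm).
#' @export
#' @examples
#' diameter_to_volume(1.41) # ~1.47 mm^3
#' volume_to_diameter(diameter_to_volume(2)) # 2
diameter_to_volume <- function(diameter) {
  if (any(diameter < 0)) stop("'diameter' must be >= 0", call. = FALSE)
  pi / 6 * diameter^3
}

#' @rdname diameter_to_volume
#' @export
volume_to_diameter <- function(volume) {
  if (any(volume < 0)) stop("'volume' must be >= 0", call. = FALSE)
  (6 * volume / pi)^(1 / 3)
}
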
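#' Molecular radius from the liquid molar volume
#'
#' Returns the stored molecular radius when the record carries one; otherwise
#' estimates the sphere-equivalent radius from the liquid molar volume,
#' \deqn{r = \left(\frac{3\,(MW/1000)}{4\pi\,\rho\,N_A}\right)^{1/3},}
#' which uses only fields a chemical record already requires (molar mass and
#' liquid density).
#'
#' @param chem A chemical record (one-row tibble, see [chemical()]), or a
#'   panel of several; the function is vectorised over rows.
#' @return Radius in m (one value per row of `chem`).
#' @export
#' @examples
#' molecular_radius(chemical("water", mw = 18.015, density = 1000))
molecular_radius <- function(chem) {
  chem <- validate_chemicals(chem)
  est <- (3 * (chem$mw / 1000) / (4 * pi * chem$density * .NA_CONST))^(1 / 3)
  ifelse(is.finite(chem$radius_m), chem$radius_m, est)
}

#' Gas-phase diffusivity by the Stokes--Einstein equation
#'
#' \deqn{D_{evap} = \frac{k_B T}{6 \pi \eta r}}
#' with \eqn{\eta} the dynamic viscosity of air and \eqn{r} the molecular
#' radius. A per-chemical `d_evap_m2_s` value in the record overrides the
#' estimate (Stokes--Einstein is a hydrodynamic continuum model; for gas-phase
#' diffusion it can sit well below tabulated binary diffusivities, so an
#' override path is first-class).
#'
#' @param chem Chemical record(s); vectorised over rows.
#' @param env A [ivpt_environment()].
#' @return Diffusivity in m^2/s, one value per row.
#' @export
#' @examples
#' env <- ivpt_environment()
#' air_diffusivity(chemical("x", mw = 117, density = 980), env)
air_diffusivity <- function(chem, env) {
  chem <- validate_chemicals(chem)
  r <- molecular_radius(chem)
  if (any(!is.finite(r) | r <= 0)) {
    stop_pbpke("pbpke_invalid_chemical", "molecular radius must be positive")
  }
  d <- .KB * env$temperature_k / (6 * pi * env$air_viscosity * r)
  ifelse(is.finite(chem$d_evap_m2_s), chem$d_evap_m2_s, d)
}

#' Legacy evaporative mass-transfer coefficient (wind-speed model)
#'
#' The empirical liquid-spill mass-transfer coefficient used by the previous
#' generation of unoccluded dermal models:
#' \deqn{K_{evap} = \frac{1.756\times 10^{-5}\, P\, MW^{2/3}\, u^{0.78}}{R\,T}}
#' with `P` in Pa, `MW` in Da, `u` the wind speed in m/s, yielding m/s. Kept
#' as a selectable mode so wind-speed-driven predictions remain reproducible;
#' the mechanistic vapour-pressure mode is the package default.
#'
#' @param chem Chemical record(s); vectorised over rows.
#' @param env A [ivpt_environment()]; uses `wind_speed` and `temperature_k`.
#' @return K_evap in m/s, one value per row. Zero when `u = 0` or `P = 0`.
#' @export
#' @examples
#' env <- ivpt_environment(wind_speed = 0.2)
#' legacy_kevap(table1_chemicals()[1, ], env)
legacy_kevap <- function(chem, env) {
  chem <- validate_chemicals(chem)
  1.756e-5 * chem$vapour_pressure_pa * chem$mw^(2 / 3) *
    env$wind_speed^0.78 / (.R * env$temperature_k)
}
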
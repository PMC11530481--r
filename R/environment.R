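#' Construct the donor-chamber environment
#'
#' The environment collects everything about the air side of the diffusion
#' cell: temperature, relative humidity, the donor-chamber height `h` (the
#' distance from the vehicle surface to the top of the donor chamber wall,
#' across which the gas-phase concentration gradient is established), air
#' viscosity for the Stokes--Einstein diffusivity, and the wind speed used
#' only by the legacy evaporation mode.
#'
#' @param temperature_k Temperature, K (> 0). Default 305.15 K (32 degC skin
#'   surface).
#' @param relative_humidity Fraction in \[0, 1\]. Default 0.5.
#' @param donor_height_m Donor chamber height `h`, m (> 0). Default 0.01.
#' @param air_viscosity Dynamic viscosity of air, Pa s. Default 1.89e-5
#'   (air near 32 degC).
#' @param wind_speed Wind speed `u`, m/s (>= 0); used only by the legacy
#'   wind-speed evaporation mode. Default 0.2 (indoor free convection).
#' @param ambient_concentrations Named numeric vector of ambient gas-phase
#'   concentrations M_a, mol/m^3, per chemical name. Chemicals not named get
#'   0 (ambient assumed free of the vehicle's ingredients); water's ambient
#'   concentration is derived from humidity via
#'   [water_ambient_concentration()] unless explicitly named here.
#'
#' @return An object of class `"pbpke_environment"` (a named list).
#' @export
#' @examples
#' ivpt_environment(temperature_k = 305.15, relative_humidity = 0.5)
ivpt_environment <- function(temperature_k = 305.15,
                             relative_humidity = 0.5,
                             donor_height_m = 0.01,
                             air_viscosity = 1.89e-5,
                             wind_speed = 0.2,
                             ambient_concentrations = NULL) {
  stopifnot(is.numeric(temperature_k), length(temperature_k) == 1)
  if (temperature_k <= 0) stop_pbpke("pbpke_invalid_environment", "temperature must be > 0 K")
  if (donor_height_m <= 0) stop_pbpke("pbpke_invalid_environment", "donor height must be > 0 m")
  if (air_viscosity <= 0) stop_pbpke("pbpke_invalid_environment", "air viscosity must be > 0")
  if (relative_humidity < 0 || relative_humidity > 1) {
    stop_pbpke("pbpke_invalid_environment", "relative humidity must lie in [0, 1]")
  }
  if (wind_speed < 0) stop_pbpke("pbpke_invalid_environment", "wind speed must be >= 0")
  structure(list(
    temperature_k = temperature_k,
    relative_humidity = relative_humidity,
    donor_height_m = donor_height_m,
    air_viscosity = air_viscosity,
    wind_speed = wind_speed,
    ambient_concentrations = ambient_concentrations %||% numeric(0)
  ), class = "pbpke_environment")
}

#' @export
print.pbpke_environment <- function(x, ...) {
  cat(sprintf(
    "<pbpke_environment> T = %.2f K, RH = %.0f%%, h = %.3g m, eta = %.3g Pa s, u = %.2g m/s\n",
    x$temperature_k, 100 * x$relative_humidity, x$donor_height_m,
    x$air_viscosity, x$wind_speed))
  invisible(x)
}

#' Saturation vapour pressure of water
#'
#' Antoine equation with the standard 1--100 degC coefficients
#' (A = 8.07131, B = 1730.63, C = 233.426; P in mmHg, temperature in degC),
#' converted to Pa. Used to supply water's saturation pressure wherever a
#' scenario does not provide one.
#'
#' @param temperature_k Temperature, K.
#' @return Saturation pressure, Pa.
#' @export
#' @examples
#' water_saturation_pressure(305.15) # ~4750 Pa at 32 degC
water_saturation_pressure <- function(temperature_k) {
  t_c <- temperature_k - 273.15
  p_mmhg <- 10^(8.07131 - 1730.63 / (233.426 + t_c))
  p_mmhg * 133.322387415
}

#' Ambient gas-phase concentration of water from humidity
#'
#' The only vehicle ingredient assumed present in the ambient air is water,
#' whose partial pressure follows from relative humidity and the ideal gas
#' law: M_a = RH * P_sat / (R T). All other chemicals default to M_a = 0.
#'
#' @param env A [ivpt_environment()].
#' @param p_sat_water Saturation pressure of water at the environment
#'   temperature, Pa. Defaults to the Antoine estimate.
#' @return Ambient molar concentration, mol/m^3.
#' @export
#' @examples
#' env <- ivpt_environment(relative_humidity = 0.5)
#' water_ambient_concentration(env)
water_ambient_concentration <- function(env,
                                        p_sat_water = water_saturation_pressure(env$temperature_k)) {
  if (p_sat_water < 0) {
    stop_pbpke("pbpke_invalid_input", "saturation pressure must be >= 0")
  }
  env$relative_humidity * p_sat_water / (.R * env$temperature_k)
}

#' Ambient concentration lookup for any chemical
#'
#' @param env A [ivpt_environment()].
#' @param chem One-row chemical tibble.
#' @return M_a in mol/m^3: an explicit per-chemical override if present in
#'   `env$ambient_concentrations`, the humidity-derived value for water, else 0.
#' @export
ambient_concentration <- function(env, chem) {
  nm <- chem$name[[1]]
  if (nm %in% names(env$ambient_concentrations)) {
    return(unname(env$ambient_concentrations[[nm]]))
  }
  if (isTRUE(chem$is_water[[1]])) return(water_ambient_concentration(env))
  0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
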
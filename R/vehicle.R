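#' Construct a multi-component vehicle state
#'
#' A vehicle is a thin, well-mixed liquid film of one or more components
#' (solvent(s) plus permeant(s)), each with a current mass. The volume follows
#' from ideal-solution additivity, \eqn{V = \sum_i m_i/\rho_i}; concentrations
#' are \eqn{C_i = m_i/V}; mole fractions from the molar inventory. Activity
#' coefficients default to 1 (ideal liquid).
#'
#' @param components Chemical panel tibble (one row per component).
#' @param masses Numeric vector of component masses, kg (same order as the
#'   rows of `components`). All must be >= 0.
#' @param activity Activity coefficients a_l, recycled to the number of
#'   components. Default 1 (ideal solution).
#' @return An object of class `"pbpke_vehicle"`: the component tibble with
#'   `mass`, `a_l` columns and a `volume` attribute-style field.
#' @export
#' @examples
#' v <- vehicle_state(dplyr::bind_rows(solvent_record("water"),
#'                                     table1_chemicals()[1, ]),
#'                    masses = c(9.9e-6, 1e-7))
#' vehicle_volume(v)
vehicle_state <- function(components, masses, activity = 1) {
  components <- validate_chemicals(components)
  if (length(masses) != nrow(components)) {
    stop_pbpke("pbpke_invalid_vehicle", "one mass per component required")
  }
  if (any(masses < 0)) {
    stop_pbpke("pbpke_invalid_vehicle", "component masses must be >= 0")
  }
  components$mass <- as.numeric(masses)
  components$a_l <- rep_len(as.numeric(activity), nrow(components))
  structure(list(components = components), class = "pbpke_vehicle")
}

#' @rdname vehicle_state
#' @param state A `pbpke_vehicle`.
#' @export
vehicle_volume <- function(state) {
  sum(state$components$mass / state$components$density)
}

#' Component concentrations in the vehicle
#'
#' @param state A `pbpke_vehicle`.
#' @param volume Optional volume override (m^3), e.g. the frozen residue-film
#'   volume after dry-down; defaults to the ideal-solution volume.
#' @return Named numeric vector of concentrations, kg/m^3.
#' @export
vehicle_concentrations <- function(state, volume = vehicle_volume(state)) {
  stats::setNames(state$components$mass / volume, state$components$name)
}

#' Mole fractions of the vehicle components
#'
#' \eqn{x_i = n_i / \sum_j n_j} with \eqn{n_i = m_i/(MW_i/1000)}. Components
#' with zero mass get exactly 0; a fully depleted vehicle (all masses zero)
#' has no defined composition and signals an empty-vehicle condition.
#'
#' @param state A `pbpke_vehicle`.
#' @return Named numeric vector of mole fractions summing to 1.
#' @export
#' @examples
#' v <- vehicle_state(dplyr::bind_rows(solvent_record("water"),
#'                                     solvent_record("ethanol")),
#'                    masses = c(0.18015, 0.04606))
#' mole_fractions(v) # 10 mol water : 1 mol ethanol
mole_fractions <- function(state) {
  comp <- state$components
  n <- comp$mass / (comp$mw / 1000)
  total <- sum(n)
  if (total <= 0) {
    stop_pbpke("pbpke_empty_vehicle",
               "vehicle fully depleted: mole fractions undefined")
  }
  stats::setNames(n / total, comp$name)
}

#' Surface gas-phase concentration above the vehicle
#'
#' Raoult's law plus the ideal gas law: the equilibrium gas concentration of
#' component i at the vehicle--air interface is
#' \deqn{M_s = \frac{P_i\, x_i\, a_i}{R\,T}.}
#'
#' @param state A `pbpke_vehicle`.
#' @param env A [ivpt_environment()].
#' @param component Optional component name; when given, returns that single
#'   value, erroring if the component is not in the vehicle.
#' @return Named vector of M_s, mol/m^3 (or a single value).
#' @export
#' @examples
#' v <- vehicle_state(table1_chemicals()[2, ], masses = 1e-6) # pure acetophenone
#' surface_gas_concentration(v, ivpt_environment())
surface_gas_concentration <- function(state, env, component = NULL) {
  comp <- state$components
  x <- mole_fractions(state)
  m_s <- comp$vapour_pressure_pa * x * comp$a_l / (.R * env$temperature_k)
  names(m_s) <- comp$name
  if (!is.null(component)) {
    if (!component %in% comp$name) {
      stop_pbpke("pbpke_unknown_component",
                 "component not in vehicle: ", component)
    }
    return(m_s[[component]])
  }
  m_s
}

#' Evaporative flux of every vehicle component
#'
#' The core evaporation step. In `mechanistic` mode the flux is Fickian
#' diffusion across the donor-chamber headspace,
#' \deqn{J_{evap} = D_{evap}\,(M_s - M_a)/h,}
#' stored as a positive outward magnitude (the vehicle mass-balance equations
#' subtract it). In `legacy` mode the gradient is multiplied by the empirical
#' wind-speed coefficient of [legacy_kevap()] instead. `occluded` forces all
#' fluxes to zero (covered donor chamber; this is also the plain no-evaporation
#' PBPK pathway). Net condensation (ambient exceeding surface concentration)
#' is clamped to zero except optionally for water under humid ambient.
#'
#' @param state A `pbpke_vehicle`.
#' @param env A [ivpt_environment()].
#' @param mode `"mechanistic"` (default), `"legacy"` or `"occluded"`.
#' @param allow_water_condensation Logical; when `TRUE` water may take a
#'   negative flux (condensation from humid ambient). Default `FALSE`.
#' @return A flux-record tibble with columns `component`, `d_evap`, `m_s`,
#'   `m_a`, `j_molar` (mol m^-2 s^-1), `j_mass` (kg m^-2 s^-1) and
#'   `k_evap_legacy` (m/s; `NA` outside legacy mode).
#' @export
#' @examples
#' v <- vehicle_state(table1_chemicals()[2, ], masses = 1e-6)
#' evaporative_flux(v, ivpt_environment())
evaporative_flux <- function(state, env,
                             mode = c("mechanistic", "legacy", "occluded"),
                             allow_water_condensation = FALSE) {
  mode <- match.arg(mode)
  comp <- state$components
  if (mode == "mechanistic" && env$donor_height_m <= 0) {
    stop_pbpke("pbpke_invalid_geometry", "donor height must be > 0")
  }
  m_s <- unname(surface_gas_concentration(state, env))
  m_a <- vapply(seq_len(nrow(comp)), function(i) {
    ambient_concentration(env, comp[i, ])
  }, numeric(1))
  d_evap <- air_diffusivity(comp, env)
  k_leg <- rep(NA_real_, nrow(comp))
  j_molar <- switch(mode,
    mechanistic = d_evap * (m_s - m_a) / env$donor_height_m,
    legacy = {
      k_leg <- legacy_kevap(comp, env)
      k_leg * (m_s - m_a)
    },
    occluded = rep(0, nrow(comp))
  )
  # condensation floor: the model describes loss; only water may run backwards
  clamp <- j_molar < 0 & !(comp$is_water & allow_water_condensation)
  j_molar[clamp] <- 0
  # dried-down components no longer evaporate
  j_molar[comp$mass <= .MASS_FLOOR] <- 0
  tibble::tibble(
    component = comp$name,
    d_evap = d_evap,
    m_s = m_s,
    m_a = m_a,
    j_molar = j_molar,
    j_mass = j_molar * comp$mw / 1000,
    k_evap_legacy = k_leg
  )
}

#' Rate of change of vehicle volume under evaporation
#'
#' Ideal-solution volume balance: \eqn{dV/dt = -\sum_i J_{mass,i} A / \rho_i}.
#' Volume loss to skin permeation is neglected (dilute permeant).
#'
#' @param state A `pbpke_vehicle`.
#' @param fluxes Flux-record tibble from [evaporative_flux()].
#' @param area Application area A, m^2.
#' @return dV/dt in m^3/s (<= 0 under pure evaporation).
#' @export
vehicle_volume_rate <- function(state, fluxes, area) {
  comp <- state$components
  rho <- stats::setNames(comp$density, comp$name)
  -sum(fluxes$j_mass * area / rho[fluxes$component])
}

#' Vehicle concentration/volume derivatives (analytic form)
#'
#' The product-rule expansion of the vehicle mass balance
#' \eqn{d(VC_i)/dt = -J_{evap,i}A - J_{skin,i}A} gives
#' \deqn{V\frac{dC_i}{dt} = -J_{evap,i}A + C_i \sum_k \frac{J_{evap,k}A}{\rho_k}
#'       - J_{skin,i}A.}
#' This closed form is exposed for analysis and testing; the integrator itself
#' advances component masses (the mathematically equivalent conservative
#' form), from which `C` and `V` are derived exactly.
#'
#' @param state A `pbpke_vehicle` with positive volume.
#' @param fluxes Flux-record tibble from [evaporative_flux()].
#' @param j_skin Named vector of skin-permeation mass fluxes (kg m^-2 s^-1,
#'   positive into the skin) per component; unnamed components get 0.
#' @param area Application area, m^2.
#' @return A list with `dC_dt` (named, kg m^-3 s^-1) and `dV_dt` (m^3/s).
#' @export
#' @examples
#' v <- vehicle_state(table1_chemicals()[2, ], masses = 1e-6)
#' f <- evaporative_flux(v, ivpt_environment())
#' vehicle_rhs(v, f, j_skin = 0, area = 1e-4)  # pure component: dC/dt = 0
vehicle_rhs <- function(state, fluxes, j_skin = 0, area) {
  comp <- state$components
  v <- vehicle_volume(state)
  if (v <= 0) {
    stop_pbpke("pbpke_depleted_vehicle", "vehicle volume is zero")
  }
  conc <- vehicle_concentrations(state)
  js <- rep(0, nrow(comp))
  names(js) <- comp$name
  if (!is.null(names(j_skin)) && length(j_skin) > 0) {
    js[names(j_skin)] <- j_skin
  } else if (length(j_skin) == 1) {
    js[] <- j_skin
  }
  shrink <- sum(fluxes$j_mass * area / comp$density)
  dc <- (-fluxes$j_mass * area + conc[comp$name] * shrink - js * area) / v
  list(dC_dt = stats::setNames(dc, comp$name),
       dV_dt = vehicle_volume_rate(state, fluxes, area))
}
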
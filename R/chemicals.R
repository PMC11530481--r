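#' Construct a chemical record
#'
#' A chemical is an immutable physicochemical record held as a one-row tibble,
#' so panels of chemicals are ordinary data frames that pipe through dplyr.
#' Vapour pressure is taken at the scenario temperature (no temperature
#' dependence is modelled).
#'
#' @param name Chemical name (character).
#' @param mw Molar mass, g/mol. Must be positive.
#' @param log_kow Base-10 octanol--water partition coefficient (dimensionless).
#' @param vapour_pressure_pa Vapour pressure of the pure liquid, Pa (>= 0).
#' @param density Liquid density, kg/m^3. Must be positive.
#' @param cas CAS registry number (character, optional).
#' @param radius_m Molecular radius, m. Optional; estimated from the liquid
#'   molar volume by [molecular_radius()] when absent.
#' @param solubility Saturation concentration in the vehicle, kg/m^3
#'   (optional; used only to emit supersaturation warnings during dry-down).
#' @param is_water Logical; water receives special ambient-humidity treatment
#'   in the evaporation model.
#' @param d_evap_m2_s Optional override for the gas-phase diffusivity, m^2/s.
#'   When `NA` the Stokes--Einstein estimate of [air_diffusivity()] is used.
#' @param vehicle Optional annotation of the vehicle the chemical was dosed in
#'   (e.g. `"PBS"`, `"Ethanol"`); informational only.
#'
#' @return A one-row tibble with the columns above.
#' @export
#' @examples
#' chemical("4-Tolunitrile", mw = 117.15, log_kow = 1.58,
#'          vapour_pressure_pa = 41.72, density = 978)
chemical <- function(name, mw, log_kow = NA_real_, vapour_pressure_pa = 0,
                     density, cas = NA_character_, radius_m = NA_real_,
                     solubility = NA_real_, is_water = FALSE,
                     d_evap_m2_s = NA_real_, vehicle = NA_character_) {
  chem <- tibble::tibble(
    name = as.character(name), cas = as.character(cas),
    mw = as.numeric(mw), log_kow = as.numeric(log_kow),
    vapour_pressure_pa = as.numeric(vapour_pressure_pa),
    density = as.numeric(density), radius_m = as.numeric(radius_m),
    solubility = as.numeric(solubility), is_water = as.logical(is_water),
    d_evap_m2_s = as.numeric(d_evap_m2_s), vehicle = as.character(vehicle)
  )
  validate_chemicals(chem)
}

#' Validate a panel of chemical records
#'
#' Checks the physical invariants of a chemical panel: positive molar mass and
#' density, non-negative vapour pressure, positive radius where given.
#'
#' @param panel A data frame of chemical records as built by [chemical()] or
#'   [table1_chemicals()].
#' @return The panel as a tibble, invisibly unchanged, if valid; otherwise an
#'   error of class `"pbpke_invalid_chemical"`.
#' @export
validate_chemicals <- function(panel) {
  panel <- tibble::as_tibble(panel)
  required <- c("name", "mw", "vapour_pressure_pa", "density")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop_pbpke("pbpke_invalid_chemical",
               "chemical panel is missing columns: ",
               paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(c("log_kow", "radius_m", "solubility", "d_evap_m2_s"),
                      names(panel))) {
    panel[[col]] <- NA_real_
  }
  if (!"is_water" %in% names(panel)) panel$is_water <- FALSE
  if (!"cas" %in% names(panel)) panel$cas <- NA_character_
  if (!"vehicle" %in% names(panel)) panel$vehicle <- NA_character_
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      stop_pbpke("pbpke_invalid_chemical", what, ": ",
                 paste(panel$name[which(cond)], collapse = ", "))
    }
  }
  bad(!is.finite(panel$mw) | panel$mw <= 0, "non-positive molar mass")
  bad(!is.finite(panel$density) | panel$density <= 0, "non-positive density")
  bad(is.finite(panel$vapour_pressure_pa) & panel$vapour_pressure_pa < 0,
      "negative vapour pressure")
  bad(is.finite(panel$radius_m) & panel$radius_m <= 0,
      "non-positive molecular radius")
  panel
}

#' The 23-chemical volatile reference panel
#'
#' The finite-dose IVPT reference panel of 23 volatile permeants (21 distinct
#' chemicals; benzophenone and geraniol appear once per application vehicle),
#' with molar mass, log Kow and vapour pressure at the standard 32 degC skin
#' surface temperature. Liquid densities are auxiliary values compiled from
#' standard handbook sources (they are not part of the panel's primary data)
#' and feed the molecular-radius estimate and the vehicle volume balance.
#'
#' @return A 23-row tibble of chemical records (see [chemical()] for columns).
#' @export
#' @examples
#' table1_chemicals()
table1_chemicals <- function() {
  p <- tibble::tribble(
    ~name,                          ~cas,          ~mw,    ~log_kow, ~vapour_pressure_pa, ~density, ~vehicle,
    "4-Tolunitrile",                "104-85-8",    117.15,  1.58,    41.72,               978,      "PBS",
    "Acetophenone",                 "98-86-2",     120.15,  0.20,    52.90,               1028,     "PBS",
    "Aminophenol",                  "95-55-6",     109.13,  0.62,    0.01,                1290,     "PBS",
    "Benylidene Acetone",           "122-57-6",    146.19,  2.07,    1.65,                1038,     "PBS",
    "Benzophenone (Ethanol)",       "119-61-9",    182.22,  3.18,    0.26,                1110,     "Ethanol",
    "Benzophenone (PBS)",           "119-61-9",    182.22,  3.18,    0.26,                1110,     "PBS",
    "Cinnamaldehyde",               "14371-10-9",  132.16,  1.90,    5.12,                1050,     "PBS",
    "Diethylmaleate",               "141-05-9",    172.18,  0.82,    14.00,               1064,     "PBS",
    "Dimethyl fumarate",            "624-49-7",    144.13,  1.74,    40.00,               1370,     "PBS",
    "Dimethyl phthalate",           "131-11-3",    194.19,  1.58,    0.41,                1190,     "PBS",
    "Ethylhexyl Acrylate",          "103-11-7",    184.28,  4.20,    23.70,               885,      "PBS",
    "Eugenol",                      "97-53-0",     164.20,  2.27,    3.02,                1067,     "PBS",
    "Geraniol (Ethanol)",           "106-24-1",    154.25,  3.56,    4.00,                889,      "Ethanol",
    "Geraniol (PBS)",               "106-24-1",    154.25,  3.56,    4.00,                889,      "PBS",
    "Isoeugenol",                   "97-54-1",     164.20,  3.04,    1.60,                1080,     "PBS",
    "Methyl Methane sulfonate",     "66-27-3",     110.13,  0.74,    55.20,               1300,     "PBS",
    "Methylisothiazolinone",        "2682-20-4",   115.15, -0.10,    4.13,                1190,     "PBS",
    "Naphthalene",                  "91-20-3",     128.17,  3.30,    11.30,               1140,     "PBS",
    "Nitrobenzene",                 "98-95-3",     123.11,  1.85,    32.70,               1199,     "PBS",
    "Propylparaben (Ethanol)",      "94-13-3",     180.20,  3.04,    0.24,                1060,     "Ethanol",
    "Tetramethyl thiuram disulfide","137-26-8",    240.42,  1.73,    0.0023,              1290,     "PBS",
    "Thioglycolic Acid",            "68-11-1",     92.11,   0.09,    11.60,               1320,     "PBS",
    "Vanillin",                     "121-33-5",    152.15,  1.19,    0.02,                1060,     "PBS"
  )
  p$radius_m <- NA_real_
  p$solubility <- NA_real_
  p$is_water <- FALSE
  p$d_evap_m2_s <- NA_real_
  validate_chemicals(p)
}

#' Built-in solvent property records
#'
#' Property records for the vehicle solvents the model supports out of the
#' box. PBS is treated as water for evaporation purposes (its salts are
#' non-volatile and dilute). Vapour pressures are at 32 degC skin-surface
#' temperature; water's saturation pressure is re-derived from the Antoine
#' equation at the scenario temperature, see [water_saturation_pressure()].
#'
#' @param name One of `"water"`, `"pbs"`, `"ethanol"`, `"acetone"`.
#' @return A one-row chemical tibble.
#' @export
#' @examples
#' solvent_record("ethanol")
solvent_record <- function(name = c("water", "pbs", "ethanol", "acetone")) {
  name <- match.arg(tolower(name), c("water", "pbs", "ethanol", "acetone"))
  switch(name,
    water = ,
    pbs = chemical("water", mw = 18.015, log_kow = -1.38,
                   vapour_pressure_pa = water_saturation_pressure(305.15),
                   density = 995, is_water = TRUE),
    ethanol = chemical("ethanol", mw = 46.07, log_kow = -0.31,
                       vapour_pressure_pa = 13300, density = 789),
    acetone = chemical("acetone", mw = 58.08, log_kow = -0.24,
                       vapour_pressure_pa = 40000, density = 784)
  )
}

#' Read / write a chemical panel as CSV
#'
#' Panels are exchanged as delimited tables with header columns
#' `name,cas,mw,log_kow,vapour_pressure_pa,density` and optional
#' `radius_m,solubility,is_water,d_evap_m2_s,vehicle`.
#'
#' @param path File path.
#' @return `read_chemicals()` returns a validated tibble; `write_chemicals()`
#'   returns `path` invisibly.
#' @export
read_chemicals <- function(path) {
  if (!file.exists(path)) {
    stop_pbpke("pbpke_io_error", "chemical panel file not found: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_chemicals(df)
}

#' @rdname read_chemicals
#' @param panel A chemical panel tibble.
#' @export
write_chemicals <- function(panel, path) {
  panel <- validate_chemicals(panel)
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

# NB: solvent_record("water") carries P_sat at 32 degC; ivpt_scenario()
# re-derives it from the Antoine fit at the scenario temperature.

# condition helper shared across the package
stop_pbpke <- function(class, ...) {
  stop(structure(
    class = c(class, "pbpke_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
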
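#' Load an exposure scenario from a YAML config file
#'
#' Config files use the human-facing units of the IVPT literature (mg/cm^2,
#' cm, degC, hours, percent humidity); conversion to the strict-SI internals
#' happens here and nowhere else. Unset keys are filled from the named
#' template (currently only `"hewitt_ivpt_default"`: 32 degC, RH 50%,
#' unoccluded 24 h leave-on, 1 cm^2 area, 10 mg/cm^2 vehicle load at 1% w/w
#' permeant, 1 cm donor height, 5 mL receptor) and every default used is
#' echoed as a message. Unknown keys are rejected.
#'
#' @param config Path to a YAML file, or an already-parsed named list.
#' @param panel Chemical panel to resolve `chemical:` names against. Default
#'   [table1_chemicals()].
#' @param quiet Suppress the default-echo messages.
#' @return A [ivpt_scenario()].
#' @export
#' @examples
#' load_scenario(list(chemical = "Vanillin", duration_h = 1), quiet = TRUE)
load_scenario <- function(config, panel = table1_chemicals(), quiet = FALSE) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      stop_pbpke("pbpke_io_error", "config file not found: ", config)
    }
    yaml::read_yaml(config)
  } else {
    config
  }
  known <- c("template", "chemical", "chemical_properties", "solvent",
             "dose_mg_cm2", "vehicle_loading_mg_cm2", "permeant_fraction",
             "area_cm2", "donor_height_cm", "temperature_c",
             "relative_humidity_pct", "wind_speed_m_s", "duration_h", "mode",
             "occluded", "rf_volume_ml", "rf_sink", "grid_mode",
             "params_override", "solver", "output_dt_s",
             "allow_water_condensation")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop_pbpke("pbpke_configuration_error",
               "unknown config keys: ", paste(unknown, collapse = ", "))
  }
  template <- cfg$template %||% "hewitt_ivpt_default"
  if (!identical(template, "hewitt_ivpt_default")) {
    stop_pbpke("pbpke_configuration_error", "unknown template: ", template)
  }
  defaults <- list(
    solvent = "water", vehicle_loading_mg_cm2 = 10, permeant_fraction = 0.01,
    area_cm2 = 1, donor_height_cm = 1, temperature_c = 32,
    relative_humidity_pct = 50, wind_speed_m_s = 0.2, duration_h = 24,
    mode = "mechanistic", rf_volume_ml = 5, rf_sink = FALSE,
    grid_mode = "layered_1d", output_dt_s = 300,
    allow_water_condensation = FALSE
  )
  used_default <- setdiff(names(defaults), names(cfg))
  cfg <- utils::modifyList(defaults, cfg)
  if (!quiet && length(used_default) > 0) {
    message("scenario defaults used (template ", template, "): ",
            paste(used_default, collapse = ", "))
  }
  # resolve the permeant
  permeant <- if (!is.null(cfg$chemical_properties)) {
    do.call(chemical, cfg$chemical_properties)
  } else if (!is.null(cfg$chemical)) {
    hit <- panel[panel$name == cfg$chemical, ]
    if (nrow(hit) == 0) {
      stop_pbpke("pbpke_configuration_error",
                 "unknown chemical '", cfg$chemical, "'; panel has: ",
                 paste(panel$name, collapse = ", "))
    }
    hit[1, ]
  } else {
    stop_pbpke("pbpke_configuration_error",
               "config must name a 'chemical' or give 'chemical_properties'")
  }
  num <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      stop_pbpke("pbpke_configuration_error",
                 "could not parse numeric value for '", key, "': ",
                 deparse(x))
    }
    x
  }
  mode <- if (isTRUE(cfg$occluded)) "occluded" else cfg$mode
  solvent <- if (identical(tolower(cfg$solvent), "none")) NULL else
    solvent_record(cfg$solvent)
  env <- ivpt_environment(
    temperature_k = num(cfg$temperature_c, "temperature_c") + 273.15,
    relative_humidity = num(cfg$relative_humidity_pct,
                            "relative_humidity_pct") / 100,
    donor_height_m = num(cfg$donor_height_cm, "donor_height_cm") / 100,
    wind_speed = num(cfg$wind_speed_m_s, "wind_speed_m_s")
  )
  geom <- skin_geometry(
    area_m2 = num(cfg$area_cm2, "area_cm2") * 1e-4,
    rf_volume_m3 = num(cfg$rf_volume_ml, "rf_volume_ml") * 1e-6,
    rf_sink = isTRUE(cfg$rf_sink)
  )
  args <- list(
    permeant = permeant, solvent = solvent, environment = env,
    geometry = geom,
    vehicle_loading_kg_m2 = num(cfg$vehicle_loading_mg_cm2,
                                "vehicle_loading_mg_cm2") / 100,
    permeant_fraction = num(cfg$permeant_fraction, "permeant_fraction"),
    duration_s = num(cfg$duration_h, "duration_h") * 3600,
    mode = mode, grid_mode = cfg$grid_mode,
    params_override = cfg$params_override %||% list(),
    solver = cfg$solver %||% list(),
    output_dt_s = num(cfg$output_dt_s, "output_dt_s"),
    allow_water_condensation = isTRUE(cfg$allow_water_condensation)
  )
  if (!is.null(cfg$dose_mg_cm2)) {
    args$dose_kg_m2 <- num(cfg$dose_mg_cm2, "dose_mg_cm2") / 100
  }
  do.call(ivpt_scenario, args)
}

#' Serialize a scenario back to config form
#'
#' Inverse of [load_scenario()] in the human-facing units; `load_scenario()`
#' of the dumped list reproduces the scenario (round-trip identity on all
#' numeric fields).
#'
#' @param scenario A [ivpt_scenario()].
#' @param path Optional YAML output path; when `NULL` the list is returned.
#' @return The config list (invisibly when written to file).
#' @export
dump_scenario <- function(scenario, path = NULL) {
  sc <- scenario
  cfg <- list(
    template = "hewitt_ivpt_default",
    chemical = sc$permeant$name[[1]],
    solvent = if (is.null(sc$solvent)) "none" else sc$solvent$name[[1]],
    dose_mg_cm2 = sc$dose_kg_m2 * 100,
    vehicle_loading_mg_cm2 = sc$vehicle_loading_kg_m2 * 100,
    permeant_fraction = sc$dose_kg_m2 / sc$vehicle_loading_kg_m2,
    area_cm2 = sc$geometry$area_m2 * 1e4,
    donor_height_cm = sc$environment$donor_height_m * 100,
    temperature_c = sc$environment$temperature_k - 273.15,
    relative_humidity_pct = sc$environment$relative_humidity * 100,
    wind_speed_m_s = sc$environment$wind_speed,
    duration_h = sc$duration_s / 3600,
    mode = sc$mode,
    rf_volume_ml = sc$geometry$rf_volume_m3 * 1e6,
    rf_sink = sc$geometry$rf_sink,
    grid_mode = sc$grid_mode,
    output_dt_s = sc$output_dt_s,
    allow_water_condensation = sc$allow_water_condensation
  )
  if (is.null(path)) return(cfg)
  yaml::write_yaml(cfg, path)
  invisible(cfg)
}

#' Write simulation results to disk
#'
#' Writes the compartment time course as a tidy long CSV
#' (`time_s,compartment,mass_kg,percent_dose`), the evaporative flux records
#' and skin depth profiles as CSVs, and a JSON run manifest (mode, events,
#' solver diagnostics, scenario echo). A read of the written CSV reproduces
#' the percentages exactly to within formatting precision (15 significant
#' digits).
#'
#' @param result A `"pbpke_result"`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_results <- function(result, dir) {
  if (!inherits(result, "pbpke_result") || nrow(result$compartments_pct) == 0) {
    stop_pbpke("pbpke_configuration_error", "empty or invalid result")
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop_pbpke("pbpke_io_error", "cannot create directory: ", dir)
  tidy_path <- file.path(dir, "compartments.csv")
  flux_path <- file.path(dir, "flux.csv")
  profile_path <- file.path(dir, "skin_profiles.csv")
  manifest_path <- file.path(dir, "manifest.json")
  long <- tidy(result)
  utils::write.csv(long, tidy_path, row.names = FALSE)
  utils::write.csv(result$flux_series, flux_path, row.names = FALSE)
  utils::write.csv(result$skin_profiles, profile_path, row.names = FALSE)
  manifest <- list(
    package = "pbpke",
    mode = result$scenario$mode,
    grid_mode = result$scenario$grid_mode,
    qspr_version = result$params$qspr_version,
    dose_kg = result$dose_kg,
    duration_s = max(result$time_s),
    residue_film_triggered = "residue_film" %in% result$events$event,
    events = result$events,
    solver = result$scenario$solver,
    solver_steps = unname(result$diagnostics$istate[3]),
    scenario = dump_scenario(result$scenario)
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(compartments = tidy_path, flux = flux_path,
              profiles = profile_path, manifest = manifest_path))
}

#' @rdname write_results
#' @param dir Directory previously written by `write_results()`.
#' @export
read_results <- function(dir) {
  path <- file.path(dir, "compartments.csv")
  if (!file.exists(path)) {
    stop_pbpke("pbpke_io_error", "no compartments.csv under ", dir)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$time_s <- as.numeric(df$time_s)
  df$mass_kg <- as.numeric(df$mass_kg)
  df$percent_dose <- as.numeric(df$percent_dose)
  tibble::as_tibble(df)
}
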
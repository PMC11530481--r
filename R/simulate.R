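#' Define a finite-dose IVPT exposure scenario
#'
#' Bundles everything one simulation needs: the permeant, the vehicle recipe,
#' the donor-chamber environment, the skin geometry, the exposure duration and
#' the evaporation mode. The model is deterministic; `seed` is retained for
#' interface stability only.
#'
#' @param permeant One-row chemical tibble (the permeating solute).
#' @param solvent One-row chemical tibble for the vehicle solvent (e.g.
#'   [solvent_record()]), or `NULL` for a neat (pure-permeant) dose.
#' @param environment A [ivpt_environment()].
#' @param geometry A [skin_geometry()].
#' @param vehicle_loading_kg_m2 Total applied vehicle per area, kg/m^2.
#'   Default 0.1 (10 mg/cm^2, a typical thin finite-dose film).
#' @param permeant_fraction Permeant mass fraction of the vehicle (w/w).
#'   Default 0.01. Ignored when `dose_kg_m2` is given.
#' @param dose_kg_m2 Permeant dose per area, kg/m^2 (overrides
#'   `permeant_fraction`). With `solvent = NULL` the whole vehicle is
#'   permeant and the loading equals the dose.
#' @param duration_s Exposure duration, s. Default 86400 (24 h leave-on).
#' @param mode Evaporation mode: `"mechanistic"` (vapour-pressure diffusion;
#'   the PBPK-E pathway), `"legacy"` (wind-speed mass-transfer coefficient) or
#'   `"occluded"` (no evaporation; this is the plain PBPK pathway — the
#'   PBPK vs PBPK-E comparison is a mode switch, not separate code).
#' @param grid_mode Skin discretization, see [build_skin_grid()].
#' @param params_override Named list of transport parameter overrides, see
#'   [transport_params()].
#' @param solver List of solver options: `rtol` (default 1e-6), `atol`
#'   (default 1e-12, kg scale), `method` (default `"lsoda"`), `maxsteps`.
#' @param output_dt_s Reporting interval, s. Default 300 (5 min grid).
#' @param allow_water_condensation Passed to [evaporative_flux()].
#' @param seed Unused (deterministic model); kept for interface stability.
#' @return Object of class `"pbpke_scenario"`.
#' @export
#' @examples
#' sc <- ivpt_scenario(table1_chemicals()[1, ], solvent_record("water"))
ivpt_scenario <- function(permeant,
                          solvent = solvent_record("water"),
                          environment = ivpt_environment(),
                          geometry = skin_geometry(),
                          vehicle_loading_kg_m2 = 0.1,
                          permeant_fraction = 0.01,
                          dose_kg_m2 = NULL,
                          duration_s = 86400,
                          mode = c("mechanistic", "legacy", "occluded"),
                          grid_mode = c("layered_1d", "brick_mortar_2d"),
                          params_override = list(),
                          solver = list(),
                          output_dt_s = 300,
                          allow_water_condensation = FALSE,
                          seed = NULL) {
  mode <- match.arg(mode)
  grid_mode <- match.arg(grid_mode)
  permeant <- validate_chemicals(permeant)
  if (nrow(permeant) != 1) {
    stop_pbpke("pbpke_configuration_error", "exactly one permeant per scenario")
  }
  if (!is.null(solvent)) {
    solvent <- validate_chemicals(solvent)
    # water's saturation pressure tracks the scenario temperature
    refresh <- which(solvent$is_water)
    solvent$vapour_pressure_pa[refresh] <-
      water_saturation_pressure(environment$temperature_k)
  }
  if (duration_s <= 0) {
    stop_pbpke("pbpke_configuration_error", "duration must be > 0")
  }
  area <- geometry$area_m2
  if (is.null(dose_kg_m2)) {
    if (permeant_fraction <= 0 || permeant_fraction > 1) {
      stop_pbpke("pbpke_configuration_error",
                 "permeant_fraction must lie in (0, 1]")
    }
    dose_kg_m2 <- vehicle_loading_kg_m2 * permeant_fraction
  }
  if (dose_kg_m2 <= 0 || vehicle_loading_kg_m2 < dose_kg_m2 - 1e-300) {
    stop_pbpke("pbpke_configuration_error",
               "dose must be positive and no larger than the vehicle loading")
  }
  if (is.null(solvent)) vehicle_loading_kg_m2 <- dose_kg_m2
  solver <- utils::modifyList(
    list(rtol = 1e-6, atol = 1e-12, method = "lsoda", maxsteps = 50000),
    solver)
  structure(list(
    permeant = permeant, solvent = solvent, environment = environment,
    geometry = geometry, vehicle_loading_kg_m2 = vehicle_loading_kg_m2,
    dose_kg_m2 = dose_kg_m2, duration_s = duration_s, mode = mode,
    grid_mode = grid_mode, params_override = params_override,
    solver = solver, output_dt_s = output_dt_s,
    allow_water_condensation = allow_water_condensation, seed = seed
  ), class = "pbpke_scenario")
}

#' Run a scenario
#'
#' Integrates the coupled vehicle mass-balance and skin method-of-lines system
#' with an adaptive stiff solver over the exposure duration, and returns the
#' full time course: per-compartment amounts and percentages of the applied
#' permeant dose (atmosphere, vehicle, SC, viable epidermis, dermis, receptor
#' fluid), the per-component vehicle state, flux records, and events
#' (component dry-down, residue-film freeze, solubility warnings).
#'
#' After total dry-down (vehicle volume below 1e-6 of its initial value) the
#' film is frozen as a residue: evaporation stops but skin contact continues
#' with the residual amounts held in the minimal film volume.
#'
#' @param scenario A [ivpt_scenario()].
#' @return Object of class `"pbpke_result"`; see [mass_balance()],
#'   [tidy.pbpke_result()], [glance.pbpke_result()], [autoplot.pbpke_result()].
#' @export
#' @examples
#' res <- run_scenario(ivpt_scenario(table1_chemicals()[1, ],
#'                                   duration_s = 3600))
#' mass_balance(res, 3600)
run_scenario <- function(scenario) {
  sc <- scenario
  env <- sc$environment
  area <- sc$geometry$area_m2
  params <- transport_params(sc$permeant, sc$params_override)
  grid <- build_skin_grid(sc$geometry, params, sc$grid_mode)

  comp <- if (is.null(sc$solvent)) sc$permeant else {
    dplyr::bind_rows(sc$solvent, sc$permeant)
  }
  comp$a_l <- 1
  ncomp <- nrow(comp)
  perm_i <- ncomp                      # permeant is the last component
  m0 <- rep(0, ncomp)
  m0[perm_i] <- sc$dose_kg_m2 * area
  if (ncomp > 1) m0[1] <- (sc$vehicle_loading_kg_m2 - sc$dose_kg_m2) * area

  # precomputed constants for the RHS
  mw_kg <- comp$mw / 1000
  rho <- comp$density
  p_vap <- comp$vapour_pressure_pa
  a_l <- comp$a_l
  rt <- .R * env$temperature_k
  d_evap <- air_diffusivity(comp, env)
  m_a <- vapply(seq_len(ncomp), function(i) ambient_concentration(env, comp[i, ]),
                numeric(1))
  k_leg <- legacy_kevap(comp, env)
  h <- env$donor_height_m
  no_clamp <- comp$is_water & sc$allow_water_condensation
  v0 <- sum(m0 / rho)
  v_min <- .RESIDUE_FRACTION * v0
  lap <- as(grid$laplacian, "CsparseMatrix")
  kcell <- grid$cells$k
  vol <- grid$vol
  top_ids <- grid$top_ids
  bot_ids <- grid$bot_ids
  u_top <- grid$u_top
  u_bot <- grid$u_bot
  rf_sink <- isTRUE(sc$geometry$rf_sink)
  v_rf <- sc$geometry$rf_volume_m3
  ncell <- nrow(grid$cells)
  i_m <- seq_len(ncomp)
  i_c <- ncomp + seq_len(ncell)
  i_rf <- ncomp + ncell + 1L
  i_ev <- ncomp + ncell + 1L + seq_len(ncomp)
  occluded <- sc$mode == "occluded"
  legacy <- sc$mode == "legacy"

  rhs <- function(t, y, parms) {
    m <- pmax(y[i_m], 0)
    v <- sum(m / rho)
    j_molar <- rep(0, ncomp)
    if (!occluded && v >= v_min) {
      n_mol <- m / mw_kg
      tot <- sum(n_mol)
      if (tot > 0) {
        m_s <- p_vap * (n_mol / tot) * a_l / rt
        j_molar <- if (legacy) k_leg * (m_s - m_a) else d_evap * (m_s - m_a) / h
        j_molar[j_molar < 0 & !no_clamp] <- 0
        j_molar[m <= .MASS_FLOOR] <- 0
      }
    }
    j_mass <- j_molar * mw_kg
    v_eff <- max(v, v_min)
    c_perm <- m[perm_i] / v_eff
    conc <- y[i_c]
    psi <- conc / kcell
    inflow <- as.numeric(lap %*% psi)
    ftop <- u_top * (c_perm / params$k_veh - psi[top_ids])
    inflow[top_ids] <- inflow[top_ids] + ftop
    psi_rf <- if (rf_sink) 0 else (y[i_rf] / v_rf) / params$k_rf
    fbot <- u_bot * (psi[bot_ids] - psi_rf)
    inflow[bot_ids] <- inflow[bot_ids] - fbot
    dm <- -j_mass * area
    dm[perm_i] <- dm[perm_i] - sum(ftop) * area
    list(c(dm, inflow / vol, sum(fbot) * area, j_mass * area))
  }

  times <- unique(c(seq(0, sc$duration_s, by = sc$output_dt_s), sc$duration_s))
  y0 <- c(m0, rep(0, ncell), 0, rep(0, ncomp))
  out <- deSolve::ode(
    y = y0, times = times, func = rhs, parms = NULL,
    method = sc$solver$method, rtol = sc$solver$rtol, atol = sc$solver$atol,
    maxsteps = sc$solver$maxsteps
  )
  if (attr(out, "istate")[1] < 0) {
    stop_pbpke("pbpke_solver_error",
               "stiff solver failed at t = ", max(out[, 1]),
               " s (istate ", attr(out, "istate")[1], ")")
  }
  tt <- out[, 1]
  m_t <- out[, 1 + i_m, drop = FALSE]
  c_t <- out[, 1 + i_c, drop = FALSE]
  rf_t <- out[, 1 + i_rf]
  ev_t <- out[, 1 + i_ev, drop = FALSE]
  v_t <- as.numeric(m_t %*% (1 / rho))
  dose <- m0[perm_i]

  layer_mass <- function(layer) {
    sel <- grid$cells$layer == layer
    as.numeric(c_t[, sel, drop = FALSE] %*% vol[sel]) * area
  }
  compartments <- tibble::tibble(
    time_s = tt,
    atmosphere = ev_t[, perm_i],
    vehicle = m_t[, perm_i],
    sc = layer_mass("sc") + layer_mass("slab"),
    ve = layer_mass("ve"),
    dermis = layer_mass("de"),
    rf = rf_t
  )
  pct <- dplyr::mutate(compartments,
                       dplyr::across(-time_s, ~ 100 * .x / dose))

  # events
  events <- list()
  for (i in seq_len(ncomp)) {
    dried <- which(m_t[, i] <= .MASS_FLOOR)
    if (length(dried) > 0 && m0[i] > .MASS_FLOOR) {
      events[[length(events) + 1]] <- tibble::tibble(
        time_s = tt[dried[1]], event = "dry_down", detail = comp$name[i])
    }
  }
  res_idx <- which(v_t < v_min)
  if (length(res_idx) > 0) {
    events[[length(events) + 1]] <- tibble::tibble(
      time_s = tt[res_idx[1]], event = "residue_film", detail = "vehicle")
  }
  for (i in seq_len(ncomp)) {
    if (is.finite(comp$solubility[i])) {
      conc_i <- m_t[, i] / pmax(v_t, v_min)
      over <- which(conc_i > comp$solubility[i])
      if (length(over) > 0) {
        events[[length(events) + 1]] <- tibble::tibble(
          time_s = tt[over[1]], event = "solubility_exceeded",
          detail = comp$name[i])
        warning("vehicle concentration of ", comp$name[i],
                " exceeds its solubility (supersaturation; no precipitation",
                " physics is applied)", call. = FALSE)
      }
    }
  }
  events <- if (length(events) > 0) dplyr::bind_rows(events) else
    tibble::tibble(time_s = numeric(0), event = character(0),
                   detail = character(0))

  vehicle_series <- tibble::tibble(
    time_s = rep(tt, each = ncomp),
    component = rep(comp$name, length(tt)),
    mass_kg = as.numeric(t(m_t)),
    volume_m3 = rep(v_t, each = ncomp),
    concentration = as.numeric(t(m_t / pmax(v_t, v_min))),
    cumulative_evaporated_kg = as.numeric(t(ev_t))
  )

  # evaporative flux records on the reporting grid (same formulas as the RHS)
  mm <- pmax(m_t, 0)
  n_mol_t <- sweep(mm, 2, mw_kg, "/")
  tot_t <- rowSums(n_mol_t)
  x_t <- n_mol_t / ifelse(tot_t > 0, tot_t, 1)
  m_s_t <- sweep(x_t, 2, p_vap * a_l / rt, "*")
  grad_t <- sweep(m_s_t, 2, m_a, "-")
  j_molar_t <- if (occluded) {
    matrix(0, nrow(mm), ncomp)
  } else if (legacy) {
    sweep(grad_t, 2, k_leg, "*")
  } else {
    sweep(grad_t, 2, d_evap / h, "*")
  }
  for (i in which(!no_clamp)) j_molar_t[j_molar_t[, i] < 0, i] <- 0
  j_molar_t[mm <= .MASS_FLOOR] <- 0
  j_molar_t[v_t < v_min | tot_t <= 0, ] <- 0
  flux_series <- tibble::tibble(
    time_s = rep(tt, each = ncomp),
    component = rep(comp$name, length(tt)),
    d_evap = rep(d_evap, length(tt)),
    m_s = as.numeric(t(m_s_t)),
    m_a = rep(m_a, length(tt)),
    j_molar = as.numeric(t(j_molar_t)),
    j_mass = as.numeric(t(sweep(j_molar_t, 2, mw_kg, "*"))),
    cumulative_evaporated_kg = as.numeric(t(ev_t))
  )

  skin_profiles <- tibble::tibble(
    time_s = rep(tt, each = ncell),
    depth_m = rep(grid$cells$depth, length(tt)),
    layer = rep(grid$cells$layer, length(tt)),
    concentration = as.numeric(t(c_t))
  )

  structure(list(
    scenario = sc, grid = grid, params = params,
    time_s = tt, dose_kg = dose,
    compartments_kg = compartments, compartments_pct = pct,
    vehicle_series = vehicle_series, flux_series = flux_series,
    skin_profiles = skin_profiles, volume_m3 = v_t,
    events = events,
    diagnostics = list(istate = attr(out, "istate"), rstate = attr(out, "rstate"))
  ), class = "pbpke_result")
}

#' @export
print.pbpke_result <- function(x, ...) {
  mb <- mass_balance(x, max(x$time_s))
  cat(sprintf("<pbpke_result> %s in %s, mode = %s, %.1f h\n",
              x$scenario$permeant$name[[1]],
              if (is.null(x$scenario$solvent)) "neat film" else
                x$scenario$solvent$name[[1]],
              x$scenario$mode, max(x$time_s) / 3600))
  print(mb)
  invisible(x)
}

#' Compartmental mass balance at a time point
#'
#' Percent of the applied permeant dose in each of the six compartments at
#' time `t`, plus the dermal delivery aggregate (viable epidermis + dermis +
#' receptor fluid). Values are linearly interpolated on the reporting grid.
#'
#' @param result A `"pbpke_result"`.
#' @param t Time, s; must lie within the simulated range.
#' @return A tibble with `compartment` and `percent_dose`; the six compartment
#'   rows sum to 100 within solver tolerance.
#' @export
mass_balance <- function(result, t = max(result$time_s)) {
  if (t < min(result$time_s) || t > max(result$time_s)) {
    stop_pbpke("pbpke_range_error", "t = ", t, " s outside simulated range [",
               min(result$time_s), ", ", max(result$time_s), "]")
  }
  pct <- result$compartments_pct
  at <- vapply(c("atmosphere", "vehicle", "sc", "ve", "dermis", "rf"),
               function(cmp) stats::approx(pct$time_s, pct[[cmp]], t)$y,
               numeric(1))
  tibble::tibble(
    compartment = c(names(at), "dermal_delivery"),
    percent_dose = c(unname(at), unname(at[["ve"]] + at[["dermis"]] + at[["rf"]]))
  )
}

#' Batch-run a chemical panel
#'
#' Runs one scenario per panel row (same vehicle recipe, environment and
#' geometry throughout) and collects the end-of-exposure mass balance into a
#' wide tibble, one row per chemical — the shape the evaluation module and the
#' observation tables use.
#'
#' @param panel Chemical panel tibble (e.g. [table1_chemicals()]).
#' @param ... Passed to [ivpt_scenario()] (everything but `permeant`;
#'   `solvent` may be a function of the panel row's `vehicle` annotation).
#' @param solvent_from_vehicle Logical; when `TRUE` (default) rows annotated
#'   `"Ethanol"` are dosed in ethanol and all others in water/PBS, overriding
#'   any `solvent` argument.
#' @return Tibble: `chemical`, `atmosphere_pct`, `vehicle_pct`, `sc_pct`,
#'   `ve_pct`, `dermis_pct`, `rf_pct`, `dermal_delivery_pct`.
#' @export
#' @examples
#' run_panel(table1_chemicals()[1:2, ], duration_s = 3600)
run_panel <- function(panel, ..., solvent_from_vehicle = TRUE) {
  panel <- validate_chemicals(panel)
  purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    row <- panel[i, ]
    args <- list(...)
    if (solvent_from_vehicle) {
      args$solvent <- if (identical(row$vehicle, "Ethanol")) {
        solvent_record("ethanol")
      } else {
        solvent_record("water")
      }
    }
    res <- do.call(ivpt_scenario, c(list(permeant = row), args))
    mb <- mass_balance(run_scenario(res))
    tibble::tibble(
      chemical = row$name,
      atmosphere_pct = mb$percent_dose[mb$compartment == "atmosphere"],
      vehicle_pct = mb$percent_dose[mb$compartment == "vehicle"],
      sc_pct = mb$percent_dose[mb$compartment == "sc"],
      ve_pct = mb$percent_dose[mb$compartment == "ve"],
      dermis_pct = mb$percent_dose[mb$compartment == "dermis"],
      rf_pct = mb$percent_dose[mb$compartment == "rf"],
      dermal_delivery_pct = mb$percent_dose[mb$compartment == "dermal_delivery"]
    )
  })
}
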
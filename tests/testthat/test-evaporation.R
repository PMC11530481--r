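test_that("mole fractions follow the molar inventory", {
  pure <- vehicle_state(test_chemical(), 1e-6)
  expect_equal(unname(mole_fractions(pure)), 1)
  # equal moles of two components
  two <- vehicle_state(dplyr::bind_rows(solvent_record("water"),
                                        solvent_record("ethanol")),
                       masses = c(18.015e-3, 46.07e-3))
  expect_equal(unname(mole_fractions(two)), c(0.5, 0.5), tolerance = 1e-12)
  # 10 mol water + 1 mol ethanol
  ratio <- vehicle_state(dplyr::bind_rows(solvent_record("water"),
                                          solvent_record("ethanol")),
                         masses = c(0.18015, 0.04607))
  expect_equal(unname(mole_fractions(ratio)), c(10 / 11, 1 / 11),
               tolerance = 1e-6)
  # zero-mass component gets exactly 0
  z <- vehicle_state(dplyr::bind_rows(solvent_record("water"),
                                      test_chemical()),
                     masses = c(1e-6, 0))
  expect_identical(unname(mole_fractions(z))[2], 0)
  expect_error(mole_fractions(vehicle_state(test_chemical(), 0)),
               class = "pbpke_empty_vehicle")
})

test_that("mole fractions sum to one across random compositions", {
  set.seed(42)
  panel <- dplyr::bind_rows(solvent_record("water"), solvent_record("ethanol"),
                            test_chemical())
  for (i in 1:25) {
    v <- vehicle_state(panel, masses = stats::runif(3, 0, 1e-3))
    x <- mole_fractions(v)
    expect_lt(abs(sum(x) - 1), 1e-12)
    expect_true(all(x >= 0 & x <= 1))
  }
})

test_that("surface gas concentration obeys Raoult's law and the ideal gas law", {
  env <- ivpt_environment(temperature_k = 305.15)
  aceto <- table1_chemicals()[2, ]  # acetophenone, P = 52.90 Pa
  pure <- vehicle_state(aceto, 1e-6)
  expect_equal(surface_gas_concentration(pure, env, "Acetophenone"),
               52.90 / (R_GAS * 305.15), tolerance = 1e-12)
  # absent component: M_s = 0
  mix <- vehicle_state(dplyr::bind_rows(solvent_record("water"), aceto),
                       masses = c(1e-6, 0))
  expect_identical(surface_gas_concentration(mix, env, "Acetophenone"), 0)
  expect_error(surface_gas_concentration(pure, env, "nope"),
               class = "pbpke_unknown_component")
  # halving the mole fraction halves M_s: compare x and x/2 compositions
  m_w <- 1e-6 * 18.015 / 120.15  # equal moles water/acetophenone
  half <- vehicle_state(dplyr::bind_rows(solvent_record("water"), aceto),
                        masses = c(m_w, 1e-6))
  expect_equal(surface_gas_concentration(half, env, "Acetophenone"),
               0.5 * surface_gas_concentration(pure, env, "Acetophenone"),
               tolerance = 1e-9)
})

test_that("evaporative flux follows Fick's law across the donor headspace", {
  env <- ivpt_environment(temperature_k = 305.15, donor_height_m = 0.01)
  aceto <- table1_chemicals()[2, ]
  aceto$d_evap_m2_s <- 3.94e-8
  pure <- vehicle_state(aceto, 1e-6)
  fr <- evaporative_flux(pure, env)
  m_s <- 52.90 / (R_GAS * 305.15)
  expect_equal(fr$j_molar, 3.94e-8 * m_s / 0.01, tolerance = 1e-12)
  expect_equal(fr$j_molar, 8.21e-8, tolerance = 1e-2)
  # mass flux conversion is exact
  expect_identical(fr$j_mass, fr$j_molar * 120.15 / 1000)
  expect_equal(fr$j_mass, 9.87e-9, tolerance = 1e-2)
  # equilibrium: ambient equals surface concentration
  env_eq <- ivpt_environment(
    ambient_concentrations = c(Acetophenone = m_s))
  expect_identical(evaporative_flux(pure, env_eq)$j_molar, 0)
  # occluded mode forces zero flux
  expect_identical(evaporative_flux(pure, env, mode = "occluded")$j_molar, 0)
  # both modes vanish exactly when P = 0
  inert <- vehicle_state(test_chemical(p = 0), 1e-6)
  expect_identical(evaporative_flux(inert, env)$j_molar, 0)
  expect_identical(evaporative_flux(inert, env, mode = "legacy")$j_molar, 0)
})

test_that("vehicle volume shrinks by the ideal-solution additive rule", {
  env <- ivpt_environment()
  aceto <- table1_chemicals()[2, ]
  pure <- vehicle_state(aceto, 1e-6)
  none <- evaporative_flux(pure, env, mode = "occluded")
  expect_identical(vehicle_volume_rate(pure, none, area = 1e-4), 0)
  # single-component hand evaluation
  fr <- none
  fr$j_mass <- 9.87e-9
  expect_equal(vehicle_volume_rate(pure, fr, area = 1e-4),
               -9.87e-9 * 1e-4 / 1028, tolerance = 1e-12)
  expect_equal(-9.87e-9 * 1e-4 / 1028, -9.60e-16, tolerance = 1e-2)
  # two components: rates add
  mix <- vehicle_state(dplyr::bind_rows(solvent_record("water"), aceto),
                       masses = c(5e-7, 1e-6))
  fmix <- evaporative_flux(mix, env)
  r_w <- -fmix$j_mass[1] * 1e-4 / 995
  r_a <- -fmix$j_mass[2] * 1e-4 / 1028
  expect_equal(vehicle_volume_rate(mix, fmix, area = 1e-4), r_w + r_a,
               tolerance = 1e-12)
})

test_that("the vehicle concentration ODE keeps a pure component at its density", {
  env <- ivpt_environment()
  pure <- vehicle_state(table1_chemicals()[2, ], 1e-6)
  fr <- evaporative_flux(pure, env)
  rhs <- vehicle_rhs(pure, fr, j_skin = 0, area = 1e-4)
  # Eq. identity: evaporation shrinks V but leaves C = rho
  expect_lt(abs(rhs$dC_dt) / 1028 * 1e-6, 1e-15)
  expect_lt(rhs$dV_dt, 0)
  # everything occluded: nothing moves
  f0 <- evaporative_flux(pure, env, mode = "occluded")
  rhs0 <- vehicle_rhs(pure, f0, j_skin = 0, area = 1e-4)
  expect_identical(unname(rhs0$dC_dt), 0)
  expect_identical(rhs0$dV_dt, 0)
  # dilute non-volatile solute concentrates as the volatile solvent dries
  mix <- vehicle_state(dplyr::bind_rows(solvent_record("ethanol"),
                                        test_chemical(p = 0)),
                       masses = c(1e-6, 1e-8))
  fmix <- evaporative_flux(mix, env)
  rhsm <- vehicle_rhs(mix, fmix, j_skin = 0, area = 1e-4)
  expect_gt(rhsm$dC_dt[["probe"]], 0)
  # depleted vehicle signals
  expect_error(vehicle_rhs(vehicle_state(test_chemical(), 0), fr,
                           area = 1e-4),
               class = "pbpke_depleted_vehicle")
})

test_that("cumulative evaporated mass equals the time integral of the flux records", {
  # neat volatile film, impermeable skin: single active process
  sc <- quick_scenario(test_chemical(p = 50, mw = 110, density = 1300),
                       solvent = NULL, duration_s = 6 * 3600,
                       params_override = impermeable_override,
                       output_dt_s = 120)
  res <- run_scenario(sc)
  fl <- res$flux_series
  a <- sc$geometry$area_m2
  trap <- cumsum(c(0, diff(fl$time_s) * (utils::head(fl$j_mass, -1) +
                                           utils::tail(fl$j_mass, -1)) / 2)) * a
  cum <- fl$cumulative_evaporated_kg
  final <- cum[length(cum)]
  expect_gt(final, 0)
  expect_lt(abs(trap[length(trap)] - final) / final, 1e-3)
})
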
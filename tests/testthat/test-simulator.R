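test_that("initial condition puts the whole dose in the vehicle", {
  res <- run_scenario(quick_scenario(table1_chemicals()[1, ]))
  mb0 <- mass_balance(res, 0)
  p <- stats::setNames(mb0$percent_dose, mb0$compartment)
  expect_equal(unname(p["vehicle"]), 100, tolerance = 1e-9)
  expect_equal(unname(sum(p[c("atmosphere", "sc", "ve", "dermis", "rf")])), 0,
               tolerance = 1e-9)
  expect_error(mass_balance(res, -1), class = "pbpke_range_error")
  expect_error(mass_balance(res, 1e9), class = "pbpke_range_error")
})

test_that("occluded runs lose nothing to the atmosphere and dermal delivery is the exact sum", {
  res <- run_scenario(quick_scenario(table1_chemicals()[2, ],
                                     mode = "occluded"))
  expect_true(all(res$compartments_pct$atmosphere == 0))
  mb <- mass_balance(res, 1800)
  p <- stats::setNames(mb$percent_dose, mb$compartment)
  expect_identical(unname(p["dermal_delivery"]),
                   unname(p["ve"] + p["dermis"] + p["rf"]))
})

test_that("occlusion, zero volatility and the plain PBPK pathway coincide", {
  inert <- test_chemical(p = 0)
  volatile <- test_chemical(p = 41.72)
  base <- list(solvent = NULL, duration_s = 4 * 3600)
  runs <- list(
    mech_p0 = run_scenario(do.call(quick_scenario,
                                   c(list(inert, mode = "mechanistic"), base))),
    occl_p0 = run_scenario(do.call(quick_scenario,
                                   c(list(inert, mode = "occluded"), base))),
    occl_p  = run_scenario(do.call(quick_scenario,
                                   c(list(volatile, mode = "occluded"), base)))
  )
  ref <- as.matrix(runs$mech_p0$compartments_kg[-1])
  scale <- max(abs(ref))
  for (nm in c("occl_p0", "occl_p")) {
    other <- as.matrix(runs[[nm]]$compartments_kg[-1])
    expect_lt(max(abs(other - ref)) / scale, 1e-10)
  }
})

test_that("mass balance closes and is insensitive to the solver tolerance", {
  chem <- table1_chemicals()[16, ]  # methyl methane sulfonate, most volatile
  res6 <- run_scenario(quick_scenario(chem, duration_s = 86400,
                                      solver = list(rtol = 1e-6)))
  expect_true(all(abs(compartment_sum(res6) - 100) < 0.1))
  res9 <- run_scenario(quick_scenario(chem, duration_s = 86400,
                                      solver = list(rtol = 1e-9)))
  p6 <- as.matrix(res6$compartments_pct[-1])
  p9 <- as.matrix(res9$compartments_pct[-1])
  expect_lt(max(abs(p6 - p9)), 0.01)
  # tight tolerance closes the balance to 1e-6 relative
  res8 <- run_scenario(quick_scenario(chem, duration_s = 86400,
                                      solver = list(rtol = 1e-8)))
  expect_true(all(abs(compartment_sum(res8) - 100) < 1e-4))
})

test_that("evaporation delays early receptor-fluid delivery on a volatile chemical", {
  # volatile solute in a non-volatile matrix: its own evaporation visibly
  # thins the vehicle concentration, so uptake must lag the occluded run
  chem <- test_chemical(p = 41.72, mw = 117.15, density = 978, log_kow = 1.58)
  base <- list(solvent = inert_matrix(), vehicle_loading_kg_m2 = 0.01,
               permeant_fraction = 0.1, duration_s = 5 * 3600,
               output_dt_s = 600)
  r_e <- run_scenario(do.call(quick_scenario,
                              c(list(chem, mode = "mechanistic"), base)))
  r_0 <- run_scenario(do.call(quick_scenario,
                              c(list(chem, mode = "occluded"), base)))
  expect_gt(utils::tail(r_e$compartments_pct$atmosphere, 1), 0.1)
  expect_true(all(r_e$compartments_pct$rf <=
                    r_0$compartments_pct$rf + 1e-9))
  expect_lt(utils::tail(r_e$compartments_pct$rf, 1),
            utils::tail(r_0$compartments_pct$rf, 1))
})

test_that("more volatile chemicals evaporate more and deliver less", {
  ps <- c(1, 10, 55.2)
  out <- purrr::map_dfr(ps, function(p) {
    res <- run_scenario(quick_scenario(test_chemical(p = p), solvent = NULL,
                                       duration_s = 86400))
    glance(res)
  })
  expect_true(all(diff(out$atmosphere_pct) > 0))
  expect_true(all(diff(out$dermal_delivery_pct) < 0))
})

test_that("solvent dry-down is detected and the run continues as a residue film", {
  # thin ethanol film dries within hours; the permeant stays behind
  sc <- quick_scenario(table1_chemicals()[1, ],
                       solvent = solvent_record("ethanol"),
                       vehicle_loading_kg_m2 = 0.02,
                       duration_s = 86400)
  res <- run_scenario(sc)
  expect_true(any(res$events$event %in% c("dry_down", "residue_film")))
  # the ethanol has effectively all left the film
  eth <- res$vehicle_series[res$vehicle_series$component == "ethanol", ]
  expect_gt(utils::tail(eth$cumulative_evaporated_kg, 1),
            0.99 * eth$mass_kg[1])
  # run completed with a closed balance
  expect_true(all(abs(compartment_sum(res) - 100) < 0.1))
  # skin uptake continued after the film dried
  t_dry <- min(res$events$time_s)
  rf <- res$compartments_pct
  expect_gt(utils::tail(rf$rf, 1),
            rf$rf[which.min(abs(rf$time_s - t_dry))])
})

test_that("supersaturation during dry-down emits a warning event", {
  chem <- table1_chemicals()[1, ]
  chem$solubility <- 20  # kg/m^3, far below what dry-down produces
  sc <- quick_scenario(chem, solvent = solvent_record("ethanol"),
                       vehicle_loading_kg_m2 = 0.02, duration_s = 86400,
                       params_override = impermeable_override)
  expect_warning(res <- run_scenario(sc), "solubility")
  expect_true("solubility_exceeded" %in% res$events$event)
})

test_that("scenario validation rejects inconsistent dosing", {
  expect_error(ivpt_scenario(table1_chemicals()[1, ], duration_s = -1),
               class = "pbpke_configuration_error")
  expect_error(ivpt_scenario(table1_chemicals()[1, ], permeant_fraction = 0),
               class = "pbpke_configuration_error")
  expect_error(ivpt_scenario(table1_chemicals()[1, ],
                             vehicle_loading_kg_m2 = 0.001, dose_kg_m2 = 0.01),
               class = "pbpke_configuration_error")
  expect_error(ivpt_scenario(table1_chemicals()[1:2, ]),
               class = "pbpke_configuration_error")
})

test_that("tidiers return the documented shapes", {
  res <- run_scenario(quick_scenario(table1_chemicals()[1, ]))
  td <- tidy(res)
  expect_setequal(names(td), c("time_s", "compartment", "mass_kg",
                               "percent_dose"))
  expect_setequal(unique(td$compartment),
                  c("atmosphere", "vehicle", "sc", "ve", "dermis", "rf"))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mass_balance_pct, 100, tolerance = 0.1)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
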
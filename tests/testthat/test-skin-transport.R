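test_that("QSPR overrides take precedence verbatim", {
  chem <- table1_chemicals()[1, ]
  sc <- qspr_sc_params(chem, override = list(k_sc = 5.0, d_sc = 1e-13))
  expect_identical(sc$k_sc, 5.0)
  expect_identical(sc$d_sc, 1e-13)
  ve <- qspr_viable_params(chem, override = list(k_ve = 2, d_ve = 3e-10))
  expect_identical(ve$k_ve, 2)
  expect_identical(ve$d_ve, 3e-10)
  # pure function of (MW, log Kow): identical inputs, identical outputs
  a <- test_chemical(mw = 150, log_kow = 2.5)
  b <- chemical("other", mw = 150, log_kow = 2.5, vapour_pressure_pa = 1,
                density = 1100)
  expect_identical(qspr_sc_params(a), qspr_sc_params(b))
  # missing log_kow without override is a configuration error
  nolk <- chemical("nolk", mw = 100, density = 1000)
  expect_error(qspr_sc_params(nolk), class = "pbpke_configuration_error")
  expect_error(qspr_viable_params(nolk), class = "pbpke_configuration_error")
})

test_that("QSPR outputs follow the expected structure-property trends", {
  lkow <- seq(-0.1, 4.2, length.out = 15)
  k_lip <- vapply(lkow, function(l) {
    qspr_sc_params(test_chemical(log_kow = l))$k_lip
  }, numeric(1))
  expect_true(all(diff(k_lip) >= 0))
  mws <- seq(90, 250, length.out = 12)
  d_ve <- vapply(mws, function(m) {
    qspr_viable_params(test_chemical(mw = m))$d_ve
  }, numeric(1))
  expect_true(all(diff(d_ve) < 0))
  d_sc <- vapply(mws, function(m) {
    qspr_sc_params(test_chemical(mw = m))$d_sc
  }, numeric(1))
  expect_true(all(diff(d_sc) < 0))
})

test_that("viable epidermis and dermis share one parameter set", {
  p <- qspr_viable_params(table1_chemicals()[5, ])
  expect_identical(p$k_ve, p$k_de)
  expect_identical(p$d_ve, p$d_de)
  tp <- transport_params(table1_chemicals()[5, ])
  expect_identical(tp$k_ve, tp$k_de)
  expect_s3_class(tp, "pbpke_transport_params")
  expect_identical(tp$k_veh, 1)
})

test_that("a homogeneous slab reduces to the two-point harmonic-mean conductance", {
  d <- 1e-10; L <- 1e-4; n <- 10
  g <- slab_grid(L, n, d = d, k = 1)
  # interior conductance for uniform cells of width dz: U = D/dz
  dz <- L / n
  lap <- as.matrix(g$laplacian)
  expect_equal(lap[1, 2], d / dz, tolerance = 1e-12)
  expect_equal(lap[2, 1], d / dz, tolerance = 1e-12)
  # discrete antisymmetry: the operator is symmetric with zero row sums
  expect_equal(max(abs(lap - t(lap))), 0)
  expect_lt(max(abs(rowSums(lap))), 1e-25)
})

test_that("steady-state membrane flux is grid-independent and matches K D dC / L", {
  d <- 2e-11; k <- 3; L <- 1.2e-4
  geom <- skin_geometry(rf_sink = TRUE)
  c_top <- 5
  exact <- k * d * c_top / L
  f50 <- steady_state_flux(slab_grid(L, 50, d, k, geom), c_vehicle = c_top)$flux
  f100 <- steady_state_flux(slab_grid(L, 100, d, k, geom), c_vehicle = c_top)$flux
  expect_equal(f50, exact, tolerance = 1e-9)
  expect_lt(abs(f100 - f50) / f50, 0.005)
})

test_that("layered 1D grids respect the geometry and refinement barely moves the flux", {
  geom <- skin_geometry(n_sc = 25, n_ve = 15, n_de = 15, rf_sink = TRUE)
  params <- transport_params(table1_chemicals()[1, ])
  g <- build_skin_grid(geom, params)
  expect_equal(sum(g$cells$dz),
               geom$thickness_sc + geom$thickness_ve + geom$thickness_de,
               tolerance = 1e-15)
  expect_true(all(g$cells$depth > 0))
  f1 <- steady_state_flux(g, c_vehicle = 10)$flux
  g2 <- build_skin_grid(skin_geometry(n_sc = 50, n_ve = 30, n_de = 30,
                                      rf_sink = TRUE), params)
  f2 <- steady_state_flux(g2, c_vehicle = 10)$flux
  expect_lt(abs(f2 - f1) / f1, 0.005)
})

test_that("vehicle-skin flux is activity-driven and linear in the driving force", {
  params <- transport_params(table1_chemicals()[1, ])
  g <- build_skin_grid(skin_geometry(), params)
  empty <- rep(0, nrow(g$cells))
  expect_identical(skin_flux(g, empty, c_vehicle = 0, params), 0)
  # equilibrium loading of the top cell zeroes the flux
  k1 <- g$cells$k[g$top_ids[1]]
  state <- empty
  state[g$top_ids] <- k1 * 10 / params$k_veh
  expect_lt(abs(skin_flux(g, state, c_vehicle = 10, params)),
            1e-12 * skin_flux(g, empty, c_vehicle = 10, params))
  # doubling the vehicle concentration doubles the initial flux
  expect_equal(skin_flux(g, empty, 20, params),
               2 * skin_flux(g, empty, 10, params), tolerance = 1e-12)
})

test_that("the method-of-lines operator conserves mass and finds equilibrium", {
  params <- transport_params(table1_chemicals()[1, ])
  g <- build_skin_grid(skin_geometry(), params)
  n <- nrow(g$cells)
  # uniform activity, receptor at the same activity, sealed top: equilibrium
  psi0 <- 4
  state <- psi0 * g$cells$k
  out <- diffusion_rhs(g, state, c_vehicle = NULL,
                       c_rf = psi0 * 1, params = list(k_veh = 1, k_rf = 1))
  expect_lt(max(abs(out$dc_dt)) * max(g$vol), 1e-18)
  # arbitrary state: volume-weighted mass change equals net boundary flux
  set.seed(7)
  state <- stats::runif(n)
  out <- diffusion_rhs(g, state, c_vehicle = 2, c_rf = 0,
                       params = list(k_veh = 1, k_rf = 1))
  net <- sum(out$dc_dt * g$vol)
  expect_lt(abs(net - (out$j_top - out$j_bottom)) /
              max(abs(out$j_top), 1e-30), 1e-10)
  # dimension mismatch is an internal error
  expect_error(diffusion_rhs(g, state[-1]), class = "pbpke_internal_error")
})

test_that("2D brick-and-mortar grids build, stagger, and degenerate to the lipid-only slab", {
  params <- transport_params(table1_chemicals()[1, ])
  geom <- skin_geometry(n_cc_layers = 4, n_ve = 4, n_de = 4, rf_sink = TRUE)
  g <- build_skin_grid(geom, params, mode = "brick_mortar_2d")
  expect_setequal(unique(g$cells$phase[g$cells$layer == "sc"]),
                  c("lipid", "corneocyte"))
  # staggering: channel columns differ between adjacent corneocyte bands
  sc <- g$cells[g$cells$layer == "sc" & !is.na(g$cells$row), ]
  band_rows <- split(sc, sc$row)
  chan_cols <- vapply(band_rows, function(b) {
    if (all(b$phase == "lipid")) NA_integer_ else b$col[b$phase == "lipid"][1]
  }, integer(1))
  chan_cols <- chan_cols[!is.na(chan_cols)]
  expect_gt(length(unique(chan_cols)), 1)
  # zero lipid-channel thickness is rejected
  expect_error(skin_geometry(lipid_thickness = 0),
               class = "pbpke_invalid_geometry")
  # with identical phase parameters the 2D SC behaves as a homogeneous slab
  hom <- params
  hom$k_cc <- hom$k_lip
  hom$d_cc <- hom$d_lip
  g_hom <- build_skin_grid(geom, hom, mode = "brick_mortar_2d")
  sc_thick <- (geom$n_cc_layers + 1) * geom$lipid_thickness +
    geom$n_cc_layers * geom$corneocyte_height
  f2d <- steady_state_flux(g_hom, c_vehicle = 1)$flux
  layers_1d <- build_skin_grid(
    skin_geometry(thickness_sc = sc_thick, n_sc = 20, n_ve = 4, n_de = 4,
                  rf_sink = TRUE),
    utils::modifyList(params, list(k_sc = hom$k_lip, d_sc = hom$d_lip)))
  f1d <- steady_state_flux(layers_1d, c_vehicle = 1)$flux
  expect_equal(f2d, f1d, tolerance = 1e-6)
  # real microstructure: corneocyte bricks slow permeation vs all-lipid
  expect_lt(steady_state_flux(g, c_vehicle = 1)$flux, f2d * 1.001)
})
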
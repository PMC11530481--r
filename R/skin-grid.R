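#' Skin geometry for an IVPT diffusion cell
#'
#' Geometry of the mounted skin and receptor: application area, layer
#' thicknesses (stratum corneum, viable epidermis, dermis), receptor-fluid
#' volume, grid resolution per layer, and the brick-and-mortar microstructure
#' parameters used only by the 2D stratum-corneum mode. Depth is measured
#' positive downward from the vehicle--SC interface.
#'
#' @param area_m2 Application area A, m^2. Default 1e-4 (1 cm^2).
#' @param thickness_sc,thickness_ve,thickness_de Layer thicknesses, m.
#'   Defaults 20, 80 and 900 um (near full-thickness skin).
#' @param rf_volume_m3 Receptor-fluid volume, m^3. Default 5e-6 (5 mL).
#' @param n_sc,n_ve,n_de Cells per layer (>= 2 each) for the 1D mode.
#' @param rf_sink Logical; treat the receptor as a perfect sink instead of a
#'   finite well-mixed volume. Default `FALSE` (stirred Franz-cell receptor).
#' @param corneocyte_width,corneocyte_height,lipid_thickness,n_cc_layers
#'   Brick-and-mortar parameters for the 2D mode: corneocyte width and height,
#'   lipid channel/gap thickness (m) and number of corneocyte layers. In 2D
#'   mode the SC thickness follows from these
#'   (`(n+1)*lipid + n*height`), not from `thickness_sc`.
#' @param cc_subrows Rows a corneocyte is split into vertically (2D mode).
#' @return Object of class `"pbpke_skin_geometry"`.
#' @export
skin_geometry <- function(area_m2 = 1e-4,
                          thickness_sc = 20e-6,
                          thickness_ve = 80e-6,
                          thickness_de = 900e-6,
                          rf_volume_m3 = 5e-6,
                          n_sc = 12, n_ve = 6, n_de = 10,
                          rf_sink = FALSE,
                          corneocyte_width = 30e-6,
                          corneocyte_height = 0.8e-6,
                          lipid_thickness = 0.075e-6,
                          n_cc_layers = 15,
                          cc_subrows = 2) {
  vals <- c(area_m2, thickness_sc, thickness_ve, thickness_de, rf_volume_m3,
            corneocyte_width, corneocyte_height, lipid_thickness)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop_pbpke("pbpke_invalid_geometry",
               "lengths, areas and volumes must all be > 0")
  }
  if (min(n_sc, n_ve, n_de) < 2) {
    stop_pbpke("pbpke_invalid_geometry", "need >= 2 cells per layer")
  }
  structure(list(
    area_m2 = area_m2, thickness_sc = thickness_sc,
    thickness_ve = thickness_ve, thickness_de = thickness_de,
    rf_volume_m3 = rf_volume_m3, n_sc = n_sc, n_ve = n_ve, n_de = n_de,
    rf_sink = rf_sink, corneocyte_width = corneocyte_width,
    corneocyte_height = corneocyte_height, lipid_thickness = lipid_thickness,
    n_cc_layers = n_cc_layers, cc_subrows = cc_subrows
  ), class = "pbpke_skin_geometry")
}

# Assemble a grid object from a cell table and face list.
# cells: tibble(id, layer, phase, depth, dz, wfrac, d, k); faces: (i, j, afrac)
# with afrac the face area per m^2 of skin surface, delta_i/delta_j the
# centroid-to-face distances. Interface conductance acts on activity
# psi = C/K:  U_ij = 1 / (delta_i/(D_i K_i) + delta_j/(D_j K_j)).
.assemble_grid <- function(cells, faces, geom) {
  n <- nrow(cells)
  u <- 1 / (faces$delta_i / (cells$d[faces$i] * cells$k[faces$i]) +
            faces$delta_j / (cells$d[faces$j] * cells$k[faces$j]))
  if (any(!is.finite(u) | u <= 0)) {
    stop_pbpke("pbpke_invalid_geometry", "non-positive interface conductance")
  }
  ua <- u * faces$afrac
  lap <- Matrix::sparseMatrix(
    i = c(faces$i, faces$j, faces$i, faces$j),
    j = c(faces$j, faces$i, faces$i, faces$j),
    x = c(ua, ua, -ua, -ua),
    dims = c(n, n)
  )
  top_ids <- which(cells$top)
  bot_ids <- which(cells$bottom)
  u_top <- (cells$d[top_ids] * cells$k[top_ids] / (cells$dz[top_ids] / 2)) *
    cells$wfrac[top_ids]
  u_bot <- (cells$d[bot_ids] * cells$k[bot_ids] / (cells$dz[bot_ids] / 2)) *
    cells$wfrac[bot_ids]
  structure(list(
    cells = cells, faces = tibble::as_tibble(faces)[, c("i", "j", "afrac")],
    laplacian = lap,
    top_ids = top_ids, u_top = u_top,
    bot_ids = bot_ids, u_bot = u_bot,
    vol = cells$dz * cells$wfrac,          # per m^2 of skin surface
    geometry = geom
  ), class = "pbpke_skin_grid")
}

#' Homogeneous slab grid
#'
#' A single homogeneous membrane discretized into `n_cells` finite volumes;
#' the building block for verification against the closed-form membrane
#' solution (steady flux `K D dC / L`, lag time `L^2 / 6D`).
#'
#' @param thickness_m Slab thickness L, m.
#' @param n_cells Number of cells (>= 2).
#' @param d,k Diffusion coefficient (m^2/s) and partition coefficient
#'   (phase/water) of the slab.
#' @param geom Optional [skin_geometry()] to carry area/RF settings.
#' @return A `"pbpke_skin_grid"`.
#' @export
slab_grid <- function(thickness_m, n_cells, d, k = 1, geom = skin_geometry()) {
  layers <- tibble::tibble(layer = "slab", thickness = thickness_m,
                           n = n_cells, d = d, k = k)
  .layered_grid(layers, geom)
}

.layered_grid <- function(layers, geom) {
  cells <- purrr::pmap_dfr(layers, function(layer, thickness, n, d, k) {
    dz <- rep(thickness / n, n)
    tibble::tibble(layer = layer, phase = layer, dz = dz, wfrac = 1,
                   d = d, k = k)
  })
  cells$id <- seq_len(nrow(cells))
  cells$depth <- cumsum(cells$dz) - cells$dz / 2
  cells$top <- cells$id == 1
  cells$bottom <- cells$id == nrow(cells)
  n <- nrow(cells)
  faces <- tibble::tibble(
    i = seq_len(n - 1), j = 2:n,
    delta_i = cells$dz[-n] / 2, delta_j = cells$dz[-1] / 2,
    afrac = 1
  )
  .assemble_grid(cells, faces, geom)
}

#' Build the discretized skin domain
#'
#' Discretizes the layered skin into finite volumes and precomputes all
#' interface conductances. Two modes:
#' \describe{
#'   \item{`layered_1d`}{(default) one vertical column of cells; the SC
#'     carries the homogenized effective (K_sc, D_sc) pair.}
#'   \item{`brick_mortar_2d`}{the SC is resolved as staggered corneocyte
#'     bricks in a lipid mortar on a laterally periodic unit cell (width =
#'     corneocyte width + lipid channel), with per-phase (K, D); the viable
#'     epidermis and dermis remain 1D below it. SC thickness follows from the
#'     microstructure parameters.}
#' }
#' Both modes expose the identical flux interface to the integrator.
#'
#' @param geom A [skin_geometry()].
#' @param params A [transport_params()] set.
#' @param mode `"layered_1d"` or `"brick_mortar_2d"`.
#' @return A `"pbpke_skin_grid"`: cell table, face table, sparse flux
#'   operator, and top/bottom boundary conductances.
#' @export
#' @examples
#' g <- build_skin_grid(skin_geometry(), transport_params(table1_chemicals()[1, ]))
#' nrow(g$cells)
build_skin_grid <- function(geom, params,
                            mode = c("layered_1d", "brick_mortar_2d")) {
  mode <- match.arg(mode)
  if (!inherits(geom, "pbpke_skin_geometry")) {
    stop_pbpke("pbpke_configuration_error", "geom must be a skin_geometry()")
  }
  if (mode == "layered_1d") {
    layers <- tibble::tibble(
      layer = c("sc", "ve", "de"),
      thickness = c(geom$thickness_sc, geom$thickness_ve, geom$thickness_de),
      n = c(geom$n_sc, geom$n_ve, geom$n_de),
      d = c(params$d_sc, params$d_ve, params$d_de),
      k = c(params$k_sc, params$k_ve, params$k_de)
    )
    return(.layered_grid(layers, geom))
  }
  .brick_mortar_grid(geom, params)
}

# 2D staggered brick-and-mortar SC over a periodic unit cell, 1D layers below.
.brick_mortar_grid <- function(geom, params) {
  s <- geom$lipid_thickness
  wc <- geom$corneocyte_width
  g <- geom$lipid_thickness
  hc <- geom$corneocyte_height
  nl <- geom$n_cc_layers
  if (s <= 0) {
    stop_pbpke("pbpke_invalid_geometry", "lipid channel thickness must be > 0")
  }
  w_unit <- wc + s
  # exact 4-column layout: channel column at x = 0 (even layers) and at
  # x = w_unit/2 (odd layers); both columns exist in every row
  xb <- c(0, s, w_unit / 2, w_unit / 2 + s, w_unit)
  wx <- diff(xb)
  nx <- length(wx)
  chan_even <- 1           # column index that is a channel in even layers
  chan_odd <- 3            # and in odd layers (staggered by half a brick)
  # rows: alternate lipid gap (1 row) and corneocyte band (cc_subrows rows)
  row_dz <- c()
  row_kind <- c()          # "gap" or layer index of the corneocyte band
  for (l in seq_len(nl)) {
    row_dz <- c(row_dz, g, rep(hc / geom$cc_subrows, geom$cc_subrows))
    row_kind <- c(row_kind, "gap", rep(as.character(l), geom$cc_subrows))
  }
  row_dz <- c(row_dz, g)
  row_kind <- c(row_kind, "gap")
  nz <- length(row_dz)
  # SC cells
  sc_cells <- purrr::map_dfr(seq_len(nz), function(r) {
    kind <- row_kind[r]
    phase <- rep("lipid", nx)
    if (kind != "gap") {
      l <- as.integer(kind)
      chan <- if (l %% 2 == 0) chan_even else chan_odd
      phase <- ifelse(seq_len(nx) == chan, "lipid", "corneocyte")
    }
    tibble::tibble(layer = "sc", phase = phase, row = r, col = seq_len(nx),
                   dz = row_dz[r], wfrac = wx / w_unit)
  })
  sc_cells$d <- ifelse(sc_cells$phase == "lipid", params$d_lip, params$d_cc)
  sc_cells$k <- ifelse(sc_cells$phase == "lipid", params$k_lip, params$k_cc)
  # 1D viable layers below
  low <- purrr::pmap_dfr(
    tibble::tibble(layer = c("ve", "de"),
                   thickness = c(geom$thickness_ve, geom$thickness_de),
                   n = c(geom$n_ve, geom$n_de),
                   d = c(params$d_ve, params$d_de),
                   k = c(params$k_ve, params$k_de)),
    function(layer, thickness, n, d, k) {
      tibble::tibble(layer = layer, phase = layer, row = NA_integer_,
                     col = NA_integer_, dz = thickness / n, wfrac = 1,
                     d = d, k = k)
    })
  cells <- dplyr::bind_rows(sc_cells, low)
  cells$id <- seq_len(nrow(cells))
  z_edges <- cumsum(c(0, row_dz))
  cells$depth <- NA_real_
  in_sc <- cells$layer == "sc"
  cells$depth[in_sc] <- z_edges[cells$row[in_sc]] + cells$dz[in_sc] / 2
  lowdepth <- sum(row_dz) + cumsum(cells$dz[!in_sc]) - cells$dz[!in_sc] / 2
  cells$depth[!in_sc] <- lowdepth
  cells$top <- in_sc & cells$row == 1
  cells$bottom <- cells$id == nrow(cells)
  idx <- matrix(cells$id[in_sc], nrow = nz, ncol = nx, byrow = TRUE)
  faces <- list()
  # vertical faces within SC
  for (r in seq_len(nz - 1)) {
    faces[[length(faces) + 1]] <- tibble::tibble(
      i = idx[r, ], j = idx[r + 1, ],
      delta_i = row_dz[r] / 2, delta_j = row_dz[r + 1] / 2,
      afrac = wx / w_unit)
  }
  # lateral faces with periodic wrap
  for (r in seq_len(nz)) {
    cnext <- c(2:nx, 1)
    faces[[length(faces) + 1]] <- tibble::tibble(
      i = idx[r, ], j = idx[r, cnext],
      delta_i = wx / 2, delta_j = wx[cnext] / 2,
      afrac = row_dz[r] / w_unit)
  }
  # SC bottom row -> first VE cell
  ve1 <- cells$id[!in_sc][1]
  faces[[length(faces) + 1]] <- tibble::tibble(
    i = idx[nz, ], j = ve1,
    delta_i = row_dz[nz] / 2, delta_j = cells$dz[ve1] / 2,
    afrac = wx / w_unit)
  # 1D chain below
  low_ids <- cells$id[!in_sc]
  nl1 <- length(low_ids)
  faces[[length(faces) + 1]] <- tibble::tibble(
    i = low_ids[-nl1], j = low_ids[-1],
    delta_i = cells$dz[low_ids[-nl1]] / 2, delta_j = cells$dz[low_ids[-1]] / 2,
    afrac = 1)
  .assemble_grid(cells, dplyr::bind_rows(faces), geom)
}

#' Vehicle-to-skin permeation flux
#'
#' The flux across the vehicle--SC interface, driven by the activity
#' difference between the well-mixed vehicle and the top skin cells:
#' \deqn{J_{skin} = \sum_{i \in top} U_{top,i}\,
#'   (C_{veh}/K_{veh} - C_i/K_i),}
#' in kg m^-2 s^-1, positive into the skin; negative values (back-diffusion
#' out of a loaded skin into a depleted vehicle) are permitted.
#'
#' @param grid A `"pbpke_skin_grid"`.
#' @param skin_state Numeric vector of per-cell concentrations, kg/m^3.
#' @param c_vehicle Vehicle concentration of the permeant, kg/m^3.
#' @param params A [transport_params()] (for `k_veh`).
#' @return Mass flux, kg m^-2 s^-1.
#' @export
skin_flux <- function(grid, skin_state, c_vehicle, params) {
  psi_top <- skin_state[grid$top_ids] / grid$cells$k[grid$top_ids]
  sum(grid$u_top * (c_vehicle / params$k_veh - psi_top))
}

#' Method-of-lines right-hand side for the skin domain
#'
#' Finite-volume conservation on the skin grid:
#' \deqn{\frac{dC_i}{dt} = \frac{1}{V_i}\Big(\sum_j U_{ij} (\psi_j - \psi_i)
#'   a_{ij} + \mathrm{boundary}\Big)}
#' with activities \eqn{\psi = C/K}. The top boundary couples to the vehicle
#' (omit `c_vehicle` for a closed top), the bottom feeds the well-mixed
#' receptor fluid (activity `c_rf / k_rf`, or 0 for a perfect sink).
#'
#' @param grid A `"pbpke_skin_grid"`.
#' @param skin_state Per-cell concentrations, kg/m^3.
#' @param c_vehicle Vehicle concentration (kg/m^3) or `NULL` for a sealed top.
#' @param c_rf Receptor-fluid concentration, kg/m^3 (ignored when the grid's
#'   geometry has `rf_sink = TRUE`).
#' @param params A [transport_params()]; supplies `k_veh` and `k_rf`.
#' @return List: `dc_dt` (per-cell, kg m^-3 s^-1), `j_top` (into skin,
#'   kg m^-2 s^-1), `j_bottom` (into RF, kg m^-2 s^-1).
#' @export
diffusion_rhs <- function(grid, skin_state, c_vehicle = NULL, c_rf = 0,
                          params = list(k_veh = 1, k_rf = 1)) {
  n <- nrow(grid$cells)
  if (length(skin_state) != n) {
    stop_pbpke("pbpke_internal_error",
               "skin state has length ", length(skin_state),
               ", grid has ", n, " cells")
  }
  psi <- skin_state / grid$cells$k
  inflow <- as.numeric(grid$laplacian %*% psi)
  j_top <- 0
  if (!is.null(c_vehicle)) {
    ftop <- grid$u_top * (c_vehicle / params$k_veh - psi[grid$top_ids])
    inflow[grid$top_ids] <- inflow[grid$top_ids] + ftop
    j_top <- sum(ftop)
  }
  psi_rf <- if (isTRUE(grid$geometry$rf_sink)) 0 else c_rf / params$k_rf
  fbot <- grid$u_bot * (psi[grid$bot_ids] - psi_rf)
  inflow[grid$bot_ids] <- inflow[grid$bot_ids] - fbot
  list(dc_dt = inflow / grid$vol, j_top = j_top, j_bottom = sum(fbot))
}

#' Steady-state permeation through a skin grid
#'
#' Solves the linear steady state of [diffusion_rhs()] for fixed vehicle and
#' receptor activities and returns the through-flux. Used for grid-convergence
#' checks and verification against the closed-form membrane solution.
#'
#' @inheritParams diffusion_rhs
#' @return List: `flux` (kg m^-2 s^-1), `psi` (per-cell activities),
#'   `concentration` (per-cell kg/m^3).
#' @export
steady_state_flux <- function(grid, c_vehicle, c_rf = 0,
                              params = list(k_veh = 1, k_rf = 1)) {
  n <- nrow(grid$cells)
  a <- grid$laplacian
  b <- numeric(n)
  diag_add <- numeric(n)
  psi_top <- c_vehicle / params$k_veh
  diag_add[grid$top_ids] <- diag_add[grid$top_ids] - grid$u_top
  b[grid$top_ids] <- b[grid$top_ids] - grid$u_top * psi_top
  psi_rf <- if (isTRUE(grid$geometry$rf_sink)) 0 else c_rf / params$k_rf
  diag_add[grid$bot_ids] <- diag_add[grid$bot_ids] - grid$u_bot
  b[grid$bot_ids] <- b[grid$bot_ids] - grid$u_bot * psi_rf
  a <- a + Matrix::Diagonal(n, diag_add)
  psi <- as.numeric(Matrix::solve(a, b))
  flux <- sum(grid$u_top * (psi_top - psi[grid$top_ids]))
  list(flux = flux, psi = psi, concentration = psi * grid$cells$k)
}
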
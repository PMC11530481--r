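# shared fixtures: everything is built in code at test time

R_GAS <- pbpke_constants$R_gas
KB <- pbpke_constants$k_boltzmann
N_AV <- pbpke_constants$n_avogadro

# a generic volatile liquid used where the identity of the chemical is
# irrelevant and only the physics is under test
test_chemical <- function(p = 41.72, mw = 117.15, density = 978,
                          log_kow = 1.58, ...) {
  chemical("probe", mw = mw, log_kow = log_kow, vapour_pressure_pa = p,
           density = density, ...)
}

# small, fast scenario: coarse grid, short duration
quick_scenario <- function(permeant, ...) {
  dots <- list(...)
  args <- list(permeant = permeant,
               geometry = skin_geometry(n_sc = 6, n_ve = 4, n_de = 6),
               duration_s = 3600, output_dt_s = 300)
  for (nm in names(dots)) args[nm] <- dots[nm]  # keeps explicit NULLs
  do.call(ivpt_scenario, args)
}

# inert oily matrix: non-volatile, non-permeating vehicle for tests that need
# a solute whose evaporation visibly thins its own concentration
inert_matrix <- function() {
  chemical("inert matrix", mw = 300, vapour_pressure_pa = 0, density = 900)
}

impermeable_override <- list(k_sc = 1, d_sc = 1e-30, k_ve = 1, d_ve = 1e-30)

compartment_sum <- function(result) {
  p <- result$compartments_pct
  p$atmosphere + p$vehicle + p$sc + p$ve + p$dermis + p$rf
}
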
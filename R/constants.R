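#' Physical constants used throughout the package
#'
#' A single ledger of the physical constants the model depends on, pinned to
#' CODATA 2018 values so that every computation in the package (and in its
#' tests) is exactly reproducible.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{R_gas}{Molar gas constant, J K\eqn{^{-1}} mol\eqn{^{-1}}.}
#'   \item{k_boltzmann}{Boltzmann constant, J/K.}
#'   \item{n_avogadro}{Avogadro constant, mol\eqn{^{-1}}.}
#' }
#' @export
#' @examples
#' pbpke_constants$R_gas
pbpke_constants <- list(
  R_gas       = 8.314462618,
  k_boltzmann = 1.380649e-23,
  n_avogadro  = 6.02214076e23
)

# internal shorthands
.R  <- pbpke_constants$R_gas
.KB <- pbpke_constants$k_boltzmann
.NA_CONST <- pbpke_constants$n_avogadro

# mass floor (kg) below which a vehicle component is treated as dried down,
# and the fraction of the initial vehicle volume below which the whole film
# is frozen as a residue
.MASS_FLOOR <- 1e-15
.RESIDUE_FRACTION <- 1e-6
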
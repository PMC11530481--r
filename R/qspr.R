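#' QSPR constants table
#'
#' The coefficients of the quantitative structure--property relationships
#' (QSPRs) that map (MW, log Kow) onto diffusion and partition coefficients in
#' the skin phases: power laws in the octanol--water partition coefficient for
#' the partition coefficients, and log-linear decay in molar mass for the
#' diffusivities, which is the established functional shape of the skin QSPR
#' literature. The numeric values are the package's own version-stamped
#' parameterisation tuned to give permeability coefficients in the range
#' observed for moderately lipophilic permeants; they are deliberately
#' overridable per chemical (see [transport_params()]), since any laboratory
#' that has fitted its own coefficients should supply them.
#'
#' All partition coefficients are referenced to water.
#'
#' @format Named list: lipid (`k_lip_*`, `d_lip_*`), corneocyte (`k_cc_*`,
#'   `d_cc_*`), viable tissue (`k_ve_*`, `d_ve_*`), SC lipid volume fraction
#'   `phi_lip`, and a `version` stamp.
#' @export
qspr_constants <- list(
  version    = "pbpke-qspr-1",
  # SC lipid phase: K = Kow^a ; log10 D = b0 + b1 * MW
  k_lip_exp  = 0.69,
  d_lip_log0 = -14.4,
  d_lip_slope = -0.0061,
  # SC corneocyte phase (keratin binding): K = 1 + a0 * Kow^a1
  k_cc_coef  = 4.2,
  k_cc_exp   = 0.31,
  d_cc_log0  = -14.6,
  d_cc_slope = -0.0061,
  # viable epidermis / dermis (single aqueous phase with binding)
  k_ve_base  = 0.7,
  k_ve_coef  = 0.3,
  k_ve_exp   = 0.33,
  d_ve_coef  = 1.0e-9,
  d_ve_exp   = -1 / 3,
  # SC lipid volume fraction for the homogenized effective medium
  phi_lip    = 0.125
)

#' Stratum corneum transport parameters from QSPR
#'
#' Lipid- and corneocyte-phase partition (K, phase/water) and diffusion (D,
#' m^2/s) coefficients for the stratum corneum, from the chemical's MW and
#' log Kow, plus a homogenized effective (K_sc, D_sc) pair for the 1D layered
#' mode. The effective pair combines the phases as volume-weighted parallel
#' partitioning,
#' \eqn{K_{sc} = \phi K_{lip} + (1-\phi) K_{cc}}, and series permeation
#' resistance,
#' \eqn{(K D)_{sc} = \left[\phi/(K_{lip}D_{lip}) +
#'  (1-\phi)/(K_{cc}D_{cc})\right]^{-1}}.
#' Any value supplied in `override` is returned verbatim in place of the QSPR
#' estimate.
#'
#' @param chem One-row chemical tibble with `mw` and `log_kow`.
#' @param override Named list of values to force, among `k_lip`, `d_lip`,
#'   `k_cc`, `d_cc`, `k_sc`, `d_sc`.
#' @return Named list with `k_lip`, `d_lip`, `k_cc`, `d_cc`, `k_sc`, `d_sc`.
#' @export
#' @examples
#' qspr_sc_params(table1_chemicals()[1, ])
#' qspr_sc_params(table1_chemicals()[1, ], override = list(k_sc = 5, d_sc = 1e-13))
qspr_sc_params <- function(chem, override = list()) {
  q <- qspr_constants
  need_qspr <- !all(c("k_sc", "d_sc") %in% names(override)) ||
    !all(c("k_lip", "d_lip", "k_cc", "d_cc") %in% names(override))
  if (need_qspr && !is.finite(chem$log_kow[[1]])) {
    stop_pbpke("pbpke_configuration_error",
               "log_kow missing for ", chem$name[[1]],
               " and no SC parameter override supplied")
  }
  kow <- 10^chem$log_kow[[1]]
  mw <- chem$mw[[1]]
  p <- list(
    k_lip = kow^q$k_lip_exp,
    d_lip = 10^(q$d_lip_log0 + q$d_lip_slope * mw),
    k_cc  = 1 + q$k_cc_coef * kow^q$k_cc_exp,
    d_cc  = 10^(q$d_cc_log0 + q$d_cc_slope * mw)
  )
  p[names(override)[names(override) %in% names(p)]] <-
    override[names(override) %in% names(p)]
  phi <- q$phi_lip
  kd_eff <- 1 / (phi / (p$k_lip * p$d_lip) + (1 - phi) / (p$k_cc * p$d_cc))
  p$k_sc <- override$k_sc %||% (phi * p$k_lip + (1 - phi) * p$k_cc)
  p$d_sc <- override$d_sc %||% (kd_eff / p$k_sc)
  p
}

#' Viable epidermis / dermis transport parameters from QSPR
#'
#' The living layers are treated as a single aqueous phase: the viable
#' epidermis and the dermis receive identical partition and diffusion
#' coefficients (the SC is the dominant barrier, so this simplification costs
#' little for total dermal delivery, though it limits per-layer accuracy).
#' K follows a weak lipophilicity power law; D follows a Stokes-like
#' \eqn{MW^{-1/3}} decay scaled for hindered diffusion in tissue.
#'
#' @inheritParams qspr_sc_params
#' @param override Named list among `k_ve`, `d_ve`.
#' @return Named list with `k_ve`, `d_ve`, `k_de`, `d_de` (the last two equal
#'   the first two by construction).
#' @export
qspr_viable_params <- function(chem, override = list()) {
  q <- qspr_constants
  need_qspr <- !all(c("k_ve", "d_ve") %in% names(override))
  if (need_qspr && !is.finite(chem$log_kow[[1]])) {
    stop_pbpke("pbpke_configuration_error",
               "log_kow missing for ", chem$name[[1]],
               " and no viable-tissue override supplied")
  }
  kow <- 10^chem$log_kow[[1]]
  mw <- chem$mw[[1]]
  k_ve <- override$k_ve %||% (q$k_ve_base + q$k_ve_coef * kow^q$k_ve_exp)
  d_ve <- override$d_ve %||% (q$d_ve_coef * mw^q$d_ve_exp)
  list(k_ve = k_ve, d_ve = d_ve, k_de = k_ve, d_de = d_ve)
}

#' Full transport parameter set for one permeant
#'
#' Bundles the SC and viable-tissue QSPR estimates with the vehicle/water
#' partition coefficient `k_veh` (1 for aqueous vehicles such as PBS; supply a
#' value for organic vehicles) and the receptor-fluid partition `k_rf`
#' (default 1, aqueous receptor).
#'
#' @inheritParams qspr_sc_params
#' @param override Named list; any of the keys of [qspr_sc_params()] /
#'   [qspr_viable_params()] plus `k_veh`, `k_rf`.
#' @return Object of class `"pbpke_transport_params"` (named list).
#' @export
#' @examples
#' transport_params(table1_chemicals()[1, ])
transport_params <- function(chem, override = list()) {
  p <- c(
    qspr_sc_params(chem, override),
    qspr_viable_params(chem, override)
  )
  p$k_veh <- override$k_veh %||% 1
  p$k_rf <- override$k_rf %||% 1
  p$qspr_version <- qspr_constants$version
  bad <- vapply(p[c("k_lip", "d_lip", "k_cc", "d_cc", "k_sc", "d_sc",
                    "k_ve", "d_ve", "k_veh", "k_rf")],
                function(x) !is.finite(x) || x <= 0, logical(1))
  if (any(bad)) {
    stop_pbpke("pbpke_configuration_error",
               "non-positive transport parameter(s): ",
               paste(names(bad)[bad], collapse = ", "))
  }
  structure(p, class = "pbpke_transport_params")
}
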
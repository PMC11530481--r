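#' Screen chemicals for volatility by mass-balance recovery
#'
#' In finite-dose IVPT studies the mass balance (percentage of applied dose
#' recovered across all measured compartments) falls short of 100% when part
#' of the dose has evaporated: a recovery below the threshold (default 90%)
#' is taken as indicative of evaporation, classifying the chemical as
#' volatile. The comparison is strict (`recovery < threshold`).
#'
#' @param records Data frame with at least `chemical` and `recovery_pct`
#'   columns (one row per chemical).
#' @param threshold_pct Recovery threshold, percent. Default 90.
#' @return The input tibble with a logical `volatile` column, in stable input
#'   order. Rows with missing recovery are excluded with a warning.
#' @export
#' @examples
#' obs <- tibble::tibble(chemical = c("a", "b"), recovery_pct = c(95, 85))
#' volatility_screen(obs)
volatility_screen <- function(records, threshold_pct = 90) {
  records <- tibble::as_tibble(records)
  if (!"recovery_pct" %in% names(records)) {
    stop_pbpke("pbpke_configuration_error",
               "records need a recovery_pct column")
  }
  missing <- !is.finite(records$recovery_pct)
  if (any(missing)) {
    warning(sum(missing), " record(s) without recovery excluded from the ",
            "volatility screen", call. = FALSE)
    records <- records[!missing, ]
  }
  dplyr::mutate(records, volatile = .data$recovery_pct < threshold_pct)
}

#' Coefficient of determination between predictions and observations
#'
#' Two conventions, both widely used and not interchangeable:
#' \describe{
#'   \item{`"pearson"`}{(default) the squared Pearson correlation — invariant
#'     under linear rescaling of either vector; measures association, not
#'     accuracy.}
#'   \item{`"identity"`}{\eqn{1 - SS_{res}/SS_{tot}} about the identity line
#'     (residuals are `predicted - observed`); penalises bias and slope, and
#'     can be negative for predictions worse than the observed mean.}
#' }
#' Evaluation reports compute both and label them.
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 3,
#'   finite).
#' @param method `"pearson"` or `"identity"`.
#' @return R-squared (dimensionless; in \[0, 1\] for `"pearson"`).
#' @export
#' @examples
#' r_squared(c(1, 2, 3, 4), c(1, 2, 3, 5))
r_squared <- function(predicted, observed,
                      method = c("pearson", "identity")) {
  method <- match.arg(method)
  if (length(predicted) != length(observed)) {
    stop_pbpke("pbpke_configuration_error",
               "predicted and observed must have equal length")
  }
  if (length(predicted) < 3) {
    stop_pbpke("pbpke_configuration_error", "need at least 3 pairs")
  }
  if (any(!is.finite(predicted)) || any(!is.finite(observed))) {
    stop_pbpke("pbpke_configuration_error", "non-finite values in input")
  }
  if (stats::var(observed) == 0 ||
      (method == "pearson" && stats::var(predicted) == 0)) {
    stop_pbpke("pbpke_undefined_statistic",
               "zero variance: R-squared undefined")
  }
  if (method == "pearson") {
    stats::cor(predicted, observed)^2
  } else {
    1 - sum((predicted - observed)^2) / sum((observed - mean(observed))^2)
  }
}

#' Compare occluded and evaporation-mode predictions against observations
#'
#' Builds the per-compartment evaluation table: for each compartment
#' (atmosphere/mass loss, vehicle, SC, viable epidermis, dermis, RF, dermal
#' delivery) the R-squared between each model's predicted percentages and the
#' observed ones, under both R-squared conventions, with n. The atmosphere
#' row is defined only for the evaporation model (a no-evaporation model
#' predicts zero mass loss for every chemical, so the statistic is
#' degenerate); observed mass loss is taken as `100 - recovery_pct`.
#'
#' @param results_pbpk,results_pbpke Wide prediction tibbles as returned by
#'   [run_panel()] (plain PBPK / occluded, and PBPK-E respectively).
#' @param observations Tibble with `chemical`, `recovery_pct` and
#'   per-compartment observed percentages (`vehicle_pct`, `sc_pct`, `ve_pct`,
#'   `dermis_pct`, `rf_pct`; `dermal_delivery_pct` is derived when absent).
#' @return Long tibble: `compartment`, `model`, `method`, `r_squared`, `n`.
#' @export
compare_models <- function(results_pbpk, results_pbpke, observations) {
  obs <- tibble::as_tibble(observations)
  for (d in list(results_pbpk, results_pbpke)) {
    miss <- setdiff(obs$chemical, d$chemical)
    if (length(miss) > 0) {
      stop_pbpke("pbpke_configuration_error",
                 "chemicals missing from predictions: ",
                 paste(miss, collapse = ", "))
    }
  }
  if (!"dermal_delivery_pct" %in% names(obs) &&
      all(c("ve_pct", "dermis_pct", "rf_pct") %in% names(obs))) {
    obs$dermal_delivery_pct <- obs$ve_pct + obs$dermis_pct + obs$rf_pct
  }
  if ("recovery_pct" %in% names(obs)) {
    obs$atmosphere_pct <- 100 - obs$recovery_pct
  }
  comps <- c(atmosphere = "atmosphere_pct", vehicle = "vehicle_pct",
             sc = "sc_pct", ve = "ve_pct", dermis = "dermis_pct",
             rf = "rf_pct", dermal_delivery = "dermal_delivery_pct")
  models <- list(pbpk = results_pbpk, pbpke = results_pbpke)
  rows <- list()
  for (cmp in names(comps)) {
    col <- comps[[cmp]]
    if (!col %in% names(obs)) next
    for (mod in names(models)) {
      if (cmp == "atmosphere" && mod == "pbpk") next  # undefined without evaporation
      pred <- models[[mod]][match(obs$chemical, models[[mod]]$chemical), ][[col]]
      keep <- is.finite(pred) & is.finite(obs[[col]])
      for (meth in c("pearson", "identity")) {
        r2 <- tryCatch(
          r_squared(pred[keep], obs[[col]][keep], method = meth),
          pbpke_error = function(e) NA_real_)
        rows[[length(rows) + 1]] <- tibble::tibble(
          compartment = cmp, model = mod, method = meth,
          r_squared = r2, n = sum(keep))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pbpke_comparison", class(out))
  out
}

#' Read an observed mass-balance table
#'
#' Observation CSVs carry one row per chemical with columns `chemical`,
#' `recovery_pct` and the per-compartment observed percentages
#' (`vehicle_pct,sc_pct,ve_pct,dermis_pct,rf_pct`); standard-deviation columns
#' (suffix `_sd`) are optional and passed through.
#'
#' @param path CSV file path.
#' @return Tibble of observations.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) {
    stop_pbpke("pbpke_io_error", "observations file not found: ", path)
  }
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!"chemical" %in% names(df)) {
    stop_pbpke("pbpke_io_error", "observations need a 'chemical' column")
  }
  df
}
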
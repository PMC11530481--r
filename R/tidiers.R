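#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result into a long tibble
#'
#' One row per (time, compartment): absolute mass (kg) and percent of the
#' applied permeant dose. The six compartments sum to 100% at every time.
#'
#' @param x A `"pbpke_result"`.
#' @param ... Unused.
#' @return Tibble: `time_s`, `compartment`, `mass_kg`, `percent_dose`.
#' @export
tidy.pbpke_result <- function(x, ...) {
  kg <- tidyr::pivot_longer(x$compartments_kg, -"time_s",
                            names_to = "compartment", values_to = "mass_kg")
  pct <- tidyr::pivot_longer(x$compartments_pct, -"time_s",
                             names_to = "compartment",
                             values_to = "percent_dose")
  dplyr::left_join(kg, pct, by = c("time_s", "compartment"))
}

#' One-row summary of a simulation result
#'
#' @param x A `"pbpke_result"`.
#' @param ... Unused.
#' @return One-row tibble: chemical, mode, duration, end-of-exposure
#'   atmosphere / receptor-fluid / dermal-delivery percentages, mass-balance
#'   closure, event count, solver steps.
#' @export
glance.pbpke_result <- function(x, ...) {
  mb <- mass_balance(x, max(x$time_s))
  p <- stats::setNames(mb$percent_dose, mb$compartment)
  closure <- sum(p[c("atmosphere", "vehicle", "sc", "ve", "dermis", "rf")])
  tibble::tibble(
    chemical = x$scenario$permeant$name[[1]],
    mode = x$scenario$mode,
    duration_h = max(x$time_s) / 3600,
    atmosphere_pct = unname(p["atmosphere"]),
    rf_pct = unname(p["rf"]),
    dermal_delivery_pct = unname(p["dermal_delivery"]),
    mass_balance_pct = closure,
    n_events = nrow(x$events),
    solver_steps = unname(x$diagnostics$istate[3])
  )
}

#' Plot the compartmental time course
#'
#' Percent of the applied dose in each compartment against time.
#'
#' @param object A `"pbpke_result"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pbpke_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s / 3600,
                                   y = .data$percent_dose,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "% of applied dose",
                  colour = "compartment",
                  title = sprintf("%s — %s mode",
                                  object$scenario$permeant$name[[1]],
                                  object$scenario$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a model-vs-observation comparison table
#'
#' Bar chart of per-compartment R-squared by model and convention.
#'
#' @param object A `"pbpke_comparison"` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pbpke_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$compartment, y = .data$r_squared,
                               fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = NULL, y = expression(R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot skin depth--concentration profiles
#'
#' @param result A `"pbpke_result"`.
#' @param times Times (s) to draw; defaults to five snapshots across the run.
#' @return A ggplot.
#' @export
plot_skin_profile <- function(result, times = NULL) {
  prof <- result$skin_profiles
  if (is.null(times)) {
    times <- stats::quantile(unique(prof$time_s), c(0.05, 0.25, 0.5, 0.75, 1))
  }
  pick <- vapply(times, function(t) {
    u <- unique(prof$time_s); u[which.min(abs(u - t))]
  }, numeric(1))
  df <- dplyr::filter(prof, .data$time_s %in% pick)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_m * 1e6,
                                   y = .data$concentration,
                                   colour = factor(round(.data$time_s / 3600, 2)))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (um)", y = "concentration (kg/m3)",
                  colour = "time (h)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
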
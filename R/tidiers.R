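#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scenario run into a long per-week tibble
#'
#' @param x An `upf_run` from [run_scenario()].
#' @param ... Unused.
#' @return A tibble with columns `scenario`, `step`, `stratum`
#'   (`population`, `income_low`, `income_high`, `edu_low`, `edu_high`),
#'   `mean_kcal` and (population rows only) `sd_kcal`.
#' @method tidy upf_run
#' @export
tidy.upf_run <- function(x, ...) {
  st <- x$steps
  long <- st |>
    dplyr::select("step", population = "mean", "income_low", "income_high",
                  "edu_low", "edu_high") |>
    tidyr::pivot_longer(-"step", names_to = "stratum",
                        values_to = "mean_kcal")
  long$sd_kcal <- ifelse(long$stratum == "population",
                         st$sd[match(long$step, st$step)], NA_real_)
  long$scenario <- x$scenario
  dplyr::relocate(long, "scenario")
}

#' One-row summary of a scenario run
#'
#' @param x An `upf_run`.
#' @param ... Unused.
#' @return The run's summary tibble: pre-policy and final means, the percent
#'   change between them, and the income-gap statistics at both weeks.
#' @method glance upf_run
#' @export
glance.upf_run <- function(x, ...) x$summary

#' Tidy the calibration candidate table
#'
#' @param x An `upf_calibration` from [calibrate()].
#' @param ... Unused.
#' @return A tibble with one row per evaluated candidate: the parameter
#'   values, the equilibrium mean and the screening flags.
#' @method tidy upf_calibration
#' @export
tidy.upf_calibration <- function(x, ...) x$candidates

#' One-row summary of a calibration
#'
#' @param x An `upf_calibration`.
#' @param ... Unused.
#' @return A tibble with the calibrated parameters, achieved equilibrium
#'   mean, final income gap, convergence flag and evaluation count.
#' @method glance upf_calibration
#' @export
glance.upf_calibration <- function(x, ...) {
  tibble::tibble(
    homophily_weight = x$parameters$homophily_weight,
    conformity_resistance = x$parameters$conformity_resistance,
    baseline_scale = x$parameters$baseline_scale,
    achieved_mean = x$achieved_mean,
    final_gap = x$gap_trajectory$gap[nrow(x$gap_trajectory)],
    converged = x$converged,
    evaluations = x$evaluations)
}
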
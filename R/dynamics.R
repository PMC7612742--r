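#' Configuration for weekly social purchasing dynamics
#'
#' Each week every agent compares her UPF purchasing to two references: the
#' mean among her network neighbours (social signal) and the mean among all
#' agents sharing her age group, income category and education (social norm).
#' If a reference differs from her own level by more than
#' `perception_threshold` kcal/week she moves `adjustment_fraction *
#' conformity_resistance` of the difference towards it; otherwise she leaves
#' her purchasing unchanged. The threshold represents imperfect knowledge of
#' friends' true purchasing, and creates a deadband that lets distinct group
#' levels persist at equilibrium.
#'
#' @param perception_threshold Deadband half-width, kcal/week (default 50).
#' @param adjustment_fraction Fraction of the difference closed per
#'   sub-update, in (0, 1] (default 0.10).
#' @param conformity_resistance Multiplier in [0, 1] on the adjustment
#'   fraction, a calibrated resistance-to-conforming knob; 1 recovers the
#'   plain 10% rule.
#' @return A list of class `"upf_dynamics_config"`.
#' @export
dynamics_config <- function(perception_threshold = 50,
                            adjustment_fraction = 0.10,
                            conformity_resistance = 1.0) {
  if (perception_threshold < 0) {
    stop("`perception_threshold` must be non-negative.", call. = FALSE)
  }
  if (adjustment_fraction <= 0 || adjustment_fraction > 1) {
    stop("`adjustment_fraction` must be in (0, 1].", call. = FALSE)
  }
  if (conformity_resistance < 0 || conformity_resistance > 1) {
    stop("`conformity_resistance` must be in [0, 1].", call. = FALSE)
  }
  structure(
    list(perception_threshold = perception_threshold,
         adjustment_fraction = adjustment_fraction,
         conformity_resistance = conformity_resistance),
    class = "upf_dynamics_config")
}

#' One social adjustment of purchasing towards a reference
#'
#' Vectorised single sub-update: if `|own - reference|` exceeds the perception
#' threshold the agent moves `adjustment_fraction * conformity_resistance` of
#' the difference towards the reference; otherwise she is unchanged. The
#' result is floored at 0.
#'
#' @param own,reference Non-negative purchasing levels, kcal/week.
#' @param config A [dynamics_config()].
#' @return Adjusted purchasing, same length as `own`.
#' @export
#' @examples
#' signal_adjustment(3000, 3500, dynamics_config())  # 3050
#' signal_adjustment(3000, 3040, dynamics_config())  # unchanged: within 50
signal_adjustment <- function(own, reference, config = dynamics_config()) {
  if (any(own < 0) || any(reference < 0)) {
    stop("Purchasing levels must be non-negative.", call. = FALSE)
  }
  step <- config$adjustment_fraction * config$conformity_resistance
  move <- abs(own - reference) > config$perception_threshold
  pmax(ifelse(move, own + step * (reference - own), own), 0)
}

#' Advance the population one or more weekly steps
#'
#' Synchronous update: both references — the neighbour mean and the
#' (age x income x education) stratum mean — are computed from the
#' start-of-step snapshot of purchasing values. Each agent first adjusts
#' towards her social signal, then adjusts the result towards her social
#' norm, before any agent's new value becomes visible to others.
#'
#' @param population An `upf_population`.
#' @param network The matching igraph friendship network.
#' @param config A [dynamics_config()].
#' @param n_steps Number of weekly steps to run (default 1).
#' @return The population with updated `upf_kcal_week`.
#' @export
step_population <- function(population, network, config = dynamics_config(),
                            n_steps = 1) {
  n <- nrow(population)
  if (igraph::vcount(network) != n) {
    stop("Network and population sizes differ.", call. = FALSE)
  }
  op <- network_operator(network)
  strat <- compact_strata(population)
  x <- population$upf_kcal_week
  for (s in seq_len(n_steps)) {
    x <- step_values(x, op, strat, config)
  }
  population$upf_kcal_week <- x
  population
}

# occupied strata re-coded 1..G, with group sizes, for the hot loop
compact_strata <- function(population) {
  raw <- as.integer(stratum_index(population))
  g <- match(raw, sort(unique(raw)))
  list(g = g, size = tabulate(g, nbins = max(g)))
}

# one synchronous step on a raw value vector (hot loop for the runner)
step_values <- function(x, op, strat, config) {
  nb <- as.numeric(op$A %*% x) / op$deg
  nb[op$isolated] <- x[op$isolated]
  sm <- (rowsum(x, strat$g) / strat$size)[strat$g]
  x1 <- signal_adjustment(x, nb, config)
  signal_adjustment(x1, sm, config)
}
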
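#' Define a policy scenario
#'
#' A policy scenario is a (tax, label, advertising-change) triple with an
#' activation step. Taxes act through the own-price elasticity, the
#' front-of-package warning label through education-stratified purchasing
#' effects, and advertising changes through the advertising elasticity. The
#' scenario is applied once, as a level shift, at `activation_step`.
#'
#' @param tax_rate Ad-valorem UPF tax as a proportion (e.g. 0.20 for 20%).
#' @param label_active Logical; is the warning-label policy in force?
#' @param advertising_change Signed proportional change in UPF advertising in
#'   \[-1, 1\] (e.g. -0.50 for a 50% reduction).
#' @param activation_step Reporting-clock week at which the policy takes
#'   effect (default 52, i.e. one year in).
#' @param name Optional scenario label; a descriptive one is built if absent.
#' @return A list of class `"upf_policy_scenario"`.
#' @export
#' @examples
#' policy_scenario(tax_rate = 0.20)
#' policy_scenario(tax_rate = 0.50, label_active = TRUE,
#'                 advertising_change = -0.50)
policy_scenario <- function(tax_rate = 0, label_active = FALSE,
                            advertising_change = 0, activation_step = 52,
                            name = NULL) {
  if (tax_rate < 0) stop("`tax_rate` must be non-negative.", call. = FALSE)
  if (abs(advertising_change) > 1) {
    stop("`advertising_change` must lie in [-1, 1].", call. = FALSE)
  }
  if (activation_step < 1) {
    stop("`activation_step` must be a positive week index.", call. = FALSE)
  }
  if (is.null(name)) {
    bits <- c(
      if (tax_rate > 0) sprintf("tax%g", 100 * tax_rate),
      if (label_active) "label",
      if (advertising_change != 0) sprintf("adv%+g", 100 * advertising_change))
    name <- if (length(bits)) paste(bits, collapse = "_") else "no_policy"
  }
  structure(
    list(tax_rate = tax_rate, label_active = isTRUE(label_active),
         advertising_change = advertising_change,
         activation_step = as.integer(activation_step), name = name),
    class = "upf_policy_scenario")
}

#' Effect parameters for the policy operators
#'
#' @param price_elasticity Own-price elasticity of UPF purchasing (default
#'   -1.2: a 1% price rise lowers purchasing 1.2%).
#' @param label_effect Named numeric `c(low =, high =)`: proportional change
#'   in purchasing caused by the warning label, by education (defaults
#'   -0.22 low education, -0.29 high education).
#' @param advertising_elasticity Elasticity of purchasing with respect to
#'   advertising exposure (default 0.113).
#' @param composition `"multiplicative"` (default) composes the per-policy
#'   factors as a product; `"additive"` sums the proportional changes, kept
#'   for sensitivity analysis.
#' @return A list of class `"upf_effect_parameters"`.
#' @export
effect_parameters <- function(price_elasticity = -1.2,
                              label_effect = c(low = -0.22, high = -0.29),
                              advertising_elasticity = 0.113,
                              composition = c("multiplicative", "additive")) {
  composition <- match.arg(composition)
  if (price_elasticity >= 0) {
    stop("`price_elasticity` must be negative.", call. = FALSE)
  }
  if (!all(c("low", "high") %in% names(label_effect)) ||
      any(label_effect > 0) || any(label_effect <= -1)) {
    stop("`label_effect` needs `low` and `high` entries in (-1, 0].",
         call. = FALSE)
  }
  if (advertising_elasticity < 0) {
    stop("`advertising_elasticity` must be non-negative.", call. = FALSE)
  }
  structure(
    list(price_elasticity = price_elasticity,
         label_effect = label_effect[c("low", "high")],
         advertising_elasticity = advertising_elasticity,
         composition = composition),
    class = "upf_effect_parameters")
}

#' Price multiplier implied by a tax
#'
#' Linear (point) elasticity: a tax of rate `t` multiplies purchasing by
#' `1 + price_elasticity * t`. With the default elasticity -1.2 a 20% tax
#' gives 0.76.
#'
#' @param tax_rate Tax rate as a proportion.
#' @param params An [effect_parameters()].
#' @return Positive multiplier.
#' @export
price_factor <- function(tax_rate, params = effect_parameters()) {
  if (any(tax_rate < 0)) stop("`tax_rate` must be >= 0.", call. = FALSE)
  f <- 1 + params$price_elasticity * tax_rate
  if (any(f <= 0)) {
    stop("Tax rate large enough to drive purchasing non-positive under the ",
         "linear elasticity.", call. = FALSE)
  }
  f
}

#' Label multiplier by education
#'
#' @param education `"low"` / `"high"` (vectorised; factors accepted).
#' @param label_active Logical; inactive labels give 1.
#' @param params An [effect_parameters()].
#' @return Multiplier(s): with defaults, 0.78 for low and 0.71 for high
#'   education when active.
#' @export
label_factor <- function(education, label_active,
                         params = effect_parameters()) {
  education <- as.character(education)
  if (!all(education %in% c("low", "high"))) {
    stop("Unknown education level.", call. = FALSE)
  }
  if (!isTRUE(label_active)) return(rep(1, length(education)))
  1 + unname(params$label_effect[education])
}

#' Advertising multiplier
#'
#' @param advertising_change Signed proportional change in advertising.
#' @param params An [effect_parameters()].
#' @return Multiplier `1 + advertising_elasticity * advertising_change`.
#' @export
advertising_factor <- function(advertising_change,
                               params = effect_parameters()) {
  f <- 1 + params$advertising_elasticity * advertising_change
  if (any(f <= 0)) stop("Advertising factor must stay positive.",
                        call. = FALSE)
  f
}

#' Combined per-agent policy multiplier
#'
#' Composes the price, label and advertising effects. Under the default
#' multiplicative composition the per-agent multiplier is the product of the
#' three component factors (label varying by education); the additive variant
#' sums the three proportional changes instead.
#'
#' @param education Education level(s) (`"low"`/`"high"`), typically
#'   `population$education`.
#' @param scenario An [policy_scenario()].
#' @param params An [effect_parameters()].
#' @return Positive multiplier(s), one per education entry.
#' @export
#' @examples
#' combined_factor("high",
#'                 policy_scenario(0.50, TRUE, -0.50))  # 0.40*0.71*0.9435
combined_factor <- function(education, scenario,
                            params = effect_parameters()) {
  pf <- price_factor(scenario$tax_rate, params)
  lf <- label_factor(education, scenario$label_active, params)
  af <- advertising_factor(scenario$advertising_change, params)
  f <- if (params$composition == "multiplicative") {
    pf * lf * af
  } else {
    1 + (pf - 1) + (lf - 1) + (af - 1)
  }
  if (any(f <= 0)) stop("Combined policy factor must stay positive.",
                        call. = FALSE)
  f
}

#' Apply a policy scenario to a population
#'
#' Rescales every agent's weekly purchasing by her combined policy multiplier.
#' This is a one-time level shift applied at the activation step; the social
#' dynamics then continue on the shifted values. Re-applying a scenario to a
#' population it has already been applied to is an error.
#'
#' @param population An `upf_population`.
#' @param scenario An [policy_scenario()].
#' @param params An [effect_parameters()].
#' @return The population with rescaled `upf_kcal_week`.
#' @export
apply_policy <- function(population, scenario,
                         params = effect_parameters()) {
  applied <- attr(population, "policy_applied")
  if (!is.null(applied) && identical(applied, scenario$name)) {
    stop("Scenario '", scenario$name,
         "' has already been applied to this population.", call. = FALSE)
  }
  f <- combined_factor(population$education, scenario, params)
  population$upf_kcal_week <- pmax(population$upf_kcal_week * f, 0)
  attr(population, "policy_applied") <- scenario$name
  population
}
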
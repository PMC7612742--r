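#' Full scenario specification
#'
#' Bundles everything one simulated policy experiment needs: population,
#' network, dynamics and effect parameters, the policy scenario, the schedule
#' (burn-in steps, reporting steps, activation step) and the replication
#' plan. A run burns in `burn_in_steps` weeks of social dynamics (not
#' recorded), then records weeks `1..total_steps`, applying the policy once
#' immediately after week `policy$activation_step` is recorded.
#'
#' @param population A [population_config()].
#' @param network A [network_config()].
#' @param dynamics A [dynamics_config()].
#' @param effects An [effect_parameters()].
#' @param policy A [policy_scenario()].
#' @param burn_in_steps Burn-in weeks excluded from the reporting clock
#'   (default 100).
#' @param total_steps Recorded weeks (default 208, i.e. 4 years).
#' @param n_replicates Monte-Carlo replicates (default 200).
#' @param master_seed Master seed; per-replicate seeds are derived from it,
#'   so two scenarios sharing a master seed are paired replicate-by-replicate.
#' @return A list of class `"upf_scenario_config"`.
#' @export
scenario_config <- function(population = population_config(),
                            network = network_config(),
                            dynamics = dynamics_config(),
                            effects = effect_parameters(),
                            policy = policy_scenario(),
                            burn_in_steps = 100,
                            total_steps = 208,
                            n_replicates = 200,
                            master_seed = 1) {
  stopifnot(inherits(population, "upf_population_config"),
            inherits(network, "upf_network_config"),
            inherits(dynamics, "upf_dynamics_config"),
            inherits(effects, "upf_effect_parameters"),
            inherits(policy, "upf_policy_scenario"))
  if (policy$activation_step >= total_steps) {
    stop("`policy$activation_step` must be before `total_steps`.",
         call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1.", call. = FALSE)
  structure(
    list(population = population, network = network, dynamics = dynamics,
         effects = effects, policy = policy,
         burn_in_steps = as.integer(burn_in_steps),
         total_steps = as.integer(total_steps),
         n_replicates = as.integer(n_replicates),
         master_seed = as.integer(master_seed)),
    class = "upf_scenario_config")
}

# derive independent sub-seeds (population, network, ...) from one seed
derive_seeds <- function(seed, n) {
  withr_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Run a single simulation replicate
#'
#' Generates the population and network from sub-seeds of `replicate_seed`,
#' burns in the social dynamics, then records per-week population and stratum
#' summaries, applying the policy once after the activation week is recorded.
#'
#' @param config A [scenario_config()].
#' @param replicate_seed Integer seed for this replicate.
#' @return A tibble with one row per recorded week: `step`, `pop_mean`, and
#'   per-stratum sums and counts (`inc_low_sum`, `inc_low_n`, ..., by income
#'   category and education) from which any stratified mean can be rebuilt.
#' @export
run_replicate <- function(config, replicate_seed) {
  seeds <- derive_seeds(replicate_seed, 2)
  pop <- generate_population(config$population, seeds[1])
  net <- build_network(pop, config$network, seeds[2])
  op <- network_operator(net)
  strat <- compact_strata(pop)
  inc <- as.integer(pop$income_category)   # 1 = low, 2 = high
  edu <- as.integer(pop$education)
  pol_factor <- combined_factor(pop$education, config$policy, config$effects)
  dyn <- config$dynamics

  x <- pop$upf_kcal_week
  for (s in seq_len(config$burn_in_steps)) {
    x <- step_values(x, op, strat, dyn)
  }

  ts <- config$total_steps
  out <- matrix(0, nrow = ts, ncol = 9)
  colnames(out) <- c("pop_mean", "inc_low_sum", "inc_low_n", "inc_high_sum",
                     "inc_high_n", "edu_low_sum", "edu_low_n", "edu_high_sum",
                     "edu_high_n")
  inc_n <- tabulate(inc, 2); edu_n <- tabulate(edu, 2)
  for (t in seq_len(ts)) {
    x <- step_values(x, op, strat, dyn)
    if (!all(is.finite(x))) {
      stop("Non-finite purchasing at step ", t, ".", call. = FALSE)
    }
    inc_sum <- c(sum(x[inc == 1]), sum(x[inc == 2]))
    edu_sum <- c(sum(x[edu == 1]), sum(x[edu == 2]))
    out[t, ] <- c(mean(x), inc_sum[1], inc_n[1], inc_sum[2], inc_n[2],
                  edu_sum[1], edu_n[1], edu_sum[2], edu_n[2])
    if (t == config$policy$activation_step) {
      x <- pmax(x * pol_factor, 0)
    }
  }
  dplyr::bind_cols(tibble::tibble(step = seq_len(ts)),
                   tibble::as_tibble(out))
}

#' Run a replicated policy scenario
#'
#' Executes `n_replicates` independent replicates with seeds derived from
#' `master_seed` and aggregates them: the per-week population mean is the
#' average of replicate means (with its SD across replicates), and stratum
#' means are pooled over replicates (total kcal / total agents per stratum),
#' so size-weighted stratum means rebuild the population mean exactly.
#'
#' @param config A [scenario_config()].
#' @return An object of class `"upf_run"`: a list with `steps` (per-week
#'   tibble), `summary` (one-row tibble with the pre-policy week, final week,
#'   percent change and income-gap statistics), `scenario` name, `config` and
#'   `replicate_seeds`. Use [tidy()][generics::tidy] / [glance()] /
#'   [autoplot()] on it.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "upf_scenario_config"))
  rep_seeds <- derive_seeds(config$master_seed, config$n_replicates)
  reps <- purrr::map(seq_along(rep_seeds), function(r) {
    res <- tryCatch(run_replicate(config, rep_seeds[r]),
                    error = function(e) {
                      stop("Replicate ", r, " (seed ", rep_seeds[r],
                           ") failed: ", conditionMessage(e), call. = FALSE)
                    })
    res$replicate <- r
    res
  })
  all <- dplyr::bind_rows(reps)
  steps <- all |>
    dplyr::summarise(
      mean = mean(.data$pop_mean),
      sd = stats::sd(.data$pop_mean),
      income_low = sum(.data$inc_low_sum) / sum(.data$inc_low_n),
      income_high = sum(.data$inc_high_sum) / sum(.data$inc_high_n),
      edu_low = sum(.data$edu_low_sum) / sum(.data$edu_low_n),
      edu_high = sum(.data$edu_high_sum) / sum(.data$edu_high_n),
      n_income_low = sum(.data$inc_low_n) / dplyr::n_distinct(.data$replicate),
      n_income_high = sum(.data$inc_high_n) /
        dplyr::n_distinct(.data$replicate),
      .by = "step")
  a <- config$policy$activation_step
  ts <- config$total_steps
  summary <- tibble::tibble(
    scenario = config$policy$name,
    pre_step = a, final_step = ts,
    mean_pre = steps$mean[a], mean_final = steps$mean[ts],
    pct_change = 100 * (steps$mean[a] - steps$mean[ts]) / steps$mean[a],
    gap_absolute_pre = income_gap(steps, a)$absolute,
    gap_relative_pre = income_gap(steps, a)$relative,
    gap_absolute_final = income_gap(steps, ts)$absolute,
    gap_relative_final = income_gap(steps, ts)$relative)
  structure(
    list(steps = steps, summary = summary, scenario = config$policy$name,
         config = config, replicate_seeds = rep_seeds),
    class = "upf_run")
}

# absolute and relative income-strata gap at one recorded step; the relative
# gap is expressed against the larger stratum mean
income_gap <- function(steps, step) {
  row <- steps[steps$step == step, ]
  if (nrow(row) != 1) stop("Step ", step, " not in the result.",
                           call. = FALSE)
  lo <- row$income_low; hi <- row$income_high
  list(absolute = abs(lo - hi),
       relative = 100 * abs(lo - hi) / max(lo, hi))
}

#' @export
print.upf_run <- function(x, ...) {
  s <- x$summary
  cat("<upf_run> scenario:", x$scenario, "\n")
  cat(sprintf("  replicates: %d   weeks: %d (policy at %d)\n",
              x$config$n_replicates, x$config$total_steps,
              x$config$policy$activation_step))
  cat(sprintf("  mean kcal/week: %.1f (week %d) -> %.1f (week %d), change %+.1f%%\n",
              s$mean_pre, s$pre_step, s$mean_final, s$final_step,
              -s$pct_change))
  cat(sprintf("  income gap: %.0f kcal (%.1f%%) -> %.0f kcal (%.1f%%)\n",
              s$gap_absolute_pre, s$gap_relative_pre,
              s$gap_absolute_final, s$gap_relative_final))
  invisible(x)
}

#' Run a grid of policy scenarios with paired seeds
#'
#' Builds the cartesian product of tax rates, label switches and advertising
#' levels, runs every cell with the same master seed (so pre-policy
#' trajectories are identical across cells and differences are pure policy
#' effects), and returns a tidy summary with the full results attached.
#'
#' @param base_config A [scenario_config()] supplying everything but the
#'   policy triple.
#' @param taxes Numeric vector of tax rates.
#' @param label_options Logical vector of label switches.
#' @param advertising_levels Numeric vector of advertising changes.
#' @return A tibble with one row per scenario: the policy triple, the glance
#'   summary columns and a `result` list-column of `upf_run` objects.
#' @export
scenario_grid <- function(base_config, taxes = 0,
                          label_options = FALSE,
                          advertising_levels = 0) {
  stopifnot(length(taxes) > 0, length(label_options) > 0,
            length(advertising_levels) > 0)
  cells <- tidyr::expand_grid(tax_rate = taxes, label = label_options,
                              advertising = advertising_levels)
  cells$scenario <- purrr::pmap_chr(cells, function(tax_rate, label,
                                                    advertising) {
    policy_scenario(tax_rate, label, advertising)$name
  })
  if (anyDuplicated(cells$scenario)) {
    stop("Duplicate scenario names in the grid.", call. = FALSE)
  }
  cells$result <- purrr::pmap(
    cells[c("tax_rate", "label", "advertising")],
    function(tax_rate, label, advertising) {
      cfg <- base_config
      cfg$policy <- policy_scenario(
        tax_rate, label, advertising,
        activation_step = base_config$policy$activation_step)
      run_scenario(cfg)
    })
  summaries <- dplyr::bind_rows(purrr::map(cells$result, "summary"))
  dplyr::bind_cols(cells[c("scenario", "tax_rate", "label", "advertising")],
                   summaries[setdiff(names(summaries), "scenario")])  |>
    dplyr::mutate(result = cells$result)
}

#' Income-equity gap table for the two social-transition stages
#'
#' Compares the absolute and relative income-strata gaps, at a chosen week,
#' between a pre-transition and a post-transition run of the same policy,
#' alongside the pre-policy gaps, to show whether the policy narrows or
#' widens social differences in UPF purchasing.
#'
#' @param result_pre,result_post `upf_run` objects for the pre- and
#'   post-transition baseline scenarios under the same policy.
#' @param step Reporting week at which to evaluate the gap (default 208).
#' @return A tibble with one row per transition stage: gaps at the policy
#'   activation week and at `step`, plus their changes.
#' @export
equity_report <- function(result_pre, result_post, step = 208) {
  one <- function(res, stage) {
    if (!step %in% res$steps$step) {
      stop("Step ", step, " out of range for the ", stage, " result.",
           call. = FALSE)
    }
    a <- res$config$policy$activation_step
    g0 <- income_gap(res$steps, a)
    g1 <- income_gap(res$steps, step)
    tibble::tibble(
      stage = stage, scenario = res$scenario, step = step,
      gap_absolute_pre = g0$absolute, gap_relative_pre = g0$relative,
      gap_absolute = g1$absolute, gap_relative = g1$relative,
      gap_absolute_change = g1$absolute - g0$absolute,
      gap_relative_change = g1$relative - g0$relative)
  }
  dplyr::bind_rows(one(result_pre, "pre_transition"),
                   one(result_post, "post_transition"))
}
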
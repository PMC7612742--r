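#' Configuration for the synthetic agent population
#'
#' Defines the socio-demographic structure of the simulated population of
#' adult female household food purchasers: fixed age-group and education
#' proportions, log-normal household income distributions by education
#' (parameterised on the natural scale in pesos/week), an income threshold
#' splitting agents into low/high income categories, and baseline weekly
#' ultra-processed-food (UPF) purchasing means by income category.
#'
#' Two baseline scenarios encode opposite stages of the social transition in
#' UPF purchasing: `"pre_transition"` (high-income households purchase more
#' UPF, as in Mexico) and `"post_transition"` (low-income households purchase
#' more, as in Chile). Baseline purchasing is drawn from a log-normal with the
#' configured income-group mean and coefficient of variation
#' `baseline_dispersion`.
#'
#' @param n_agents Number of agents (default 1000).
#' @param age_proportions Named numeric of length 3 over
#'   `c("younger", "middle", "older")`; must sum to 1.
#' @param p_high_education Proportion of agents with at least a high-school
#'   education (default 0.27).
#' @param income_low_ed,income_high_ed Named numeric `c(mean =, sd =)` of the
#'   weekly household income distribution (pesos/week, natural scale) for the
#'   low- and high-education groups.
#' @param income_threshold Income (pesos/week) strictly above which an agent is
#'   classed as high income (default 1890).
#' @param scenario `"pre_transition"` or `"post_transition"`.
#' @param baseline_mean_by_income Named numeric `c(low =, high =)` of baseline
#'   mean UPF purchasing (kcal/week) per income category. Defaults depend on
#'   `scenario`: pre-transition `c(low = 2966, high = 3446)`, post-transition
#'   `c(low = 3100, high = 2620)`.
#' @param baseline_dispersion Coefficient of variation of the baseline
#'   purchasing draw (default 0.30).
#'
#' @return A list of class `"upf_population_config"`.
#' @export
#' @examples
#' cfg <- population_config(n_agents = 100)
#' pop <- generate_population(cfg, seed = 1)
population_config <- function(n_agents = 1000,
                              age_proportions = c(younger = 0.25,
                                                  middle = 0.50,
                                                  older = 0.25),
                              p_high_education = 0.27,
                              income_low_ed = c(mean = 889, sd = 911),
                              income_high_ed = c(mean = 2044, sd = 2225),
                              income_threshold = 1890,
                              scenario = c("pre_transition", "post_transition"),
                              baseline_mean_by_income = NULL,
                              baseline_dispersion = 0.30) {
  scenario <- match.arg(scenario)
  if (length(n_agents) != 1 || !is.finite(n_agents) || n_agents < 1) {
    stop("`n_agents` must be a positive integer.", call. = FALSE)
  }
  n_agents <- as.integer(n_agents)
  if (length(age_proportions) != 3 || any(age_proportions < 0)) {
    stop("`age_proportions` must be three non-negative proportions.",
         call. = FALSE)
  }
  if (abs(sum(age_proportions) - 1) > 1e-9) {
    stop("`age_proportions` must sum to 1.", call. = FALSE)
  }
  if (is.null(names(age_proportions))) {
    names(age_proportions) <- c("younger", "middle", "older")
  }
  if (p_high_education < 0 || p_high_education > 1) {
    stop("`p_high_education` must be a proportion in [0, 1].", call. = FALSE)
  }
  for (nm in c("income_low_ed", "income_high_ed")) {
    v <- get(nm)
    if (length(v) != 2 || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("`%s` must be positive c(mean =, sd =).", nm),
           call. = FALSE)
    }
  }
  if (income_threshold <= 0) {
    stop("`income_threshold` must be strictly positive.", call. = FALSE)
  }
  if (is.null(baseline_mean_by_income)) {
    baseline_mean_by_income <- switch(scenario,
      pre_transition  = c(low = 2966, high = 3446),
      post_transition = c(low = 3100, high = 2620))
  }
  if (!all(c("low", "high") %in% names(baseline_mean_by_income)) ||
      any(baseline_mean_by_income <= 0)) {
    stop("`baseline_mean_by_income` needs positive `low` and `high` entries.",
         call. = FALSE)
  }
  if (baseline_dispersion <= 0) {
    stop("`baseline_dispersion` must be strictly positive.", call. = FALSE)
  }
  structure(
    list(n_agents = n_agents,
         age_proportions = age_proportions,
         p_high_education = p_high_education,
         income_low_ed = c(mean = unname(income_low_ed[1]),
                           sd = unname(income_low_ed[2])),
         income_high_ed = c(mean = unname(income_high_ed[1]),
                            sd = unname(income_high_ed[2])),
         income_threshold = income_threshold,
         scenario = scenario,
         baseline_mean_by_income = baseline_mean_by_income[c("low", "high")],
         baseline_dispersion = baseline_dispersion),
    class = "upf_population_config")
}

#' Convert natural-scale moments to log-normal parameters
#'
#' Given the mean and standard deviation of a log-normal variable on the
#' natural scale, returns the `meanlog` and `sdlog` parameters such that the
#' implied analytic mean and SD reproduce the inputs exactly.
#'
#' @param mean,sd Positive natural-scale mean and standard deviation.
#' @return A list with elements `meanlog` and `sdlog`.
#' @export
#' @examples
#' p <- moments_to_lognormal(889, 911)
#' exp(p$meanlog + p$sdlog^2 / 2)  # 889
moments_to_lognormal <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Largest-remainder apportionment of counts to proportions
#'
#' Deterministically rounds `n * proportions` to integer counts that sum to
#' `n`, giving the extra units to the cells with the largest fractional
#' remainders (ties broken by cell order).
#'
#' @param n Total count.
#' @param proportions Non-negative numeric summing to 1.
#' @return Integer vector of counts, same names as `proportions`.
#' @export
largest_remainder <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    rem <- raw - counts
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

#' Assign income category by threshold
#'
#' An agent is high income iff her continuous income strictly exceeds the
#' threshold; an income exactly at the threshold is classed low.
#'
#' @param income Positive income(s), pesos/week.
#' @param threshold Positive threshold, pesos/week (default 1890).
#' @return Character vector of `"low"` / `"high"`.
#' @export
#' @examples
#' income_category(c(500, 1890, 2500))
income_category <- function(income, threshold = 1890) {
  if (any(!is.finite(income)) || any(income <= 0)) {
    stop("`income` must be strictly positive.", call. = FALSE)
  }
  if (threshold <= 0) stop("`threshold` must be positive.", call. = FALSE)
  ifelse(income > threshold, "high", "low")
}

age_levels <- c("younger", "middle", "older")
edu_levels <- c("low", "high")

#' Generate the synthetic agent population
#'
#' Creates `n_agents` agents with exact category counts (largest-remainder
#' rounding of the configured proportions, so the default 1000-agent
#' population has exactly 270 high-education, 250 younger, 500 middle and 250
#' older agents), log-normal incomes matched to the configured natural-scale
#' mean/SD per education group, income categories by threshold, and baseline
#' weekly UPF purchasing drawn log-normally per income category with
#' coefficient of variation `baseline_dispersion`.
#'
#' Age group and education are assigned independently (categories are
#' shuffled against each other), matching a population where the two margins
#' are specified but no joint structure is.
#'
#' @param config A [population_config()].
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A tibble of class `"upf_population"` with columns `id`,
#'   `age_group`, `education`, `income`, `income_category`, `upf_kcal_week`.
#'   The config is kept in attribute `"config"`.
#' @export
generate_population <- function(config, seed) {
  stopifnot(inherits(config, "upf_population_config"))
  n <- config$n_agents
  withr_seed(seed, {
    age_counts <- largest_remainder(n, config$age_proportions)
    age_group <- sample(rep(age_levels, times = age_counts))
    edu_counts <- largest_remainder(
      n, c(low = 1 - config$p_high_education, high = config$p_high_education))
    education <- sample(rep(edu_levels, times = edu_counts))

    income <- numeric(n)
    for (ed in edu_levels) {
      idx <- which(education == ed)
      mom <- if (ed == "low") config$income_low_ed else config$income_high_ed
      lp <- moments_to_lognormal(mom[["mean"]], mom[["sd"]])
      income[idx] <- stats::rlnorm(length(idx), lp$meanlog, lp$sdlog)
    }
    inc_cat <- income_category(income, config$income_threshold)

    upf <- numeric(n)
    cv <- config$baseline_dispersion
    for (ic in c("low", "high")) {
      idx <- which(inc_cat == ic)
      m <- config$baseline_mean_by_income[[ic]]
      lp <- moments_to_lognormal(m, cv * m)
      upf[idx] <- stats::rlnorm(length(idx), lp$meanlog, lp$sdlog)
    }
    upf <- pmax(upf, 0)

    pop <- tibble::tibble(
      id = seq_len(n),
      age_group = factor(age_group, levels = age_levels),
      education = factor(education, levels = edu_levels),
      income = income,
      income_category = factor(inc_cat, levels = edu_levels),
      upf_kcal_week = upf)
    attr(pop, "config") <- config
    class(pop) <- c("upf_population", class(pop))
    pop
  })
}

# run code with a temporarily-set RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Mean UPF purchasing per (age, income, education) stratum
#'
#' Social norms operate over agents sharing age group, income category and
#' education; this returns the mean weekly purchasing of every occupied
#' stratum. Empty strata are absent.
#'
#' @param population An `upf_population` tibble.
#' @param values Optional numeric vector to average instead of the
#'   population's current `upf_kcal_week` (used by the dynamics to evaluate
#'   norms on a start-of-step snapshot).
#' @return A tibble with columns `age_group`, `income_category`, `education`,
#'   `n`, `mean_kcal`.
#' @export
stratum_means <- function(population, values = NULL) {
  if (nrow(population) == 0) stop("Population is empty.", call. = FALSE)
  x <- if (is.null(values)) population$upf_kcal_week else values
  stopifnot(length(x) == nrow(population))
  population |>
    dplyr::mutate(.x = x) |>
    dplyr::summarise(n = dplyr::n(), mean_kcal = mean(.data$.x),
                     .by = c("age_group", "income_category", "education"))
}

# integer stratum index for fast per-step norm computation
stratum_index <- function(population) {
  interaction(population$age_group, population$income_category,
              population$education, drop = FALSE)
}

#' Export a population as CSV
#'
#' @param population An `upf_population`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_population_csv <- function(population, path) {
  utils::write.csv(as.data.frame(population), path, row.names = FALSE)
  invisible(path)
}
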
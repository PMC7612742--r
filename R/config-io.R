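#' Read a scenario configuration from a YAML or JSON file
#'
#' The document mirrors [scenario_config()]: top-level sections `population`,
#' `network`, `dynamics`, `effects`, `policy` (each holding the arguments of
#' the corresponding constructor) plus scalar fields `burn_in_steps`,
#' `total_steps`, `n_replicates`, `master_seed`. Missing sections or fields
#' fall back to the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  scenario_config_from_list(doc)
}

#' Build a scenario configuration from a plain list
#'
#' @param doc A nested list as produced by parsing a config document.
#' @return A [scenario_config()].
#' @export
scenario_config_from_list <- function(doc) {
  build <- function(ctor, section) {
    args <- doc[[section]] %||% list()
    vec_args <- c("age_proportions", "income_low_ed", "income_high_ed",
                  "baseline_mean_by_income", "label_effect")
    for (v in intersect(names(args), vec_args)) args[[v]] <- unlist(args[[v]])
    do.call(ctor, args)
  }
  scalars <- list(
    burn_in_steps = doc$burn_in_steps %||% 100,
    total_steps = doc$total_steps %||% 208,
    n_replicates = doc$n_replicates %||% 200,
    master_seed = doc$master_seed %||% 1)
  do.call(scenario_config, c(
    list(population = build(population_config, "population"),
         network = build(network_config, "network"),
         dynamics = build(dynamics_config, "dynamics"),
         effects = build(effect_parameters, "effects"),
         policy = build(policy_scenario, "policy")),
    scalars))
}

#' Named policy presets for the reported scenario grid
#'
#' Every combination reported for the counterfactual experiments: taxes of
#' 0/8/20/50%, label on/off, and advertising changes of -50/-25/0/+25/+50%,
#' plus shorthand names for the headline single and combined policies.
#'
#' @return A named list of [policy_scenario()] objects.
#' @export
policy_presets <- function() {
  headline <- list(
    no_policy   = policy_scenario(0,    FALSE, 0),
    tax8        = policy_scenario(0.08, FALSE, 0),
    tax20       = policy_scenario(0.20, FALSE, 0),
    tax50       = policy_scenario(0.50, FALSE, 0),
    label       = policy_scenario(0,    TRUE,  0),
    adv_plus50  = policy_scenario(0,    FALSE, 0.50),
    adv_minus50 = policy_scenario(0,    FALSE, -0.50),
    tax8_label  = policy_scenario(0.08, TRUE,  0),
    tax8_label_adv_plus25 = policy_scenario(0.08, TRUE, 0.25),
    tax50_label = policy_scenario(0.50, TRUE,  0),
    all_max     = policy_scenario(0.50, TRUE,  -0.50),
    tax50_label_adv_plus50 = policy_scenario(0.50, TRUE, 0.50))
  grid <- tidyr::expand_grid(tax = c(0, 0.08, 0.20, 0.50),
                             label = c(FALSE, TRUE),
                             adv = c(-0.50, -0.25, 0, 0.25, 0.50))
  full <- purrr::pmap(grid, function(tax, label, adv) {
    policy_scenario(tax, label, adv)
  })
  names(full) <- purrr::map_chr(full, "name")
  c(headline, full[setdiff(names(full), purrr::map_chr(headline, "name"))])
}

#' Write a run result to tidy CSV and a JSON summary
#'
#' @param run An `upf_run`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; defaults to the scenario name.
#' @return Paths of the files written, invisibly.
#' @export
export_run <- function(run, dir, stem = run$scenario) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, "_steps.csv"))
  js <- file.path(dir, paste0(stem, "_summary.json"))
  utils::write.csv(as.data.frame(tidy(run)), csv, row.names = FALSE)
  jsonlite::write_json(as.list(run$summary), js, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(csv, js))
}

#' Export a network edge list as CSV
#'
#' @param network An igraph network.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_edgelist_csv <- function(network, path) {
  el <- igraph::as_edgelist(network)
  utils::write.csv(data.frame(from = el[, 1], to = el[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}
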
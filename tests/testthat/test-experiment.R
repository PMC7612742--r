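test_that("frozen dynamics and no policy give flat trajectories", {
  cfg <- tiny_config()
  cfg$dynamics <- dynamics_config(conformity_resistance = 0)
  cfg$policy <- policy_scenario(0, FALSE, 0, activation_step = 15)
  tr <- run_replicate(cfg, 99)
  expect_equal(length(unique(round(tr$pop_mean, 9))), 1)
  expect_equal(nrow(tr), cfg$total_steps)
})

test_that("a single replicate aggregates to itself", {
  cfg <- tiny_config(n_replicates = 1)
  run <- run_scenario(cfg)
  tr <- run_replicate(cfg, run$replicate_seeds[1])
  expect_equal(run$steps$mean, tr$pop_mean)
  expect_equal(run$steps$income_low, tr$inc_low_sum / tr$inc_low_n)
  expect_true(all(is.na(run$steps$sd)))
})

test_that("size-weighted stratum means rebuild the population mean at every step", {
  run <- run_scenario(tiny_config(n_replicates = 3))
  st <- run$steps
  rebuilt <- (st$income_low * st$n_income_low +
                st$income_high * st$n_income_high) /
    (st$n_income_low + st$n_income_high)
  expect_equal(rebuilt, st$mean, tolerance = 1e-6)
})

test_that("runs are deterministic and pre-policy trajectories are seed-paired", {
  cfg_tax <- tiny_config(policy = policy_scenario(0.2, activation_step = 15))
  r1 <- run_scenario(cfg_tax)
  r2 <- run_scenario(cfg_tax)
  expect_identical(r1$steps, r2$steps)

  cfg_lab <- tiny_config(policy = policy_scenario(0, TRUE,
                                                  activation_step = 15))
  r3 <- run_scenario(cfg_lab)
  pre <- r1$steps$step <= 15
  expect_identical(r1$steps$mean[pre], r3$steps$mean[pre])
  expect_false(identical(r1$steps$mean[!pre], r3$steps$mean[!pre]))
})

test_that("a mid-run tax shifts the mean by about the price factor", {
  cfg <- tiny_config(n_agents = 300, n_replicates = 3,
                     policy = policy_scenario(0.2, activation_step = 15))
  run <- run_scenario(cfg)
  s <- glance(run)
  expect_equal(s$mean_final / s$mean_pre, 0.76, tolerance = 0.01)
  expect_equal(s$pct_change, 24, tolerance = 1)
})

test_that("scenario grids enumerate cells, pair seeds, and order by tax", {
  base <- tiny_config(n_agents = 200, n_replicates = 2)
  grid <- scenario_grid(base, taxes = c(0, 0.2, 0.5),
                        label_options = c(FALSE, TRUE),
                        advertising_levels = 0)
  expect_equal(nrow(grid), 6)
  expect_setequal(
    grid$scenario,
    c("no_policy", "label", "tax20", "tax20_label", "tax50", "tax50_label"))

  # no-policy cell is stable between the activation and final weeks
  np <- grid[grid$scenario == "no_policy", ]
  expect_lt(abs(np$mean_final - np$mean_pre),
            2 * max(np$result[[1]]$steps$sd) + 5)

  # reductions increase with the tax at fixed label setting
  for (lab in c(FALSE, TRUE)) {
    sub <- grid[grid$label == lab, ]
    sub <- sub[order(sub$tax_rate), ]
    expect_true(all(diff(sub$pct_change) > 0))
  }
  expect_error(scenario_grid(base, taxes = c(0.2, 0.2)), "Duplicate")
})

test_that("equity gaps match their printed-definition arithmetic", {
  fake_run <- function(lo, hi, scenario = "label") {
    steps <- tibble::tibble(step = c(52, 208),
                            mean = c(3100, (lo + hi) / 2), sd = 0,
                            income_low = c(3000, lo),
                            income_high = c(2900, hi),
                            edu_low = 0, edu_high = 0,
                            n_income_low = 800, n_income_high = 200)
    structure(list(steps = steps, scenario = scenario,
                   config = list(policy = policy_scenario(
                     0, TRUE, 0, activation_step = 52))),
              class = "upf_run")
  }
  # identical stratum means: zero gap
  eq <- equity_report(fake_run(2500, 2500), fake_run(2500, 2500), step = 208)
  expect_equal(eq$gap_absolute, c(0, 0))
  expect_equal(eq$gap_relative, c(0, 0))

  # the worked 138-kcal example: relative gap against the larger mean
  eq <- equity_report(fake_run(3000, 2862), fake_run(3000, 2862), step = 208)
  expect_equal(eq$gap_absolute[1], 138)
  expect_equal(eq$gap_relative[1], 100 * 138 / 3000, tolerance = 1e-9)
  expect_equal(round(eq$gap_relative[1], 1), 4.6)
  expect_error(equity_report(fake_run(1, 1), fake_run(1, 1), step = 999),
               "out of range")
})

test_that("gap statistics agree with brute-force recomputation from agent export", {
  cfg <- tiny_config(n_agents = 200, n_replicates = 1)
  cfg$dynamics <- dynamics_config(conformity_resistance = 0)
  run <- run_scenario(cfg)
  # with frozen dynamics the final state is the policy-scaled initial draw;
  # recompute the gap directly from the exported agent table
  seeds <- upfsim:::derive_seeds(run$replicate_seeds[1], 2)
  pop <- generate_population(cfg$population, seeds[1])
  pop <- apply_policy(pop, cfg$policy, cfg$effects)
  path <- tempfile(fileext = ".csv")
  export_population_csv(pop, path)
  agents <- utils::read.csv(path)
  g <- tapply(agents$upf_kcal_week, agents$income_category, mean)
  expect_equal(upfsim:::income_gap(run$steps, cfg$total_steps)$absolute,
               abs(g[["low"]] - g[["high"]]), tolerance = 1e-8)
})

test_that("tidiers, autoplot and exports produce well-formed output", {
  run <- run_scenario(tiny_config(n_replicates = 2))
  td <- tidy(run)
  expect_setequal(unique(td$stratum),
                  c("population", "income_low", "income_high",
                    "edu_low", "edu_high"))
  expect_equal(nrow(td), 5 * run$config$total_steps)
  expect_s3_class(glance(run), "tbl_df")
  p <- autoplot(run, strata = "income")
  expect_s3_class(p, "ggplot")
  dir <- tempfile()
  files <- export_run(run, dir)
  expect_true(all(file.exists(file.path(
    dir, c(paste0(run$scenario, "_steps.csv"),
           paste0(run$scenario, "_summary.json"))))))
})

test_that("scenario configs round-trip through YAML", {
  doc <- list(
    population = list(n_agents = 150, scenario = "post_transition"),
    network = list(homophily_weight = 3),
    dynamics = list(conformity_resistance = 0.8),
    policy = list(tax_rate = 0.08, label_active = TRUE,
                  activation_step = 52),
    n_replicates = 4, master_seed = 9)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, path)
  cfg <- read_scenario_config(path)
  expect_s3_class(cfg, "upf_scenario_config")
  expect_equal(cfg$population$n_agents, 150L)
  expect_equal(cfg$population$baseline_mean_by_income[["low"]], 3100)
  expect_equal(cfg$network$homophily_weight, 3)
  expect_equal(cfg$dynamics$conformity_resistance, 0.8)
  expect_equal(cfg$policy$name, "tax8_label")
  expect_equal(cfg$n_replicates, 4L)
  expect_equal(cfg$burn_in_steps, 100L)

  presets <- policy_presets()
  expect_true(all(c("no_policy", "tax20", "all_max") %in% names(presets)))
  expect_equal(presets$all_max$tax_rate, 0.5)
  expect_true(presets$all_max$label_active)
  expect_equal(presets$all_max$advertising_change, -0.5)
})
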
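# calibration unit tests run at reduced scale (small populations, few
# replicates, short windows); the full-scale criteria live in the
# acceptance tests

small_cal_config <- function(scenario = "pre_transition", seed = 101) {
  scenario_config(
    population = population_config(n_agents = 250, scenario = scenario),
    burn_in_steps = 40, master_seed = seed)
}

test_that("with conformity switched off the equilibrium equals the initial mean", {
  cfg <- small_cal_config()
  ev <- evaluate_candidate(list(conformity_resistance = 0), cfg,
                           calibration_targets(), n_runs = 3, seed = 11)
  seeds <- upfsim:::derive_seeds(11, 3)
  init_means <- vapply(seeds, function(s) {
    ps <- upfsim:::derive_seeds(s, 2)
    mean(generate_population(cfg$population, ps[1])$upf_kcal_week)
  }, numeric(1))
  expect_equal(ev$mean, mean(init_means), tolerance = 1e-9)
  expect_true(ev$ordering_ok)
})

test_that("income-group ordering holds under both transition stages", {
  pre <- evaluate_candidate(list(), small_cal_config("pre_transition"),
                            calibration_targets(ordering = "pre"),
                            n_runs = 4, seed = 2)
  expect_true(pre$ordering_ok)
  expect_true(all(pre$gap_trajectory$signed_gap > 0))
  post <- evaluate_candidate(list(), small_cal_config("post_transition"),
                             calibration_targets(ordering = "post"),
                             n_runs = 4, seed = 2)
  expect_true(post$ordering_ok)
  expect_true(all(post$gap_trajectory$signed_gap < 0))
})

test_that("an infinite tolerance accepts the first candidate", {
  cfg <- small_cal_config()
  cal <- calibrate(cfg, calibration_targets(tolerance = Inf),
                   search_spec = list(homophily_weight = c(3, 7),
                                      conformity_resistance = 1),
                   n_runs = 2, seed = 5)
  expect_equal(cal$evaluations, 1L)
  expect_equal(cal$parameters$homophily_weight, 3)
})

test_that("baseline rescaling recovers an arbitrary target under frozen dynamics", {
  # conformity 0 freezes the dynamics, so the equilibrium mean equals the
  # initial mean and scales exactly with the baseline means: calibration
  # must find the scale mapping it onto any requested target
  cfg <- small_cal_config()
  target <- 2500
  cal <- calibrate(cfg,
                   calibration_targets(population_mean = target,
                                       tolerance = 5),
                   search_spec = list(homophily_weight = 5,
                                      conformity_resistance = 0),
                   n_runs = 3, seed = 11)
  expect_lte(abs(cal$achieved_mean - target), 5)
  ev0 <- evaluate_candidate(list(conformity_resistance = 0), cfg,
                            calibration_targets(), n_runs = 3, seed = 11)
  expect_equal(cal$parameters$baseline_scale, target / ev0$mean,
               tolerance = 0.01)
})

test_that("full mixing fails the distinctness negative control", {
  cfg <- small_cal_config()
  cfg$dynamics <- dynamics_config(perception_threshold = 0,
                                  adjustment_fraction = 0.5)
  expect_error(
    calibrate(cfg,
              calibration_targets(distinctness_margin = 25),
              search_spec = list(homophily_weight = 0,
                                 conformity_resistance = 1),
              n_runs = 2, seed = 3),
    "ordering and distinctness")
})

test_that("candidate evaluation is deterministic given the seed", {
  cfg <- small_cal_config()
  e1 <- evaluate_candidate(list(homophily_weight = 4), cfg,
                           calibration_targets(), n_runs = 2, seed = 42)
  e2 <- evaluate_candidate(list(homophily_weight = 4), cfg,
                           calibration_targets(), n_runs = 2, seed = 42)
  expect_identical(e1$mean, e2$mean)
  expect_identical(e1$gap_trajectory, e2$gap_trajectory)
})
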
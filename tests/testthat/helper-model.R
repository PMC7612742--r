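# Shared fixtures: hand-built miniature populations/graphs for oracle tests,
# and a small fast scenario configuration.

# population tibble built directly from vectors (all invariants supplied by
# the caller) so dynamics can be tested on exactly-known instances
make_pop <- function(upf, age = "middle", edu = "low", inc = "low",
                     income = 1000) {
  n <- length(upf)
  pop <- tibble::tibble(
    id = seq_len(n),
    age_group = factor(rep_len(age, n),
                       levels = c("younger", "middle", "older")),
    education = factor(rep_len(edu, n), levels = c("low", "high")),
    income = rep_len(income, n),
    income_category = factor(rep_len(inc, n), levels = c("low", "high")),
    upf_kcal_week = as.numeric(upf))
  class(pop) <- c("upf_population", class(pop))
  pop
}

# ring graph on n nodes (each node tied to its two ring neighbours)
ring_graph <- function(n) igraph::make_ring(n)

# the linear one-step operator of the dynamics with threshold 0 and a single
# stratum: first sub-update rows (1-f)I + f D^-1 A, then mixing with the
# snapshot stratum mean (computed from the start-of-step values)
linear_step_matrix <- function(g, f) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  M1 <- (1 - f) * diag(n) + f * A / rowSums(A)
  (1 - f) * M1 + f * matrix(1 / n, n, n)
}

mat_pow <- function(M, k) {
  out <- diag(nrow(M))
  for (i in seq_len(k)) out <- out %*% M
  out
}

# small, fast scenario config for experiment-level unit tests
tiny_config <- function(n_agents = 120, n_replicates = 2, master_seed = 7,
                        policy = policy_scenario(activation_step = 15),
                        burn_in = 20, total = 40, ...) {
  scenario_config(
    population = population_config(n_agents = n_agents, ...),
    network = network_config(),
    policy = policy,
    burn_in_steps = burn_in, total_steps = total,
    n_replicates = n_replicates, master_seed = master_seed)
}
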
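test_that("edge count pins the mean degree and bounds hold at every node", {
  pop <- generate_population(population_config(n_agents = 400), 1)
  cfg <- network_config()
  for (seed in c(2, 17, 300)) {
    g <- build_network(pop, cfg, seed)
    expect_equal(2 * igraph::ecount(g) / igraph::vcount(g),
                 round(5.47 * 400 / 2) * 2 / 400)
    deg <- igraph::degree(g)
    expect_gte(min(deg), 3)
    expect_lte(max(deg), 50)
    expect_equal(igraph::vcount(g), 400)
    expect_false(igraph::any_multiple(g) || any(igraph::which_loop(g)))
  }
})

test_that("generation is reproducible and rejects infeasible inputs", {
  pop <- generate_population(population_config(n_agents = 150), 4)
  g1 <- build_network(pop, network_config(), 9)
  g2 <- build_network(pop, network_config(), 9)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  g3 <- build_network(pop, network_config(), 10)
  expect_false(identical(igraph::as_edgelist(g1), igraph::as_edgelist(g3)))
  expect_error(build_network(pop[1:3, ], network_config(), 1), "smaller")
  expect_error(network_config(min_degree = 10, target_mean_degree = 5),
               "min_degree")
})

test_that("metrics match closed forms on known graphs", {
  # complete graph on 5 nodes
  pop5 <- make_pop(rep(3000, 5))
  k5 <- igraph::make_full_graph(5)
  m <- network_metrics(k5, pop5)
  expect_equal(m$mean_degree, 4)
  expect_equal(m$clustering, 1)
  expect_equal(m$mean_path_length, 1)

  # pure ring lattice (target degree 4, no rewiring): clustering 1/2 and
  # mean path length from the circulant-distance enumeration oracle
  popn <- generate_population(population_config(n_agents = 20), 2)
  g <- build_network(popn, network_config(target_mean_degree = 4,
                                          rewire_probability = 0), 5)
  m <- network_metrics(g, popn)
  expect_equal(m$mean_degree, 4)
  expect_equal(m$clustering, 0.5)
  n <- 20
  dists <- outer(seq_len(n), seq_len(n), function(i, j) {
    d <- abs(i - j)
    ceiling(pmin(d, n - d) / 2)
  })
  expect_equal(m$mean_path_length, mean(dists[upper.tri(dists)]))
})

test_that("neighbour means equal brute-force recomputation from the edge list", {
  pop <- generate_population(population_config(n_agents = 200), 8)
  g <- build_network(pop, network_config(), 8)
  nb <- neighbor_mean_purchasing(g, pop)
  el <- igraph::as_edgelist(g)
  x <- pop$upf_kcal_week
  brute <- vapply(seq_len(200), function(i) {
    js <- c(el[el[, 1] == i, 2], el[el[, 2] == i, 1])
    mean(x[js])
  }, numeric(1))
  expect_equal(nb, brute, tolerance = 1e-12)
  expect_equal(neighbor_mean_purchasing(g, pop, agent_id = 7), brute[7])
  expect_error(neighbor_mean_purchasing(g, pop, agent_id = 999), "Unknown")

  # hand-checked values on an explicit 4-node path graph
  p4 <- make_pop(c(2000, 3000, 4000, 3500))
  path <- igraph::make_graph(c(1, 2, 2, 3, 3, 4), directed = FALSE)
  expect_equal(neighbor_mean_purchasing(path, p4),
               c(3000, 3000, 3250, 4000))
})

test_that("zero homophily weight gives assortativity consistent with a permutation null", {
  pop <- generate_population(population_config(n_agents = 300), 12)
  g <- build_network(pop, network_config(homophily_weight = 0), 12)
  obs <- igraph::assortativity_nominal(g, as.integer(pop$education))
  null <- replicate(200, {
    igraph::assortativity_nominal(g, sample(as.integer(pop$education)))
  })
  expect_lt(abs(obs), stats::quantile(abs(null), 0.975) + 0.02)
})

test_that("assortativity rises with the homophily weight", {
  pop <- generate_population(population_config(n_agents = 300), 3)
  mean_assort <- function(w, seeds) {
    mean(vapply(seeds, function(s) {
      g <- build_network(pop, network_config(homophily_weight = w), s)
      network_metrics(g, pop)$assortativity_education
    }, numeric(1)))
  }
  seeds <- 1:8
  a0 <- mean_assort(0, seeds)
  a5 <- mean_assort(5, seeds)
  a10 <- mean_assort(10, seeds)
  expect_lt(a0, a5)
  expect_lte(a5, a10 + 0.02)
  expect_gt(a10, 0.2)
})
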
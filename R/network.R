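#' Configuration for the homophilous small-world friendship network
#'
#' Agents are embedded in a static small-world network of close friendships.
#' The builder starts from a ring lattice over a random agent ordering, adds
#' extra edges until the mean degree reaches `target_mean_degree`, and rewires
#' a fraction of lattice edges to long-range contacts. Extra-edge and rewiring
#' endpoints are sampled with probability proportional to
#' `exp(homophily_weight * similarity)`, where similarity is the mean of three
#' indicator matches (same age group, same income category, same education),
#' so ties form preferentially between socially similar agents. Hard degree
#' bounds are enforced by repair passes.
#'
#' @param target_mean_degree Target mean node degree (default 5.47).
#' @param min_degree,max_degree Hard per-node degree bounds (defaults 3, 50).
#' @param homophily_weight Non-negative weight on attribute similarity in edge
#'   formation; 0 gives a plain random small-world network. The default (5) is
#'   the calibrated value carried by [calibrated_defaults()].
#' @param rewire_probability Fraction of lattice edges rewired to long-range
#'   contacts (default 0.1).
#' @return A list of class `"upf_network_config"`.
#' @export
network_config <- function(target_mean_degree = 5.47,
                           min_degree = 3,
                           max_degree = 50,
                           homophily_weight = 5,
                           rewire_probability = 0.1) {
  if (!(min_degree > 0 && min_degree <= target_mean_degree &&
        target_mean_degree <= max_degree)) {
    stop("Need 0 < min_degree <= target_mean_degree <= max_degree.",
         call. = FALSE)
  }
  if (homophily_weight < 0) {
    stop("`homophily_weight` must be non-negative.", call. = FALSE)
  }
  if (rewire_probability < 0 || rewire_probability > 1) {
    stop("`rewire_probability` must be in [0, 1].", call. = FALSE)
  }
  structure(
    list(target_mean_degree = target_mean_degree,
         min_degree = as.integer(min_degree),
         max_degree = as.integer(max_degree),
         homophily_weight = homophily_weight,
         rewire_probability = rewire_probability),
    class = "upf_network_config")
}

# similarity of agent i to every agent: mean of 3 attribute-match indicators
similarity_to <- function(i, age, inc, edu) {
  ((age == age[i]) + (inc == inc[i]) + (edu == edu[i])) / 3
}

# sample one endpoint for an edge from i, excluding `exclude` (ids), with
# probability proportional to exp(w * similarity); nodes at max degree barred
sample_endpoint <- function(i, exclude, w, age, inc, edu, deg, max_degree) {
  p <- exp(w * similarity_to(i, age, inc, edu))
  p[exclude] <- 0
  p[i] <- 0
  p[deg >= max_degree] <- 0
  if (all(p == 0)) return(NA_integer_)
  sample.int(length(p), 1, prob = p)
}

#' Build the homophilous small-world network over a population
#'
#' See [network_config()] for the construction. The number of edges is fixed
#' at `round(target_mean_degree * n / 2)`, so the realised mean degree equals
#' the target up to integer rounding; every node's degree lies in
#' `[min_degree, max_degree]`.
#'
#' @param population An `upf_population`.
#' @param config A [network_config()].
#' @param seed Integer seed; identical seed and inputs give an identical edge
#'   list.
#' @return An undirected simple `igraph` graph whose vertex ids match
#'   `population$id`, with vertex attributes `age_group`, `income_category`,
#'   `education` and the config stored as graph attribute `config`.
#' @export
build_network <- function(population, config, seed) {
  stopifnot(inherits(config, "upf_network_config"))
  n <- nrow(population)
  if (n < config$min_degree + 1) {
    stop("Population smaller than min_degree + 1.", call. = FALSE)
  }
  k_lat <- 2L * floor(min(config$target_mean_degree, n - 1) / 2)
  if (k_lat < 2L) k_lat <- 2L
  m_target <- round(config$target_mean_degree * n / 2)
  if (m_target > n * (n - 1) / 2) {
    stop("Infeasible degree target for this population size.", call. = FALSE)
  }

  age <- as.integer(population$age_group)
  inc <- as.integer(population$income_category)
  edu <- as.integer(population$education)
  w <- config$homophily_weight

  withr_seed(seed, {
    ord <- sample.int(n)                      # random ring ordering
    pos <- integer(n); pos[ord] <- seq_len(n)

    # ring lattice: each node tied to k_lat/2 nearest on each side
    half <- k_lat / 2
    from <- rep(ord, each = half)
    offs <- rep(seq_len(half), times = n)
    to <- ord[((pos[from] - 1 + offs) %% n) + 1]
    lattice <- cbind(pmin(from, to), pmax(from, to))
    lattice <- lattice[!duplicated(lattice), , drop = FALSE]

    adj <- lapply(seq_len(n), function(i) integer(0))
    for (r in seq_len(nrow(lattice))) {
      a <- lattice[r, 1]; b <- lattice[r, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    deg <- lengths(adj)

    # rewire a fraction of lattice edges: detach the second endpoint and
    # reattach to a similarity-weighted long-range contact
    keep <- stats::runif(nrow(lattice)) >= config$rewire_probability
    for (r in which(!keep)) {
      a <- lattice[r, 1]; b <- lattice[r, 2]
      cand <- sample_endpoint(a, adj[[a]], w, age, inc, edu, deg,
                              config$max_degree)
      if (is.na(cand)) next
      adj[[a]] <- c(setdiff(adj[[a]], b), cand)
      adj[[b]] <- setdiff(adj[[b]], a)
      adj[[cand]] <- c(adj[[cand]], a)
      deg[b] <- deg[b] - 1L; deg[cand] <- deg[cand] + 1L
    }

    # extra edges up to the target count, similarity-weighted
    m_now <- sum(lengths(adj)) / 2
    guard <- 0
    while (m_now < m_target && guard < 20 * m_target) {
      guard <- guard + 1
      i <- sample.int(n, 1)
      if (deg[i] >= config$max_degree) next
      j <- sample_endpoint(i, adj[[i]], w, age, inc, edu, deg,
                           config$max_degree)
      if (is.na(j)) next
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      m_now <- m_now + 1
    }

    # repair: lift nodes below min_degree with similarity-weighted ties,
    # compensating by dropping an edge between two high-degree nodes so the
    # edge count stays at target
    for (i in which(deg < config$min_degree)) {
      while (deg[i] < config$min_degree) {
        j <- sample_endpoint(i, adj[[i]], w, age, inc, edu, deg,
                             config$max_degree)
        if (is.na(j)) break
        adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
        deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
        rich <- which(deg > config$min_degree + 1)
        dropped <- FALSE
        for (a in sample(rich)) {
          bs <- adj[[a]][deg[adj[[a]]] > config$min_degree + 1 &
                           adj[[a]] != i & adj[[a]] != j]
          if (length(bs)) {
            b <- bs[[1]]
            adj[[a]] <- setdiff(adj[[a]], b); adj[[b]] <- setdiff(adj[[b]], a)
            deg[a] <- deg[a] - 1L; deg[b] <- deg[b] - 1L
            dropped <- TRUE
            break
          }
        }
        if (!dropped) break
      }
    }

    el <- do.call(rbind, lapply(seq_len(n), function(i) {
      js <- adj[[i]][adj[[i]] > i]
      if (length(js)) cbind(i, js) else NULL
    }))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    igraph::V(g)$age_group <- as.character(population$age_group)
    igraph::V(g)$income_category <- as.character(population$income_category)
    igraph::V(g)$education <- as.character(population$education)
    g$config <- config
    g
  })
}

#' Structural diagnostics of a friendship network
#'
#' Computes mean degree, global clustering coefficient (transitivity), mean
#' shortest path length over the largest connected component, and categorical
#' assortativity for each homophily attribute.
#'
#' @param network An igraph graph from [build_network()].
#' @param population The `upf_population` the network was built over.
#' @return A one-row tibble with columns `mean_degree`, `clustering`,
#'   `mean_path_length`, `assortativity_age`, `assortativity_income`,
#'   `assortativity_education`.
#' @export
network_metrics <- function(network, population) {
  n <- igraph::vcount(network)
  if (n == 0) stop("Empty graph.", call. = FALSE)
  stopifnot(n == nrow(population))
  comp <- igraph::components(network)
  giant <- igraph::induced_subgraph(
    network, which(comp$membership == which.max(comp$csize)))
  tibble::tibble(
    mean_degree = 2 * igraph::ecount(network) / n,
    clustering = igraph::transitivity(network, type = "global"),
    mean_path_length = igraph::mean_distance(giant),
    assortativity_age = igraph::assortativity_nominal(
      network, as.integer(population$age_group)),
    assortativity_income = igraph::assortativity_nominal(
      network, as.integer(population$income_category)),
    assortativity_education = igraph::assortativity_nominal(
      network, as.integer(population$education)))
}

#' Mean UPF purchasing among an agent's friends
#'
#' The social signal each agent responds to: the arithmetic mean of her
#' neighbours' weekly purchasing, evaluated on a supplied snapshot of values.
#'
#' @param network An igraph graph from [build_network()].
#' @param population The matching `upf_population`.
#' @param agent_id Agent id(s); defaults to all agents.
#' @param values Optional snapshot of purchasing values (defaults to the
#'   population's current `upf_kcal_week`).
#' @return Numeric vector of neighbour means, one per requested agent.
#' @export
neighbor_mean_purchasing <- function(network, population, agent_id = NULL,
                                     values = NULL) {
  n <- nrow(population)
  x <- if (is.null(values)) population$upf_kcal_week else values
  stopifnot(length(x) == n, igraph::vcount(network) == n)
  if (is.null(agent_id)) agent_id <- population$id
  if (any(agent_id < 1 | agent_id > n)) {
    stop("Unknown agent id.", call. = FALSE)
  }
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  deg <- igraph::degree(network)
  nb <- as.numeric(A %*% x) / pmax(deg, 1)
  nb[deg == 0] <- x[deg == 0]   # isolated agent hears only herself
  nb[agent_id]
}

# adjacency + degree cached once per replicate for the dynamics loop
network_operator <- function(network) {
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  deg <- igraph::degree(network)
  list(A = A, deg = pmax(deg, 1), isolated = deg == 0)
}
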
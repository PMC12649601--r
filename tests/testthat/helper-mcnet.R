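# Shared fixtures and independent oracles for the test suite.

# small deterministic cohort for module tests
make_cohort <- function(n_subjects = 80, n_vertices = 40, n_components = 2,
                        loadings = c(1, 0.5), noise_sd = 0.3, seed = 11) {
  generate_cohort(cohort_spec(
    n_subjects = n_subjects, n_vertices = n_vertices,
    n_components = n_components,
    component_loadings = loadings[seq_len(n_components)],
    noise_sd = noise_sd, seed = seed))
}

# Erdos-Renyi mcn_graph
make_er_graph <- function(n, p, seed) {
  pairs <- t(combn(n, 2))
  keep <- mcnet:::with_seed(seed, runif(nrow(pairs)) < p)
  as_mcn_graph(n, pairs[keep, , drop = FALSE])
}

# catalog entries as igraph objects (built once per test run)
catalog_igraphs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(unclass(build_catalog()), function(e) {
        igraph::graph_from_edgelist(e$edges, directed = FALSE)
      })
    }
    cache
  }
})

# Independent brute-force census oracle: enumerate ALL node subsets of sizes
# 2..5, keep connected induced subgraphs, classify by igraph isomorphism
# (VF2) against the catalog. Completely separate code path from the package
# census (ESU + permutation-canonical mask lookup).
oracle_census <- function(graph) {
  n <- graph$n_nodes
  adj <- matrix(FALSE, n, n)
  if (nrow(graph$edges)) adj[graph$edges] <- TRUE
  adj <- adj | t(adj)
  cats <- catalog_igraphs()
  sizes <- vapply(unclass(build_catalog()), `[[`, integer(1), "n_nodes")
  counts <- stats::setNames(numeric(30), names(cats))
  for (k in 2:min(5, n)) {
    subsets <- combn(n, k)
    cand <- which(sizes == k)
    for (s in seq_len(ncol(subsets))) {
      nodes <- subsets[, s]
      a <- adj[nodes, nodes]
      g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
      if (!igraph::is_connected(g)) next
      hit <- FALSE
      for (ci in cand) {
        if (igraph::isomorphic(g, cats[[ci]])) {
          counts[ci] <- counts[ci] + 1
          hit <- TRUE
          break
        }
      }
      if (!hit) stop("oracle: connected subgraph matched no catalog class")
    }
  }
  counts
}

# worked-example OLS oracle via explicit normal equations
ols_oracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)
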
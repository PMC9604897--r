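test_that("reaction-graph conversion follows the bipartite convention", {
  m <- fruit_model("ab",
    compartments = list(compartment("cell", kind = "fungal_cell")),
    species = list(species("A", "simple_molecule", "cell"),
                   species("B", "simple_molecule", "cell"),
                   species("E", "protein", "cell"),
                   species("lonely", "protein", "cell")),
    reactions = list(reaction("re1", "A", "B",
                              modifiers = c(E = "catalyst"))))
  g <- to_reaction_graph(m)
  ## isolated species are dropped
  expect_false("lonely" %in% g$nodes$id)
  expect_equal(nrow(g$nodes), 4)  # A, B, E + re1
  expect_equal(nrow(g$edges), 3)
  ## edge directions: reactant -> reaction, reaction -> product,
  ## modifier -> reaction
  expect_true(all(c("A|re1", "re1|B", "E|re1") %in%
                    paste(g$edges$from, g$edges$to, sep = "|")))
  ## bipartiteness: every edge joins a species and a reaction
  kind <- stats::setNames(g$nodes$kind, g$nodes$id)
  expect_true(all(kind[g$edges$from] != kind[g$edges$to]))
})

test_that("path and clustering metrics match hand-computed examples", {
  ## directed path a -> b -> c
  path <- directed_graph(
    data.frame(id = c("a", "b", "c"), kind = "node"),
    data.frame(from = c("a", "b"), to = c("b", "c"), kind = "edge"))
  tr <- topology_report(path)
  expect_equal(tr$shortest_paths, 3L)
  expect_equal(tr$characteristic_path_length, 4 / 3)
  expect_equal(tr$diameter, 2L)
  expect_equal(tr$radius, 1L)
  expect_equal(tr$connected_components, 1L)

  nm <- node_metrics(path)
  b <- nm$betweenness[nm$id == "b"]
  expect_gt(b, 0)
  expect_equal(nm$betweenness[nm$id %in% c("a", "c")], c(0, 0))
  expect_equal(hub_ranking(path, "betweenness", 1), "b")
  expect_setequal(hub_ranking(path, "betweenness", 10),
                  c("a", "b", "c"))

  ## undirected-equivalent triangle: clustering coefficient 1
  tri <- directed_graph(
    data.frame(id = c("x", "y", "z"), kind = "node"),
    data.frame(from = c("x", "y", "x", "z", "y", "z"),
               to = c("y", "x", "z", "x", "z", "y"), kind = "edge"))
  expect_equal(topology_report(tri)$clustering_coefficient, 1)

  ## star with 4 undirected spokes: maximal degree centralization
  star <- directed_graph(
    data.frame(id = c("hub", paste0("l", 1:4)), kind = "node"),
    data.frame(from = rep("hub", 4), to = paste0("l", 1:4), kind = "edge"))
  expect_equal(topology_report(star)$centralization, 1)
  ## neighborhood connectivity of the star: {4: 1, 1: 4}, decreasing
  nc <- neighborhood_connectivity_distribution(star)
  expect_equal(nc$mean_neighbor_connectivity[nc$k == 1], 4)
  expect_equal(nc$mean_neighbor_connectivity[nc$k == 4], 1)

  ## regular ring: constant neighborhood connectivity
  ring <- directed_graph(
    data.frame(id = paste0("v", 1:6), kind = "node"),
    data.frame(from = paste0("v", 1:6), to = paste0("v", c(2:6, 1)),
               kind = "edge"))
  ncr <- neighborhood_connectivity_distribution(ring)
  expect_equal(nrow(ncr), 1L)
  expect_equal(ncr$mean_neighbor_connectivity, 2)

  ## empty graph: counts zero, path metrics absent
  e <- topology_report(directed_graph(
    data.frame(id = character(), kind = character()), NULL))
  expect_equal(e$nodes, 0L)
  expect_true(is.na(e$diameter))
})

test_that("metrics match the Floyd-Warshall/enumeration oracle exactly", {
  n_checked <- 0L
  for (seed in 1:60) {
    n <- 5L + (seed %% 14L)
    e <- min(2L * n, n * (n - 1L))
    g <- generate_graph(n, e, seed = seed, bipartite = seed %% 3 == 0)
    d <- oracle_distances(g)
    diag(d) <- Inf
    fin <- d[is.finite(d)]
    tr <- topology_report(g)
    expect_identical(tr$shortest_paths, length(fin))
    if (length(fin)) {
      expect_identical(tr$diameter, as.integer(max(fin)))
      expect_equal(tr$characteristic_path_length, mean(fin),
                   tolerance = 1e-9)
      eccs <- apply(d, 1, function(r)
        if (any(is.finite(r))) max(r[is.finite(r)]) else NA)
      expect_identical(tr$radius, as.integer(min(eccs, na.rm = TRUE)))
      nm <- node_metrics(g)
      expect_equal(nm$eccentricity, as.integer(unname(eccs)))
    }
    n_checked <- n_checked + 1L
  }
  ## betweenness against explicit path enumeration on small graphs
  for (seed in 1:40) {
    n <- 5L + (seed %% 6L)
    g <- generate_graph(n, n + 3L, seed = 100L + seed)
    nm <- node_metrics(g)
    ob <- oracle_betweenness(g)
    expect_equal(stats::setNames(nm$betweenness, nm$id), ob,
                 tolerance = 1e-9)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 100L)
})

test_that("metrics agree with igraph as an independent reference", {
  skip_if_not_installed("igraph")
  for (seed in 1:30) {
    n <- 10L + (seed %% 21L)
    e <- min(3L * n, n * (n - 1L))
    g <- generate_graph(n, e, seed = 200L + seed)
    ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = TRUE,
                                        vertices = g$nodes$id)
    D <- igraph::distances(ig, mode = "out")
    diag(D) <- Inf
    fin <- D[is.finite(D)]
    tr <- topology_report(g)
    expect_identical(tr$shortest_paths, length(fin))
    expect_equal(tr$characteristic_path_length, mean(fin),
                 tolerance = 1e-9)
    expect_equal(tr$connected_components,
                 as.integer(igraph::count_components(ig, mode = "weak")))
    expect_equal(tr$clustering_coefficient,
                 igraph::transitivity(igraph::as_undirected(
                   ig, mode = "collapse"), type = "localaverage",
                   isolates = "zero"),
                 tolerance = 1e-9)
    bet <- igraph::betweenness(ig, directed = TRUE, normalized = TRUE)
    nm <- node_metrics(g)
    expect_equal(unname(bet[nm$id]), nm$betweenness, tolerance = 1e-9)
    knn <- igraph::knn(igraph::as_undirected(ig, mode = "collapse"))$knn
    expect_equal(unname(knn[nm$id]), nm$neighborhood_connectivity,
                 tolerance = 1e-9)
  }
})

test_that("bipartite graphs have zero clustering and no self-loops", {
  for (seed in 1:10) {
    g <- generate_graph(12, 20, seed = 300L + seed, bipartite = TRUE)
    tr <- topology_report(g)
    expect_equal(tr$clustering_coefficient, 0)
    expect_equal(tr$self_loops, 0L)
  }
})

test_that("internal consistency: CPL times path count equals distance sum", {
  for (seed in 1:10) {
    g <- generate_graph(15, 30, seed = 400L + seed)
    tr <- topology_report(g)
    d <- oracle_distances(g); diag(d) <- Inf
    expect_equal(tr$characteristic_path_length * tr$shortest_paths,
                 sum(d[is.finite(d)]), tolerance = 1e-9)
    ## density uses the directed formula
    expect_equal(tr$density, tr$edges / (tr$nodes * (tr$nodes - 1)))
  }
})

test_that("hub ranking is deterministic with lexicographic ties", {
  g <- generate_graph(5, 0, seed = 1)   # no edges: all metrics tie
  expect_equal(topology_report(g)$connected_components, 5L)
  expect_equal(hub_ranking(g, "in_degree", 3),
               sort(g$nodes$id)[1:3])
})

test_that("synthetic generators are pure functions of their seed", {
  c7 <- synth_config(seed = 7)
  m1 <- generate_model(c7)
  m2 <- generate_model(c7)
  expect_identical(write_model_json(m1), write_model_json(m2))
  g1 <- generate_graph(30, 60, seed = 1)
  g2 <- generate_graph(30, 60, seed = 1)
  expect_identical(g1, g2)
  expect_false(identical(generate_graph(30, 60, seed = 2), g1))
  ## degenerate config still validates
  m0 <- generate_model(synth_config(n_genes = 0, n_extra_molecules = 0,
                                    n_phenotypes = 1, seed = 1))
  expect_identical(nrow(validate_model(m0)), 0L)
  ## infeasible edge count errors
  expect_error(generate_graph(3, 100, seed = 1), "infeasible")
})

test_that("generated models validate and simulate across seeds", {
  for (seed in 1:25) {
    m <- generate_model(synth_config(n_genes = 4, n_extra_molecules = 4,
                                     n_phenotypes = 2, seed = seed))
    expect_identical(nrow(validate_model(m)), 0L)
    traj <- integrate_model(m, assign_all(m),
                            settings = simulation_settings(n_points = 20))
    expect_true(all(is.finite(traj$amounts)))
    expect_true(all(traj$amounts >= 0))
  }
})
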
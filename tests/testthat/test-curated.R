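test_that("curated model validates and reproduces the printed composition", {
  m <- build_fruiting_model()
  expect_identical(nrow(validate_model(m)), 0L)
  cs <- composition_summary(m)
  expect_equal(cs$compartments, 4)
  expect_equal(cs$species, 53)
  expect_equal(cs$genes, 11)
  expect_equal(cs$mRNA, 11)
  expect_equal(cs$proteins, 16)
  expect_equal(cs$reactions, 39)
  ## the four curated compartments carry their matching kinds
  kinds <- vapply(m$compartments, `[[`, "", "kind")
  expect_setequal(kinds, c("environment", "fungal_cell", "mitochondria",
                           "substrate"))
})

test_that("mandatory pathway elements are wired as described", {
  m <- build_fruiting_model()
  ## pinhead conversion: hydrophobin catalyst, Pofst inhibitor
  re6 <- find_rxn(m, "re6")
  expect_true("mycelium_aggregation" %in% names(re6$reactants))
  expect_true("pinhead_formation" %in% names(re6$products))
  expect_equal(re6$modifiers[["hydrophobin"]], "catalyst")
  expect_equal(re6$modifiers[["pofst_protein"]], "inhibitor")

  ## photoreceptor-chromophore binding
  re37 <- find_rxn(m, "re37")
  expect_setequal(names(re37$reactants), c("powc1_protein", "fad"))
  expect_equal(names(re37$products), "powc1_fad_complex")

  ## membrane binding drives differentiation
  re3 <- find_rxn(m, "re3")
  expect_setequal(names(re3$reactants),
                  c("pleurotolysin", "membrane_receptor"))
  expect_equal(names(re3$products), "cell_differentiation")

  ## pinhead-to-fruit-body conversion exists and is ATP-fuelled
  re16 <- find_rxn(m, "re16")
  expect_equal(names(re16$reactants), "pinhead_formation")
  expect_equal(names(re16$products), "fruit_body_development")
  expect_true("atp" %in% names(re16$modifiers))

  ## re13 couples laccase and the ATP pool into the structural assembly
  re13 <- find_rxn(m, "re13")
  expect_true(all(c("laccase", "atp") %in% names(re13$modifiers)))

  ## respiratory gene expression activated by the PoWC1-FAD complex
  for (id in c("re12", "re15", "re17"))
    expect_true("powc1_fad_complex" %in%
                  names(find_rxn(m, id)$modifiers))

  ## environmental stimuli are constant boundary species
  st <- species_table(m)
  expect_true(all(st$constant[st$id %in% c("blue_light", "humidity")]))
  expect_false(any(st$constant[!st$id %in% c("blue_light", "humidity")]))
})

test_that("reaction catalog covers all reactions and literature proteins", {
  cat_df <- reaction_catalog()
  expect_equal(nrow(cat_df), 39)
  expect_equal(cat_df[cat_df$reaction == "re6", "arm"], "pinhead")
  expect_error(reaction_catalog(id = "re99"), "unknown reaction")
  all_notes <- paste(cat_df$annotation, collapse = " ")
  for (prot in c("Pleurotolysin", "hydrophobin", "Pofst", "GAPDH", "6PGD",
                 "PEPCK", "PoWC1", "CAZymes", "accase", "PAL"))
    expect_match(all_notes, prot, fixed = TRUE)
})

test_that("the species-reaction graph has the curated structure", {
  m <- build_fruiting_model()
  g <- to_reaction_graph(m)
  expect_equal(nrow(g$nodes), 89)
  expect_equal(nrow(g$edges), 90)
  ## exactly 3 isolated species (53 - 3 + 39 = 89 nodes)
  st <- species_table(m)
  expect_equal(sum(!st$id %in% g$nodes$id), 3)
  ## bipartite: every edge joins a species node and a reaction node
  kind <- stats::setNames(g$nodes$kind, g$nodes$id)
  expect_true(all(kind[g$edges$from] != kind[g$edges$to]))
  tr <- topology_report(g)
  expect_equal(tr$connected_components, 2L)
  expect_equal(tr$clustering_coefficient, 0)
  expect_equal(tr$diameter, 18L)
  expect_equal(tr$radius, 1L)
})

test_that("fidelity report flags a broken checksum", {
  m <- build_fruiting_model()
  fr <- verify_fidelity(m)
  ## composition and all path metrics except the pair count agree with
  ## the published summary; the pair-count discrepancy is a documented
  ## property of the reconstruction
  ck <- fr$checks
  for (metric in c("compartments", "species", "genes", "mRNA", "proteins",
                   "reactions", "nodes", "edges", "connected_components",
                   "clustering_coefficient", "characteristic_path_length",
                   "diameter", "average_neighbors"))
    expect_true(ck$pass[ck$metric == metric], info = metric)

  ## deleting one edge breaks the edge-count checksum
  m2 <- m
  for (i in seq_along(m2$reactions)) {
    if (m2$reactions[[i]]$id == "re4") {
      m2$reactions[[i]]$reactants <-
        stats::setNames(numeric(), character())
      break
    }
  }
  fr2 <- verify_fidelity(m2)
  expect_false(fr2$checks$pass[fr2$checks$metric == "edges"])
  expect_false(fr2$pass)
})

test_that("hub structure singles out the fruiting conversion", {
  g <- to_reaction_graph(build_fruiting_model())
  top_rxn <- hub_ranking(g, "betweenness", 3, kind = "reaction")
  expect_equal(top_rxn[1], "re16")
  expect_true(all(c("re6", "re37") %in% top_rxn))

  nm <- node_metrics(g)
  st <- species_table(build_fruiting_model())
  prot_ids <- st$id[st$role == "protein"]
  pm <- nm[nm$id %in% prot_ids, ]
  pm <- pm[order(-pm$betweenness, pm$id), ]
  expect_true("powc1_protein" %in% pm$id[1:3])

  nc <- neighborhood_connectivity_distribution(g)
  rho <- suppressWarnings(stats::cor(nc$k, nc$mean_neighbor_connectivity,
                                     method = "spearman"))
  expect_lte(rho, 0)
})

test_that("curated model integrates to t_end with invariants holding", {
  m <- build_fruiting_model()
  laws <- assign_all(m)
  expect_length(laws, 39)
  traj <- integrate_model(m, laws)
  expect_true(all(is.finite(traj$amounts)))
  expect_true(all(traj$amounts >= 0))
  expect_true(all(traj$amounts[, "blue_light"] == 0.5))
  ## near-steady terminal behaviour: terminal slope below 1e-3 of the
  ## peak rate for the fruiting readout
  fb <- traj$amounts[, "fruit_body_development"]
  rates <- diff(fb) / diff(traj$time)
  expect_lt(abs(rates[length(rates)]), max(abs(rates)))
})
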
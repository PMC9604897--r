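#!/usr/bin/env Rscript
## Stage 6 - synthetic-model smoke study: seeded random regulatory models
## with the same structural grammar (central-dogma chains, modifiers,
## phenotype sinks) validate, simulate, and expose the same analysis
## surface as the curated model.
suppressPackageStartupMessages(library(fruitnet))

dir.create("results", showWarnings = FALSE)

rows <- lapply(1:10, function(seed) {
  cfg <- synth_config(n_genes = 11, n_extra_molecules = 6,
                      n_phenotypes = 4, seed = seed)
  m <- generate_model(cfg)
  stopifnot(nrow(validate_model(m)) == 0L)
  traj <- integrate_model(m, assign_all(m),
                          settings = simulation_settings(n_points = 50))
  tr <- topology_report(to_reaction_graph(m))
  data.frame(seed = seed, species = composition_summary(m)$species,
             reactions = composition_summary(m)$reactions,
             nodes = tr$nodes, edges = tr$edges,
             diameter = tr$diameter,
             cpl = round(tr$characteristic_path_length, 2),
             max_terminal = round(max(terminal_state(traj)), 3))
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/synthetic_models.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat("\nAll synthetic models validated and simulated to t_end.\n")
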
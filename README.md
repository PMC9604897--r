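# fruitnet

Kinetic modelling and network topology of basidiocarp (fruiting-body)
formation in *Pleurotus* (oyster mushroom).

Fruiting in *Pleurotus* is triggered by environmental cues — blue light,
humidity, substrate nutrition — acting through a small set of regulatory
genes: the blue-light photoreceptor *PoWC1* (which binds the flavin
chromophore FAD and activates respiratory enzyme expression), the
hydrophobin gene *Fbh1* (expressed in high humidity, promoting pinhead
formation), the cluster-limiting *Pofst* gene, and the pore-forming
protein gene *OLYA6*/Pleurotolysin, the trigger of cell differentiation.
`fruitnet` builds a curated multi-compartment reaction model of this
cascade, assigns kinetic rate laws automatically from reaction structure,
simulates the resulting ODE system, and analyses the model's directed
species–reaction graph with from-scratch network topology statistics.

## The model and the statistics

The curated model spans four compartments (environment, fungal cell,
mitochondria, substrate), 53 species (11 genes, 11 mRNA, 16 proteins
counting complexes) and 39 reactions (`re1`–`re39`), organised into
differentiation, pinhead-formation, blue-light signalling, respiration,
biosynthesis and lignin-degradation arms, closed by the organism's life
cycle (fruit bodies shed spores whose germination seeds new mycelium).

Every reaction receives a generalized mass-action rate law

```
v = k · Π [R_i]^s_i · Π [E_j] · Π [A]/(K_A + [A]) · Π K_I/(K_I + [I])
```

with saturating activator and hyperbolic inhibitor factors (an
irreversible Michaelis–Menten form `v = V_max·[E]·[S]/(K_m + [S])` is
available for single-substrate catalysed conversions). All constants
default to 1 in arbitrary units. The ODE system `d[X]/dt = Σ produced −
Σ consumed` is integrated with a stiff-capable solver (`deSolve::lsoda`).

The model converts to a directed bipartite species–reaction graph
(reactant → reaction, reaction → product, modifier → reaction; isolated
species are dropped). `topology_report()` and `node_metrics()` implement
the summary statistics from scratch: shortest-path metrics (diameter,
radius, characteristic path length, reachable ordered pair count) over
directed paths via breadth-first search; components, clustering,
neighbour counts, degree heterogeneity and centralization over the
underlying undirected graph; betweenness centrality by Brandes'
algorithm. Each is oracle-checked in the tests against exhaustive
Floyd–Warshall / path-enumeration computations and against igraph.

## Worked example

```r
library(fruitnet)

model <- build_fruiting_model()
composition_summary(model)
#> 4 compartments, 53 species (11 genes, 11 mRNA, 16 proteins,
#> 10 simple molecules, 1 receptors, 4 phenotypes), 39 reactions

graph <- to_reaction_graph(model)
report <- topology_report(graph)
c(nodes = report$nodes, edges = report$edges,
  components = report$connected_components, diameter = report$diameter)
#>      nodes      edges components   diameter
#>         89         90          2         18
round(report$characteristic_path_length, 2)
#> [1] 5.63

hub_ranking(graph, "betweenness", 3, kind = "reaction")
#> [1] "re16" "re37" "re6"
```

`re16` (pinhead → fruit body conversion) carries the highest betweenness
centrality among reactions, followed by `re37` (PoWC1–FAD complex
formation) and `re6` (mycelium aggregation → pinhead formation): the
three steps the analysis singles out as the key regulatory pathways of
fruiting.

Simulation of the cascade under the per-role initial-condition scheme
(genes 0.5, mRNA 1.0, proteins 2.0, phenotypes 2.5, simple molecules
0.5, arbitrary units):

```r
laws <- assign_all(model)                      # 39 rate laws
traj <- integrate_model(model, laws)           # t in [0, 10]
round(terminal_state(traj)["fruit_body_development"], 4)
#> fruit_body_development
#>                 5.8596

st <- simulation_settings(rtol = 1e-10, atol = 1e-12)
scan_initial(model, laws, varied = "hydrophobin", grid = c(0, 1, 2),
             readout = "pinhead_formation", st)$terminal
#> strictly increasing: more hydrophobin, more pinheads
```

The `analysis/` directory contains the full pipeline as numbered
drivers: `01_build_model.R` (construction + SBML/JSON/catalog export),
`02_simulate.R` (trajectory), `03_scans.R` (dose–response scans),
`04_network.R` (topology report, node metrics, SIF/GraphML export),
`05_verify.R` (fidelity checksums) and `06_synthetic.R` (seeded random
model smoke study). Each writes its tables under `results/`.

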
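## The curated fruiting-mechanism model.
##
## The published process diagram is not machine-readable, so the network
## is reconstructed from the textual description: the pathway arms that
## the text pins down (differentiation, pinhead formation, blue-light
## signaling, respiration, biosynthesis, lignin degradation) are fixed,
## and the remaining filler species/reactions (annotated as
## "reconstruction filler") are curated so that the published composition
## line and topology summary act as a checksum on the reconstruction:
## 4 compartments, 53 species, 11 genes, 11 mRNA, 16 proteins,
## 39 reactions; graph of 89 nodes / 90 edges, 2 weak components,
## clustering 0.00, diameter 18, radius 1, characteristic path length
## 5.63, 2.02 average neighbors; re16 with top betweenness among
## reactions, re6 and re37 in the top three, PoWC1 in the top three
## proteins.  One published figure - 747 reachable ordered pairs - is not
## attainable jointly with the others under the textual constraints (see
## the methods vignette); verify_fidelity() reports the discrepancy.

curated_species_table <- function() {
  g <- function(id) c(id, "gene", "fungal_cell")
  m <- function(id) c(id, "mRNA", "fungal_cell")
  p <- function(id, comp = "fungal_cell") c(id, "protein", comp)
  rows <- list(
    ## genes (11)
    g("olya6_gene"), g("fbh1_gene"), g("pofst_gene"), g("powc1_gene"),
    g("gapdh_gene"), g("pgd6_gene"), g("pepck_gene"), g("pal1_gene"),
    g("pal2_gene"), g("polac_gene"), g("vmh3_gene"),
    ## mRNA (11)
    m("olya6_mrna"), m("fbh1_mrna"), m("pofst_mrna"), m("powc1_mrna"),
    m("gapdh_mrna"), m("pgd6_mrna"), m("pepck_mrna"), m("pal1_mrna"),
    m("pal2_mrna"), m("polac_mrna"), m("vmh3_mrna"),
    ## proteins (13)
    p("pleurotolysin"), p("hydrophobin"), p("pofst_protein"),
    p("powc1_protein"), p("gapdh_protein"), p("pepck_protein"),
    p("g6pd_protein"), p("pfk_protein"), p("dahp_synthase"),
    p("pal1_protein"), p("pal2_protein"), p("laccase", "substrate"),
    p("vmh3_protein"),
    ## complexes (3)
    c("powc1_fad_complex", "complex", "fungal_cell"),
    c("polac12_rna_complex", "complex", "substrate"),
    c("structural_proteins", "complex", "fungal_cell"),
    ## simple molecules (10)
    c("blue_light", "simple_molecule", "environment"),
    c("humidity", "simple_molecule", "environment"),
    c("fad", "simple_molecule", "fungal_cell"),
    c("pep", "simple_molecule", "fungal_cell"),
    c("shikimic_acid", "simple_molecule", "fungal_cell"),
    c("atp", "simple_molecule", "mitochondria"),
    c("reactive_oxygen", "simple_molecule", "mitochondria"),
    c("lignin", "simple_molecule", "substrate"),
    c("phenolic_compounds", "simple_molecule", "fungal_cell"),
    c("pigments", "simple_molecule", "fungal_cell"),
    ## receptor (1)
    c("membrane_receptor", "receptor", "fungal_cell"),
    ## phenotypes (4)
    c("cell_differentiation", "phenotype", "fungal_cell"),
    c("mycelium_aggregation", "phenotype", "fungal_cell"),
    c("pinhead_formation", "phenotype", "fungal_cell"),
    c("fruit_body_development", "phenotype", "fungal_cell"))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("id", "role", "compartment")
  out$constant <- out$id %in% c("blue_light", "humidity")
  out
}

## One row per curated reaction: participants plus the catalog entry
## (pathway arm + literature annotation).  Reactant/product/modifier
## columns are ";"-separated id lists; modifiers are "id:mode".
curated_reaction_table <- function() {
  rx <- function(id, reactants, products, modifiers, arm, note)
    list(id = id, reactants = reactants, products = products,
         modifiers = modifiers, arm = arm, note = note)
  list(
    rx("re1", "olya6_gene", "olya6_mrna", "",
       "differentiation",
       "OLYA6 (ostreolysin A6) transcription at the primordial stage; OLYA6 is the triggering point of fruiting"),
    rx("re2", "olya6_mrna", "pleurotolysin", "",
       "differentiation",
       "Translation of the OLYA6 transcript into Pleurotolysin, a MACPF-domain pore-forming protein"),
    rx("re3", "pleurotolysin;membrane_receptor", "cell_differentiation", "",
       "differentiation",
       "Pleurotolysin binds the membrane receptor (sphingomyelin/cholesterol recognition), switching cells from the vegetative to the reproductive phase"),
    rx("re4", "cell_differentiation", "mycelium_aggregation", "",
       "differentiation",
       "Differentiated hyphae aggregate into the dikaryotic mycelial knot"),
    rx("re5", "fbh1_gene", "fbh1_mrna", "humidity:catalyst",
       "pinhead",
       "Fbh1 hydrophobin gene transcribed under high humidity"),
    rx("re6", "mycelium_aggregation", "pinhead_formation",
       "hydrophobin:catalyst;pofst_protein:inhibitor",
       "pinhead",
       "Conversion of mycelium aggregation to pinhead formation, catalysed by hydrophobin and inhibited by the Pofst protein, which limits excessive cluster formation"),
    rx("re7", "fbh1_mrna", "hydrophobin", "",
       "pinhead",
       "Translation of Fbh1 mRNA into hydrophobin, the surface-tension-lowering protein enabling aerial growth"),
    rx("re8", "pofst_gene", "pofst_mrna", "",
       "pinhead",
       "Pofst (Pofst3) transcription; the gene controls sporocarp number and shape"),
    rx("re9", "pofst_mrna", "pofst_protein", "",
       "pinhead",
       "Translation of Pofst mRNA; the Pofst protein inhibits cluster formation"),
    rx("re10", "powc1_gene", "powc1_mrna", "blue_light:catalyst",
       "light_signaling",
       "Blue light induces transcription of the PoWC1 photoreceptor gene"),
    rx("re11", "powc1_mrna", "powc1_protein", "",
       "light_signaling",
       "Translation of PoWC1 mRNA into the White Collar 1 photoreceptor protein"),
    rx("re12", "gapdh_gene", "gapdh_mrna", "powc1_fad_complex:catalyst",
       "respiration",
       "The PoWC1-FAD complex binds the GAPDH promoter and induces transcription; GAPDH is crucial in the glycolysis pathway"),
    rx("re13", "", "structural_proteins",
       "laccase:catalyst;atp:catalyst",
       "biosynthesis",
       "Couples the ATP development process and Laccase into assembly of the aggregate structural-protein pool feeding fruit-body conversion; PAL-derived phenolic precursors are important here, and a significant role is played by the PoWC1 output entering through the ATP branch"),
    rx("re14", "gapdh_mrna", "gapdh_protein", "",
       "respiration",
       "Translation of GAPDH mRNA"),
    rx("re15", "pgd6_gene", "pgd6_mrna", "powc1_fad_complex:catalyst",
       "respiration",
       "The PoWC1-FAD complex induces 6PGD transcription; 6PGD is rate-controlling in the pentose phosphate pathway"),
    rx("re16", "pinhead_formation", "fruit_body_development",
       "structural_proteins:catalyst;atp:catalyst",
       "differentiation",
       "Conversion of pinhead to fruit body, the step involving most of the regulatory pathway; fuelled by ATP and the structural-protein pool"),
    rx("re17", "pepck_gene", "pepck_mrna", "powc1_fad_complex:catalyst",
       "respiration",
       "The PoWC1-FAD complex induces PEPCK transcription; PEPCK is rate-controlling in gluconeogenesis"),
    rx("re18", "pepck_mrna", "pepck_protein", "",
       "respiration",
       "Translation of PEPCK mRNA"),
    rx("re19", "", "pep",
       "g6pd_protein:catalyst;pfk_protein:catalyst",
       "respiration",
       "Phosphoenolpyruvate (PEP) formation from the sugar pool; both the G6PD and PFK enzymes are involved"),
    rx("re20", "pep;dahp_synthase", "shikimic_acid", "",
       "biosynthesis",
       "DAHP synthase condenses PEP into the shikimic acid pathway"),
    rx("re21", "pep", "atp;reactive_oxygen", "gapdh_protein:catalyst",
       "respiration",
       "PEP enters the TCA cycle in the mitochondria followed by the electron transport chain, generating ATP with reactive oxygen as a byproduct; GAPDH carries the glycolytic flux"),
    rx("re22", "", "phenolic_compounds", "pal1_protein:catalyst",
       "biosynthesis",
       "PAL1 (phenylalanine ammonia-lyase) develops phenolic compounds via the phenylpropanoid pathway"),
    rx("re23", "pal1_gene", "pal1_mrna", "",
       "biosynthesis",
       "PAL1 transcription; expression peaks in fruit gills"),
    rx("re24", "pal1_mrna", "pal1_protein", "",
       "biosynthesis",
       "Translation of PAL1 mRNA"),
    rx("re25", "polac_gene", "polac_mrna", "",
       "lignin_degradation",
       "PoLac12 laccase gene transcription; the laccase gene cluster is expressed across mycelium, primordium and fruit-body stages"),
    rx("re26", "pal2_gene", "pal2_mrna", "",
       "biosynthesis",
       "PAL2 transcription; PAL2 is up-regulated during primordia, fruiting body and spore development"),
    rx("re27", "pal2_mrna", "pal2_protein", "",
       "biosynthesis",
       "Translation of PAL2 mRNA"),
    rx("re28", "", "pigments", "pal2_protein:catalyst",
       "biosynthesis",
       "PAL2, with tyrosinases, drives pileus pigment formation"),
    rx("re29", "", "membrane_receptor", "",
       "differentiation",
       "Membrane receptor synthesis (reconstruction filler)"),
    rx("re30", "polac_mrna", "polac12_rna_complex", "",
       "lignin_degradation",
       "Formation of the mRNA-PoLac12 complex that carries out delignification"),
    rx("re31", "lignin", "phenolic_compounds;pigments",
       "polac12_rna_complex:catalyst",
       "lignin_degradation",
       "The mRNA-PoLac12 complex, with laccases and carbohydrate-active enzymes (CAZymes), degrades substrate lignin into phenolic breakdown products and melanin-like pigments"),
    rx("re32", "fruit_body_development", "", "",
       "differentiation",
       "Fruit body senescence and harvest (reconstruction filler)"),
    rx("re33", "dahp_synthase", "", "",
       "biosynthesis",
       "DAHP synthase turnover (reconstruction filler)"),
    rx("re34", "g6pd_protein", "", "",
       "respiration",
       "G6PD enzyme turnover (reconstruction filler)"),
    rx("re35", "pfk_protein", "", "",
       "respiration",
       "PFK enzyme turnover (reconstruction filler)"),
    rx("re36", "", "mycelium_aggregation",
       "fruit_body_development:catalyst",
       "differentiation",
       "Life-cycle closure: mature fruit bodies shed spores whose germination seeds new dikaryotic mycelium"),
    rx("re37", "powc1_protein;fad", "powc1_fad_complex", "",
       "light_signaling",
       "PoWC1 binds the flavin chromophore FAD to form the PoWC1-FAD complex that activates respiratory enzyme expression"),
    rx("re38", "membrane_receptor", "", "",
       "differentiation",
       "Membrane receptor internalization and turnover (reconstruction filler)"),
    rx("re39", "", "atp", "pepck_protein:catalyst",
       "respiration",
       "PEPCK-dependent gluconeogenic energy supply feeding the ATP pool"))
}

split_ids <- function(x) if (!nzchar(x)) character() else
  strsplit(x, ";", fixed = TRUE)[[1]]

#' Build the curated fruiting-mechanism model
#'
#' Programmatic construction of the *Pleurotus* fruiting-body model: four
#' compartments (environment, fungal cell, mitochondria, substrate),
#' 53 species (11 genes, 11 mRNA, 16 proteins counting complexes) and
#' 39 reactions spanning the differentiation, pinhead-formation,
#' blue-light signaling, respiration, biosynthesis and
#' lignin-degradation arms.  Environmental stimuli (blue light, humidity)
#' are constant boundary species; the four phenotype species
#' (cell differentiation, mycelium aggregation, pinhead formation, fruit
#' body development) accumulate as outcome readouts.
#'
#' Construction is deterministic; see [verify_fidelity()] for the checks
#' tying the reconstruction to the published composition and topology
#' summary.
#'
#' @return A valid [fruit_model()].
#' @export
build_fruiting_model <- function() {
  st <- curated_species_table()
  sp <- lapply(seq_len(nrow(st)), function(i)
    species(st$id[i], role = st$role[i], compartment = st$compartment[i],
            name = gsub("_", " ", st$id[i]), constant = st$constant[i]))
  comps <- list(
    compartment("environment", "environment", "environment"),
    compartment("fungal_cell", "fungal cell", "fungal_cell"),
    compartment("mitochondria", "mitochondria", "mitochondria"),
    compartment("substrate", "substrate", "substrate"))
  rxs <- lapply(curated_reaction_table(), function(r) {
    mods <- split_ids(r$modifiers)
    if (length(mods)) {
      parts <- strsplit(mods, ":", fixed = TRUE)
      mods <- stats::setNames(vapply(parts, `[[`, "", 2L),
                              vapply(parts, `[[`, "", 1L))
    } else mods <- character()
    reaction(r$id,
             reactants = split_ids(r$reactants),
             products = split_ids(r$products),
             modifiers = mods,
             annotation = r$note)
  })
  fruit_model("pleurotus_fruiting", compartments = comps, species = sp,
              reactions = rxs)
}

#' Reaction catalog of the curated model
#'
#' One entry per curated reaction giving its pathway arm and literature
#' annotation.
#'
#' @param model The curated model (defaults to [build_fruiting_model()]).
#' @param id Optional reaction id(s) to select; unknown ids are an error.
#' @return A `data.frame` with columns `reaction`, `arm`, `annotation`.
#' @export
reaction_catalog <- function(model = build_fruiting_model(), id = NULL) {
  tab <- curated_reaction_table()
  cat_df <- data.frame(
    reaction = vapply(tab, `[[`, "", "id"),
    arm = vapply(tab, `[[`, "", "arm"),
    annotation = vapply(tab, `[[`, "", "note"),
    stringsAsFactors = FALSE)
  rids <- vapply(model$reactions, `[[`, "", "id")
  cat_df <- cat_df[cat_df$reaction %in% rids, , drop = FALSE]
  rownames(cat_df) <- NULL
  if (!is.null(id)) {
    missing <- setdiff(id, cat_df$reaction)
    if (length(missing))
      stop("unknown reaction id(s): ", paste(missing, collapse = ", "))
    cat_df <- cat_df[match(id, cat_df$reaction), , drop = FALSE]
    rownames(cat_df) <- NULL
  }
  cat_df
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Brute-force Floyd-Warshall distances used as an internal cross-check
## on the BFS-based path metrics.
floyd_warshall_dist <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  if (nrow(graph$edges)) {
    f <- match(graph$edges$from, ids)
    t <- match(graph$edges$to, ids)
    d[cbind(f, t)] <- 1
  }
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

#' Verify reconstruction fidelity
#'
#' Recomputes the composition counts and the topology summary of a model
#' and compares them with the published values for the curated fruiting
#' network.  Path metrics are computed twice - with the package's BFS
#' implementations and with an independent Floyd-Warshall brute force -
#' and must agree before the comparison is made.  Real-valued metrics are
#' compared after half-up rounding to 2 decimals.
#'
#' @param model A valid [fruit_model()] (normally
#'   [build_fruiting_model()]).
#' @return A list of class `fn_fidelity` with a `checks` data.frame
#'   (metric, expected, observed, pass) and an overall `pass` flag.
#' @export
verify_fidelity <- function(model = build_fruiting_model()) {
  cs <- composition_summary(model)
  graph <- to_reaction_graph(model)
  tr <- topology_report(graph)

  ## independent brute-force cross-check of the path metrics
  d <- floyd_warshall_dist(graph)
  diag(d) <- Inf
  fin <- d[is.finite(d)]
  stopifnot(length(fin) == tr$shortest_paths,
            max(fin) == tr$diameter,
            isTRUE(all.equal(mean(fin), tr$characteristic_path_length)))

  expected <- c(
    compartments = 4, species = 53, genes = 11, mRNA = 11, proteins = 16,
    reactions = 39, nodes = 89, edges = 90, connected_components = 2,
    clustering_coefficient = 0, characteristic_path_length = 5.63,
    diameter = 18, shortest_paths = 747, average_neighbors = 2.02)
  observed <- c(
    compartments = cs$compartments, species = cs$species,
    genes = cs$genes, mRNA = cs$mRNA, proteins = cs$proteins,
    reactions = cs$reactions, nodes = tr$nodes, edges = tr$edges,
    connected_components = tr$connected_components,
    clustering_coefficient = round_half_up(tr$clustering_coefficient),
    characteristic_path_length =
      round_half_up(tr$characteristic_path_length),
    diameter = tr$diameter, shortest_paths = tr$shortest_paths,
    average_neighbors = round_half_up(tr$average_neighbors))
  checks <- data.frame(metric = names(expected), expected = unname(expected),
                       observed = unname(observed),
                       pass = unname(expected == observed),
                       stringsAsFactors = FALSE)
  structure(list(checks = checks, pass = all(checks$pass)),
            class = "fn_fidelity")
}

#' @export
print.fn_fidelity <- function(x, ...) {
  cat(sprintf("Fidelity report: %s\n",
              if (x$pass) "PASS" else "FAIL"))
  print(x$checks, row.names = FALSE)
  invisible(x)
}
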
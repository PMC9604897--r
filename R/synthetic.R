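## Seeded generators of structurally realistic regulatory models and of
## random directed graphs (oracle fodder for the topology metrics).
## Generation is a pure function of the configuration, including its
## seed: the same configuration always yields the identical object, and
## no global random state is consumed.

#' Synthetic model configuration
#'
#' @param n_genes Number of gene -> mRNA -> protein central-dogma chains.
#' @param n_extra_molecules Number of additional simple molecules strung
#'   into conversion chains.
#' @param n_phenotypes Number of phenotype sink species (at least 1).
#' @param cross_link_probability Probability that a protein is attached
#'   as a modifier to a randomly chosen conversion reaction.
#' @param inhibitor_fraction Probability that an attached modifier is an
#'   inhibitor rather than a catalyst.
#' @param seed Integer seed; generation is a pure function of the
#'   configuration.
#' @return A list of class `fn_synth_config`.
#' @export
synth_config <- function(n_genes = 11, n_extra_molecules = 6,
                         n_phenotypes = 4, cross_link_probability = 0.5,
                         inhibitor_fraction = 0.2, seed = 1L) {
  stopifnot(n_genes >= 0, n_extra_molecules >= 0, n_phenotypes >= 1,
            cross_link_probability >= 0, cross_link_probability <= 1,
            inhibitor_fraction >= 0, inhibitor_fraction <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_extra_molecules = as.integer(n_extra_molecules),
                 n_phenotypes = as.integer(n_phenotypes),
                 cross_link_probability = cross_link_probability,
                 inhibitor_fraction = inhibitor_fraction,
                 seed = as.integer(seed)),
            class = "fn_synth_config")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic regulatory model
#'
#' Emulates the structure of the curated fruiting model: per gene a
#' transcription (gene -> mRNA) and translation (mRNA -> protein)
#' reaction; extra simple molecules strung into conversion chains;
#' proteins attached as catalysts or inhibitors of randomly chosen
#' conversions; and at least one reaction path from the molecule pool
#' into every phenotype sink.  Everything lives in a single fungal-cell
#' compartment plus an environment compartment.
#'
#' @param config A [synth_config()].
#' @return A valid [fruit_model()].
#' @export
generate_model <- function(config = synth_config()) {
  stopifnot(inherits(config, "fn_synth_config"))
  with_local_seed(config$seed, {
    comps <- list(compartment("environment", kind = "environment"),
                  compartment("cell", kind = "fungal_cell"))
    sp <- list()
    rxs <- list()
    add_sp <- function(s) sp[[length(sp) + 1L]] <<- s
    add_rx <- function(r) rxs[[length(rxs) + 1L]] <<- r
    rid <- 0L
    next_rid <- function() { rid <<- rid + 1L; paste0("re", rid) }

    ng <- config$n_genes
    for (i in seq_len(ng)) {
      g <- sprintf("gene_%02d", i); m <- sprintf("mrna_%02d", i)
      p <- sprintf("protein_%02d", i)
      add_sp(species(g, "gene", "cell"))
      add_sp(species(m, "mRNA", "cell"))
      add_sp(species(p, "protein", "cell"))
      add_rx(reaction(next_rid(), g, m,
                      annotation = sprintf("transcription of %s", g)))
      add_rx(reaction(next_rid(), m, p,
                      annotation = sprintf("translation of %s", m)))
    }

    nm <- config$n_extra_molecules
    mols <- sprintf("molecule_%02d", seq_len(nm))
    for (mo in mols) add_sp(species(mo, "simple_molecule", "cell"))
    conv <- character()
    if (nm >= 2L) {
      for (i in seq_len(nm - 1L)) {
        id <- next_rid()
        add_rx(reaction(id, mols[i], mols[i + 1L],
                        annotation = "molecule conversion"))
        conv <- c(conv, id)
      }
    }

    phen <- sprintf("phenotype_%02d", seq_len(config$n_phenotypes))
    for (ph in phen) add_sp(species(ph, "phenotype", "cell"))
    feeders <- if (nm) mols else if (ng) sprintf("protein_%02d", seq_len(ng))
               else character()
    for (ph in phen) {
      id <- next_rid()
      if (length(feeders)) {
        src <- feeders[sample.int(length(feeders), 1L)]
        add_rx(reaction(id, src, ph, annotation = "phenotype formation"))
      } else {
        add_rx(reaction(id, character(), ph,
                        annotation = "phenotype formation"))
      }
      conv <- c(conv, id)
    }

    ## attach proteins as modifiers of conversions
    if (ng && length(conv)) {
      for (i in seq_len(ng)) {
        if (stats::runif(1) <= config$cross_link_probability) {
          target_id <- conv[sample.int(length(conv), 1L)]
          mode <- if (stats::runif(1) < config$inhibitor_fraction)
            "inhibitor" else "catalyst"
          p <- sprintf("protein_%02d", i)
          for (j in seq_along(rxs)) {
            if (rxs[[j]]$id == target_id &&
                !p %in% c(names(rxs[[j]]$modifiers),
                          names(rxs[[j]]$reactants))) {
              rxs[[j]]$modifiers <-
                c(rxs[[j]]$modifiers, stats::setNames(mode, p))
              break
            }
          }
        }
      }
    }
    m <- fruit_model(sprintf("synthetic_seed%d", config$seed),
                     compartments = comps, species = sp, reactions = rxs)
    stop_if_invalid(m)
    m
  })
}

#' Generate a random simple directed graph
#'
#' Uniformly samples `n_edges` distinct directed edges (no self-loops)
#' among `n_nodes` nodes; with `bipartite = TRUE` nodes are split into
#' species/reaction halves and edges only join the two classes, so the
#' result is a legal reaction-graph shape.
#'
#' @param n_nodes Number of nodes (at least 1).
#' @param n_edges Number of directed edges; must not exceed the number of
#'   permissible node pairs.
#' @param seed Integer seed.
#' @param bipartite Logical.
#' @return An [directed_graph()].
#' @export
generate_graph <- function(n_nodes, n_edges, seed = 1L, bipartite = FALSE) {
  stopifnot(n_nodes >= 1, n_edges >= 0)
  with_local_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n_nodes))
    if (bipartite) {
      ns <- ceiling(n_nodes / 2)
      kind <- c(rep("species", ns), rep("reaction", n_nodes - ns))
      ok <- which(outer(kind, kind, `!=`), arr.ind = TRUE)
    } else {
      kind <- rep("node", n_nodes)
      ok <- which(!diag(n_nodes), arr.ind = TRUE)
    }
    if (n_edges > nrow(ok))
      stop("infeasible edge count: at most ", nrow(ok), " edges possible")
    pick <- sample.int(nrow(ok), n_edges)
    edges <- data.frame(from = ids[ok[pick, 1L]], to = ids[ok[pick, 2L]],
                        kind = rep("edge", n_edges),
                        stringsAsFactors = FALSE)
    directed_graph(data.frame(id = ids, kind = kind, label = ids,
                              stringsAsFactors = FALSE), edges)
  })
}
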
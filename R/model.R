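#' @keywords internal
"_PACKAGE"

## Controlled vocabularies for model elements.
COMPARTMENT_KINDS <- c("environment", "fungal_cell", "mitochondria",
                       "substrate", "other")
SPECIES_ROLES <- c("gene", "mRNA", "protein", "complex",
                   "simple_molecule", "receptor", "phenotype")
MODIFIER_MODES <- c("catalyst", "activator", "inhibitor")

#' Create a compartment
#'
#' Compartments partition the species of a fruiting model into the
#' physical locations the network spans: the growing environment, the
#' fungal cell, its mitochondria and the lignocellulosic substrate.
#'
#' @param id Unique identifier (character scalar).
#' @param name Human-readable name; defaults to `id`.
#' @param kind One of `"environment"`, `"fungal_cell"`, `"mitochondria"`,
#'   `"substrate"`, `"other"`.
#' @return A list of class `fn_compartment`.
#' @export
compartment <- function(id, name = id, kind = "other") {
  kind <- match.arg(kind, COMPARTMENT_KINDS)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name, kind = kind),
            class = "fn_compartment")
}

#' Create a species
#'
#' A species is any molecular entity or phenotypic readout in the model:
#' genes, mRNAs, proteins, protein complexes, simple molecules (small
#' metabolites and environmental stimuli), membrane receptors, and
#' phenotype species used as accumulating outcome readouts.
#'
#' @param id Unique identifier.
#' @param role One of `"gene"`, `"mRNA"`, `"protein"`, `"complex"`,
#'   `"simple_molecule"`, `"receptor"`, `"phenotype"`.
#' @param compartment Identifier of the containing compartment.
#' @param name Human-readable name; defaults to `id`.
#' @param initial_amount Non-negative initial amount in arbitrary
#'   concentration units, or `NA` to fall back on the per-role default
#'   (see [default_initial_conditions()]).
#' @param constant Logical; constant species (environmental stimuli such
#'   as blue light or humidity) are held fixed during simulation.
#' @return A list of class `fn_species`.
#' @export
species <- function(id, role, compartment, name = id,
                    initial_amount = NA_real_, constant = FALSE) {
  role <- match.arg(role, SPECIES_ROLES)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(compartment), length(compartment) == 1L,
            is.logical(constant), length(constant) == 1L)
  initial_amount <- as.numeric(initial_amount)
  structure(list(id = id, name = name, role = role,
                 compartment = compartment,
                 initial_amount = initial_amount, constant = constant),
            class = "fn_species")
}

#' Create a reaction
#'
#' @param id Unique identifier (the curated fruiting model uses
#'   `"re1"` .. `"re39"`).
#' @param reactants,products Named numeric vectors mapping species
#'   identifiers to positive integer stoichiometries.  Either may be
#'   empty: a reaction with no reactants is a source (constant influx
#'   scaled by its modifiers), one with no products is a sink
#'   (degradation).
#' @param modifiers Named character vector mapping species identifiers to
#'   a modifier mode: `"catalyst"`, `"activator"` or `"inhibitor"`.
#' @param name Human-readable name; defaults to `id`.
#' @param reversible Logical, default `FALSE` (all curated reactions are
#'   irreversible).
#' @param annotation Free-text literature role of the reaction.
#' @return A list of class `fn_reaction`.
#' @export
reaction <- function(id, reactants = numeric(), products = numeric(),
                     modifiers = character(), name = id,
                     reversible = FALSE, annotation = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  reactants <- as_stoich(reactants, "reactants")
  products <- as_stoich(products, "products")
  if (length(modifiers)) {
    stopifnot(is.character(modifiers), !is.null(names(modifiers)))
    bad <- setdiff(unname(modifiers), MODIFIER_MODES)
    if (length(bad))
      stop("unknown modifier mode(s): ", paste(bad, collapse = ", "))
  } else {
    modifiers <- stats::setNames(character(), character())
  }
  structure(list(id = id, name = name, reactants = reactants,
                 products = products, modifiers = modifiers,
                 reversible = isTRUE(reversible), annotation = annotation),
            class = "fn_reaction")
}

as_stoich <- function(x, what) {
  if (is.character(x) && is.null(names(x)))  # bare species ids, stoich 1
    x <- stats::setNames(rep(1, length(x)), x)
  if (!length(x)) return(stats::setNames(numeric(), character()))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be a named vector (names are species ids)")
  x <- stats::setNames(as.numeric(x), names(x))
  if (any(!is.finite(x)) || any(x <= 0) || any(x != round(x)))
    stop(what, " stoichiometries must be positive integers")
  x
}

#' Create a fruiting model
#'
#' A model bundles compartments, species and reactions.  Use
#' [validate_model()] to check the cross-reference and uniqueness
#' invariants; construction itself performs only shape checks so invalid
#' models can be built deliberately and then diagnosed.
#'
#' @param id Model identifier.
#' @param compartments List of [compartment()] objects.
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @return A list of class `fn_model`.
#' @export
fruit_model <- function(id, compartments = list(), species = list(),
                        reactions = list()) {
  stopifnot(is.character(id), length(id) == 1L,
            all(vapply(compartments, inherits, TRUE, "fn_compartment")),
            all(vapply(species, inherits, TRUE, "fn_species")),
            all(vapply(reactions, inherits, TRUE, "fn_reaction")))
  structure(list(id = id, compartments = compartments, species = species,
                 reactions = reactions),
            class = "fn_model")
}

#' @export
print.fn_model <- function(x, ...) {
  cs <- composition_summary(x)
  cat(sprintf(
    "<fn_model '%s'>: %d compartments, %d species (%d genes, %d mRNA, %d proteins), %d reactions\n",
    x$id, cs$compartments, cs$species, cs$genes, cs$mRNA, cs$proteins,
    cs$reactions))
  invisible(x)
}

#' Species table of a model
#'
#' @param model A [fruit_model()].
#' @return A `data.frame` with one row per species: `id`, `name`, `role`,
#'   `compartment`, `initial_amount`, `constant`.
#' @export
species_table <- function(model) {
  stopifnot(inherits(model, "fn_model"))
  data.frame(
    id = vapply(model$species, `[[`, "", "id"),
    name = vapply(model$species, `[[`, "", "name"),
    role = vapply(model$species, `[[`, "", "role"),
    compartment = vapply(model$species, `[[`, "", "compartment"),
    initial_amount = vapply(model$species, `[[`, 0, "initial_amount"),
    constant = vapply(model$species, `[[`, TRUE, "constant"),
    stringsAsFactors = FALSE)
}

#' Reaction participation table
#'
#' Long-format view of every (species, reaction) participation, one row
#' per reactant, product or modifier slot.
#'
#' @param model A [fruit_model()].
#' @return A `data.frame` with columns `reaction`, `species`, `part`
#'   (`"reactant"`, `"product"`, `"modifier"`), `stoichiometry` (NA for
#'   modifiers) and `mode` (NA except for modifiers).
#' @export
participation_table <- function(model) {
  stopifnot(inherits(model, "fn_model"))
  rows <- lapply(model$reactions, function(r) {
    data.frame(
      reaction = r$id,
      species = c(names(r$reactants), names(r$products), names(r$modifiers)),
      part = c(rep("reactant", length(r$reactants)),
               rep("product", length(r$products)),
               rep("modifier", length(r$modifiers))),
      stoichiometry = c(unname(r$reactants), unname(r$products),
                        rep(NA_real_, length(r$modifiers))),
      mode = c(rep(NA_character_, length(r$reactants) + length(r$products)),
               unname(r$modifiers)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(reaction = character(), species = character(),
                      part = character(), stoichiometry = numeric(),
                      mode = character(), stringsAsFactors = FALSE)
  out
}

#' Validate a model
#'
#' Checks every schema invariant and returns the violations as data
#' rather than raising: identifier uniqueness, resolvable
#' cross-references, non-negative initial amounts, at least one reactant
#' or product per reaction, and no species acting as both reactant and
#' modifier of the same reaction.
#'
#' @param model A [fruit_model()].
#' @return A `data.frame` with columns `element`, `rule` and `message`,
#'   one row per broken invariant; zero rows when the model is valid.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "fn_model"))
  v <- list()
  add <- function(element, rule, message)
    v[[length(v) + 1L]] <<- data.frame(element = element, rule = rule,
                                       message = message,
                                       stringsAsFactors = FALSE)

  cids <- vapply(model$compartments, `[[`, "", "id")
  sids <- vapply(model$species, `[[`, "", "id")
  rids <- vapply(model$reactions, `[[`, "", "id")
  for (dup in unique(c(cids[duplicated(cids)], sids[duplicated(sids)],
                       rids[duplicated(rids)])))
    add(dup, "unique_id", sprintf("identifier '%s' is not unique", dup))
  all_ids <- c(cids, sids, rids)
  for (dup in unique(all_ids[duplicated(all_ids)]))
    if (!dup %in% c(cids[duplicated(cids)], sids[duplicated(sids)],
                    rids[duplicated(rids)]))
      add(dup, "unique_id",
          sprintf("identifier '%s' is reused across element types", dup))

  for (sp in model$species) {
    if (!sp$compartment %in% cids)
      add(sp$id, "compartment_resolves",
          sprintf("species '%s' references unknown compartment '%s'",
                  sp$id, sp$compartment))
    if (!is.na(sp$initial_amount) && sp$initial_amount < 0)
      add(sp$id, "initial_amount_nonnegative",
          sprintf("species '%s' has negative initial amount", sp$id))
  }

  for (r in model$reactions) {
    if (length(r$reactants) + length(r$products) == 0L)
      add(r$id, "has_participant",
          sprintf("reaction '%s' has neither reactants nor products", r$id))
    for (ref in unique(c(names(r$reactants), names(r$products),
                         names(r$modifiers))))
      if (!ref %in% sids)
        add(r$id, "species_resolves",
            sprintf("reaction '%s' references unknown species '%s'",
                    r$id, ref))
    both <- intersect(names(r$reactants), names(r$modifiers))
    for (b in both)
      add(r$id, "reactant_not_modifier",
          sprintf("species '%s' is both reactant and modifier of '%s'",
                  b, r$id))
  }

  if (length(v)) do.call(rbind, v)
  else data.frame(element = character(), rule = character(),
                  message = character(), stringsAsFactors = FALSE)
}

stop_if_invalid <- function(model) {
  v <- validate_model(model)
  if (nrow(v))
    stop("invalid model; validate_model() reports ", nrow(v),
         " violation(s), first: ", v$message[[1L]], call. = FALSE)
  invisible(model)
}

#' Composition summary
#'
#' Counts model elements by role.  `proteins` counts species of role
#' `"protein"` together with role `"complex"`, so that a protein-protein
#' or protein-cofactor complex contributes to the protein tally and the
#' role counts sum to the total species count.
#'
#' @param model A valid [fruit_model()].
#' @return A list of class `fn_composition` with fields `compartments`,
#'   `species`, `genes`, `mRNA`, `proteins`, `simple_molecules`,
#'   `receptors`, `phenotypes`, `reactions`.
#' @export
composition_summary <- function(model) {
  stop_if_invalid(model)
  roles <- vapply(model$species, `[[`, "", "role")
  structure(list(
    compartments = length(model$compartments),
    species = length(model$species),
    genes = sum(roles == "gene"),
    mRNA = sum(roles == "mRNA"),
    proteins = sum(roles %in% c("protein", "complex")),
    simple_molecules = sum(roles == "simple_molecule"),
    receptors = sum(roles == "receptor"),
    phenotypes = sum(roles == "phenotype"),
    reactions = length(model$reactions)
  ), class = "fn_composition")
}

#' @export
print.fn_composition <- function(x, ...) {
  cat(sprintf(paste0(
    "%d compartments, %d species (%d genes, %d mRNA, %d proteins, ",
    "%d simple molecules, %d receptors, %d phenotypes), %d reactions\n"),
    x$compartments, x$species, x$genes, x$mRNA, x$proteins,
    x$simple_molecules, x$receptors, x$phenotypes, x$reactions))
  invisible(x)
}

#' Look up one reaction by id
#' @param model A [fruit_model()].
#' @param id Reaction identifier.
#' @return The [reaction()] object.
#' @keywords internal
get_reaction <- function(model, id) {
  for (r in model$reactions) if (r$id == id) return(r)
  stop("unknown reaction id '", id, "'", call. = FALSE)
}
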
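## SBML Level 2 Version 4 reading and writing (the CellDesigner-era
## level), plus a JSON model dialect.  Core SBML has no notion of a
## "phenotype" species or of our role vocabulary, so species role and
## modifier mode are stored both as SBO terms and in a namespaced
## annotation block that the reader prefers; kinetic laws are embedded as
## content MathML.

SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
FN_NS <- "urn:fruitnet:annotations"

SBO_ROLE <- c(gene = "SBO:0000243", mRNA = "SBO:0000250",
              protein = "SBO:0000252", complex = "SBO:0000253",
              simple_molecule = "SBO:0000247", receptor = "SBO:0000244",
              phenotype = "SBO:0000358")
SBO_MODE <- c(catalyst = "SBO:0000013", activator = "SBO:0000459",
              inhibitor = "SBO:0000020")

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write a model as SBML Level 2 Version 4
#'
#' @param model A valid [fruit_model()].
#' @param file Path to write; when `NULL` the SBML document is returned
#'   as a character string.
#' @param laws Optional rate laws from [assign_all()]; when given, each
#'   reaction's law is embedded as a `kineticLaw` (content MathML plus
#'   local parameters).
#' @return `file` (invisibly), or the SBML text when `file` is `NULL`.
#' @export
write_sbml <- function(model, file = NULL, laws = NULL) {
  stop_if_invalid(model)
  out <- character()
  w <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  w("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  w(sprintf("<sbml xmlns=\"%s\" level=\"2\" version=\"4\">", SBML_NS))
  w(sprintf("  <model id=\"%s\">", xml_escape(model$id)))

  w("    <listOfCompartments>")
  for (cm in model$compartments)
    w(sprintf(paste0("      <compartment id=\"%s\" name=\"%s\" size=\"1\">",
                     "<annotation><fn:kind xmlns:fn=\"%s\">%s</fn:kind>",
                     "</annotation></compartment>"),
              cm$id, xml_escape(cm$name), FN_NS, cm$kind))
  w("    </listOfCompartments>")

  w("    <listOfSpecies>")
  for (sp in model$species) {
    amt <- if (is.na(sp$initial_amount)) "" else
      sprintf(" initialAmount=\"%.17g\"", sp$initial_amount)
    w(sprintf(paste0("      <species id=\"%s\" name=\"%s\" compartment=",
                     "\"%s\"%s constant=\"%s\" sboTerm=\"%s\">",
                     "<annotation><fn:role xmlns:fn=\"%s\">%s</fn:role>",
                     "</annotation></species>"),
              sp$id, xml_escape(sp$name), sp$compartment, amt,
              tolower(sp$constant), SBO_ROLE[[sp$role]], FN_NS, sp$role))
  }
  w("    </listOfSpecies>")

  w("    <listOfReactions>")
  for (r in model$reactions) {
    w(sprintf("      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\">",
              r$id, xml_escape(r$name), tolower(r$reversible)))
    if (nzchar(r$annotation))
      w(sprintf("        <annotation><fn:note xmlns:fn=\"%s\">%s</fn:note></annotation>",
                FN_NS, xml_escape(r$annotation)))
    if (length(r$reactants)) {
      w("        <listOfReactants>")
      for (s in names(r$reactants))
        w(sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%g\"/>",
                  s, r$reactants[[s]]))
      w("        </listOfReactants>")
    }
    if (length(r$products)) {
      w("        <listOfProducts>")
      for (s in names(r$products))
        w(sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%g\"/>",
                  s, r$products[[s]]))
      w("        </listOfProducts>")
    }
    if (length(r$modifiers)) {
      w("        <listOfModifiers>")
      for (s in names(r$modifiers))
        w(sprintf(paste0("          <modifierSpeciesReference species=\"%s\"",
                         " sboTerm=\"%s\"><annotation>",
                         "<fn:mode xmlns:fn=\"%s\">%s</fn:mode>",
                         "</annotation></modifierSpeciesReference>"),
                  s, SBO_MODE[[r$modifiers[[s]]]], FN_NS, r$modifiers[[s]]))
      w("        </listOfModifiers>")
    }
    if (!is.null(laws) && r$id %in% names(laws)) {
      law <- laws[[r$id]]
      w("        <kineticLaw>")
      w(paste0("          ", render_expression(law, "mathml")))
      w("          <listOfParameters>")
      for (pn in names(law$parameters))
        w(sprintf("            <parameter id=\"%s\" value=\"%.17g\"/>",
                  pn, law$parameters[[pn]]))
      w("          </listOfParameters>")
      w("        </kineticLaw>")
    }
    w("      </reaction>")
  }
  w("    </listOfReactions>")
  w("  </model>")
  w("</sbml>")
  txt <- paste(out, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' Read a model from SBML
#'
#' Reads the SBML L2V4 subset written by [write_sbml()]: compartments
#' with kind annotations, species with role annotations (falling back on
#' SBO terms), reactions with reactants/products/modifiers.  Unresolvable
#' references are reported with the offending element.
#'
#' @param source Path or literal SBML string.
#' @return A [fruit_model()].
#' @export
read_sbml <- function(source) {
  doc <- xml2::read_xml(source)
  ns <- c(s = SBML_NS, fn = FN_NS)
  mnode <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mnode, "xml_missing")) stop("no <model> element found")
  att <- function(node, a) xml2::xml_attr(node, a)

  comps <- lapply(xml2::xml_find_all(mnode, ".//s:compartment", ns),
    function(nd) {
      kind <- xml2::xml_text(xml2::xml_find_first(nd, ".//fn:kind", ns))
      if (is.na(kind)) kind <- "other"
      compartment(att(nd, "id"), name = att(nd, "name") %||% att(nd, "id"),
                  kind = kind)
    })
  cids <- vapply(comps, `[[`, "", "id")

  sps <- lapply(xml2::xml_find_all(mnode, ".//s:species", ns),
    function(nd) {
      role <- xml2::xml_text(xml2::xml_find_first(nd, ".//fn:role", ns))
      if (is.na(role)) {
        sbo <- att(nd, "sboTerm")
        role <- names(SBO_ROLE)[match(sbo, SBO_ROLE)]
        if (is.na(role)) role <- "simple_molecule"
      }
      cmp <- att(nd, "compartment")
      if (!cmp %in% cids)
        stop("species '", att(nd, "id"),
             "' references unresolved compartment '", cmp, "'")
      amt <- att(nd, "initialAmount")
      species(att(nd, "id"), role = role, compartment = cmp,
              name = att(nd, "name") %||% att(nd, "id"),
              initial_amount = if (is.na(amt)) NA_real_ else as.numeric(amt),
              constant = identical(att(nd, "constant"), "true"))
    })

  rxs <- lapply(xml2::xml_find_all(mnode, ".//s:reaction", ns),
    function(nd) {
      sref <- function(xp) {
        refs <- xml2::xml_find_all(nd, xp, ns)
        if (!length(refs)) return(stats::setNames(numeric(), character()))
        st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        st[is.na(st)] <- 1
        stats::setNames(st, xml2::xml_attr(refs, "species"))
      }
      mods <- xml2::xml_find_all(
        nd, "./s:listOfModifiers/s:modifierSpeciesReference", ns)
      modes <- character()
      if (length(mods)) {
        mode <- vapply(mods, function(m) {
          mm <- xml2::xml_text(xml2::xml_find_first(m, ".//fn:mode", ns))
          if (!is.na(mm)) return(mm)
          sbo <- xml2::xml_attr(m, "sboTerm")
          md <- names(SBO_MODE)[match(sbo, SBO_MODE)]
          if (is.na(md)) "catalyst" else md
        }, "")
        modes <- stats::setNames(mode, xml2::xml_attr(mods, "species"))
      }
      note <- xml2::xml_text(xml2::xml_find_first(nd, ".//fn:note", ns))
      reaction(att(nd, "id"),
               reactants = sref("./s:listOfReactants/s:speciesReference"),
               products = sref("./s:listOfProducts/s:speciesReference"),
               modifiers = modes,
               name = att(nd, "name") %||% att(nd, "id"),
               reversible = identical(att(nd, "reversible"), "true"),
               annotation = if (is.na(note)) "" else note)
    })

  m <- fruit_model(att(mnode, "id") %||% "model", compartments = comps,
                   species = sps, reactions = rxs)
  v <- validate_model(m)
  if (nrow(v))
    stop("SBML contains unresolved references: ", v$message[[1L]])
  m
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write / read the JSON model dialect
#'
#' A direct JSON rendering of the model schema: `id`, `compartments`
#' (id, name, kind), `species` (id, name, role, compartment,
#' initial_amount, constant) and `reactions` (id, name, reactants,
#' products, modifiers, reversible, annotation).  UTF-8, loss-free for
#' every schema field.
#'
#' @param model A valid [fruit_model()].
#' @param file Path, or `NULL` to return the JSON text.
#' @return `write_model_json`: the path or JSON string;
#'   `read_model_json`: a [fruit_model()].
#' @export
write_model_json <- function(model, file = NULL) {
  stop_if_invalid(model)
  obj <- list(
    id = model$id,
    compartments = lapply(model$compartments, function(cm)
      list(id = cm$id, name = cm$name, kind = cm$kind)),
    species = lapply(model$species, function(sp)
      list(id = sp$id, name = sp$name, role = sp$role,
           compartment = sp$compartment,
           initial_amount = sp$initial_amount, constant = sp$constant)),
    reactions = lapply(model$reactions, function(r)
      list(id = r$id, name = r$name,
           reactants = as.list(r$reactants),
           products = as.list(r$products),
           modifiers = as.list(r$modifiers),
           reversible = r$reversible, annotation = r$annotation)))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          null = "null", na = "null", pretty = TRUE)
  if (is.null(file)) return(as.character(txt))
  writeLines(as.character(txt), file)
  invisible(file)
}

#' @rdname write_model_json
#' @param source Path or literal JSON string.
#' @export
read_model_json <- function(source) {
  obj <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  nalist <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  comps <- lapply(obj$compartments, function(cm)
    compartment(cm$id, cm$name, cm$kind))
  sps <- lapply(obj$species, function(sp)
    species(sp$id, role = sp$role, compartment = sp$compartment,
            name = sp$name, initial_amount = nalist(sp$initial_amount),
            constant = isTRUE(sp$constant)))
  rxs <- lapply(obj$reactions, function(r) {
    tostoich <- function(x) {
      if (!length(x)) return(stats::setNames(numeric(), character()))
      stats::setNames(vapply(x, as.numeric, 0), names(x))
    }
    mods <- if (length(r$modifiers))
      stats::setNames(vapply(r$modifiers, as.character, ""),
                      names(r$modifiers)) else character()
    reaction(r$id, reactants = tostoich(r$reactants),
             products = tostoich(r$products), modifiers = mods,
             name = r$name, reversible = isTRUE(r$reversible),
             annotation = r$annotation %||% "")
  })
  fruit_model(obj$id, compartments = comps, species = sps, reactions = rxs)
}
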
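## Automatic rate-law assignment from reaction structure and modifier
## roles, in the style of SBMLsqueezer's defaults: generalized mass
## action (gma) everywhere, optionally Michaelis-Menten (mm) for
## single-substrate catalysed conversions.  Modifier factors are
## saturating (hyperbolic), so generated laws stay finite and
## non-negative for any non-negative state:
##
##   gma: v = k * prod [R_i]^s_i * prod [E_j]
##            * prod [A]/(K_A + [A]) * prod K_I/(K_I + [I])
##   mm:  v = V_max * [E] * [S] / (K_m + [S]) * (same A/I factors)
##
## Source reactions (no reactants) reduce to v = k * modifier factors.

#' Assign a rate law to one reaction
#'
#' @param reaction A [reaction()] object.
#' @param form `"gma"` (generalized mass action, default) or `"mm"`
#'   (irreversible Michaelis-Menten; requires exactly one reactant with
#'   unit stoichiometry and at least one catalyst).
#' @param defaults Named list of default parameter values; recognised
#'   names are `k`, `K_A`, `K_I`, `V_max`, `K_m` (all default 1.0,
#'   arbitrary units).
#' @return A list of class `fn_rate_law` with fields `reaction`, `form`,
#'   `parameters` (named numeric vector, names like `k_re6`,
#'   `K_I_re6_pofst_protein`) and `terms` (the structured factorisation
#'   used by [rate_function()] and [render_expression()]).
#' @export
assign_rate_law <- function(reaction, form = c("gma", "mm"),
                            defaults = list()) {
  stopifnot(inherits(reaction, "fn_reaction"))
  form <- match.arg(form)
  def <- function(nm) {
    if (!is.null(defaults[[nm]])) as.numeric(defaults[[nm]]) else 1.0
  }
  mods <- reaction$modifiers
  catalysts <- names(mods)[mods == "catalyst"]
  activators <- names(mods)[mods == "activator"]
  inhibitors <- names(mods)[mods == "inhibitor"]
  rid <- reaction$id

  params <- numeric()
  if (form == "mm") {
    if (length(reaction$reactants) != 1L || reaction$reactants[[1L]] != 1)
      stop("mm form requires exactly one reactant with unit stoichiometry ",
           "(reaction '", rid, "')")
    if (!length(catalysts))
      stop("mm form requires at least one catalyst (reaction '", rid, "')")
    params[paste0("V_max_", rid)] <- def("V_max")
    params[paste0("K_m_", rid)] <- def("K_m")
  } else {
    params[paste0("k_", rid)] <- def("k")
  }
  for (a in activators) params[paste0("K_A_", rid, "_", a)] <- def("K_A")
  for (i in inhibitors) params[paste0("K_I_", rid, "_", i)] <- def("K_I")

  structure(list(
    reaction = rid,
    form = form,
    parameters = params,
    terms = list(reactants = reaction$reactants, catalysts = catalysts,
                 activators = activators, inhibitors = inhibitors)
  ), class = "fn_rate_law")
}

#' Assign rate laws to every reaction of a model
#'
#' @param model A valid [fruit_model()].
#' @param policy `"gma"` assigns generalized mass action everywhere
#'   (default); `"mm_enzymes"` assigns Michaelis-Menten to
#'   single-substrate catalysed conversions and gma elsewhere.
#' @param defaults Default parameter values, see [assign_rate_law()].
#' @param overrides Optional named numeric vector of per-parameter
#'   overrides keyed by full parameter name (e.g. `k_re6 = 2`), applied
#'   after assignment.
#' @return Named list of `fn_rate_law`, one per reaction id.
#' @export
assign_all <- function(model, policy = c("gma", "mm_enzymes"),
                       defaults = list(), overrides = numeric()) {
  stop_if_invalid(model)
  policy <- match.arg(policy)
  laws <- lapply(model$reactions, function(r) {
    form <- "gma"
    if (policy == "mm_enzymes" && length(r$reactants) == 1L &&
        r$reactants[[1L]] == 1 && any(r$modifiers == "catalyst"))
      form <- "mm"
    assign_rate_law(r, form = form, defaults = defaults)
  })
  names(laws) <- vapply(model$reactions, `[[`, "", "id")
  if (length(overrides)) {
    stopifnot(!is.null(names(overrides)))
    for (nm in names(overrides)) {
      hit <- FALSE
      for (i in seq_along(laws)) {
        if (nm %in% names(laws[[i]]$parameters)) {
          laws[[i]]$parameters[[nm]] <- as.numeric(overrides[[nm]])
          hit <- TRUE
        }
      }
      if (!hit) stop("override names unknown parameter '", nm, "'")
    }
  }
  laws
}

#' Evaluate a rate law at a state
#'
#' @param law An `fn_rate_law`.
#' @param state Named numeric vector of species amounts (must cover every
#'   species the law references).
#' @param parameters Optional replacement parameter vector; defaults to
#'   the law's own.
#' @return Single non-negative finite numeric rate.
#' @export
eval_rate <- function(law, state, parameters = law$parameters) {
  stopifnot(inherits(law, "fn_rate_law"))
  tm <- law$terms
  rid <- law$reaction
  need <- c(names(tm$reactants), tm$catalysts, tm$activators, tm$inhibitors)
  missing <- setdiff(need, names(state))
  if (length(missing))
    stop("state misses species: ", paste(missing, collapse = ", "))
  p <- function(nm) parameters[[nm]]

  if (law$form == "mm") {
    s <- names(tm$reactants)[[1L]]
    v <- p(paste0("V_max_", rid)) * state[[s]] /
      (p(paste0("K_m_", rid)) + state[[s]])
  } else {
    v <- p(paste0("k_", rid))
    for (s in names(tm$reactants)) v <- v * state[[s]]^tm$reactants[[s]]
  }
  for (e in tm$catalysts) v <- v * state[[e]]
  for (a in tm$activators) {
    ka <- p(paste0("K_A_", rid, "_", a))
    v <- v * state[[a]] / (ka + state[[a]])
  }
  for (i in tm$inhibitors) {
    ki <- p(paste0("K_I_", rid, "_", i))
    v <- v * ki / (ki + state[[i]])
  }
  unname(v)
}

#' Render a rate-law expression
#'
#' @param law An `fn_rate_law`.
#' @param dialect `"text"` for unambiguous infix text, `"mathml"` for
#'   content MathML suitable for embedding in an SBML `kineticLaw`.
#' @return A character scalar.
#' @export
render_expression <- function(law, dialect = c("text", "mathml")) {
  stopifnot(inherits(law, "fn_rate_law"))
  dialect <- match.arg(dialect)
  tm <- law$terms
  rid <- law$reaction

  if (dialect == "text") {
    fac <- character()
    if (law$form == "mm") {
      s <- names(tm$reactants)[[1L]]
      fac <- c(fac, sprintf("V_max_%s * %s / (K_m_%s + %s)", rid, s, rid, s))
    } else {
      fac <- c(fac, paste0("k_", rid))
      for (s in names(tm$reactants)) {
        st <- tm$reactants[[s]]
        fac <- c(fac, if (st == 1) s else sprintf("%s^%d", s, as.integer(st)))
      }
    }
    fac <- c(fac, tm$catalysts)
    for (a in tm$activators)
      fac <- c(fac, sprintf("%s / (K_A_%s_%s + %s)", a, rid, a, a))
    for (i in tm$inhibitors)
      fac <- c(fac, sprintf("K_I_%s_%s / (K_I_%s_%s + %s)",
                            rid, i, rid, i, i))
    return(paste(fac, collapse = " * "))
  }

  ## content MathML
  ci <- function(x) paste0("<ci> ", x, " </ci>")
  divide <- function(a, b)
    paste0("<apply><divide/>", a, b, "</apply>")
  plus <- function(a, b) paste0("<apply><plus/>", a, b, "</apply>")
  pow <- function(a, n)
    paste0("<apply><power/>", a, "<cn type=\"integer\"> ",
           as.integer(n), " </cn></apply>")
  fac <- character()
  if (law$form == "mm") {
    s <- names(tm$reactants)[[1L]]
    fac <- c(fac, ci(paste0("V_max_", rid)),
             divide(ci(s), plus(ci(paste0("K_m_", rid)), ci(s))))
  } else {
    fac <- c(fac, ci(paste0("k_", rid)))
    for (s in names(tm$reactants)) {
      st <- tm$reactants[[s]]
      fac <- c(fac, if (st == 1) ci(s) else pow(ci(s), st))
    }
  }
  fac <- c(fac, vapply(tm$catalysts, ci, ""))
  for (a in tm$activators)
    fac <- c(fac, divide(ci(a), plus(ci(paste0("K_A_", rid, "_", a)), ci(a))))
  for (i in tm$inhibitors)
    fac <- c(fac, divide(ci(paste0("K_I_", rid, "_", i)),
                         plus(ci(paste0("K_I_", rid, "_", i)), ci(i))))
  body <- if (length(fac) == 1L) fac else
    paste0("<apply><times/>", paste(fac, collapse = ""), "</apply>")
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">", body,
         "</math>")
}

#' Parse a rate law from its MathML rendering
#'
#' Inverse of [render_expression()] for the MathML dialect restricted to
#' the expression family this package generates (products of symbols,
#' integer powers and the hyperbolic modifier quotients).  Returns a
#' plain evaluator closure over a state/parameter environment; used to
#' round-trip kinetic laws through SBML.
#'
#' @param mathml Character scalar of content MathML.
#' @return A function `f(values)` where `values` is a named numeric
#'   vector covering every `<ci>` symbol.
#' @export
mathml_evaluator <- function(mathml) {
  doc <- xml2::read_xml(mathml)
  ns <- c(m = "http://www.w3.org/1998/Math/MathML")
  node_to_expr <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "math")
      return(node_to_expr(xml2::xml_child(node)))
    if (nm == "ci")
      return(as.name(trimws(xml2::xml_text(node))))
    if (nm == "cn")
      return(as.numeric(trimws(xml2::xml_text(node))))
    if (nm == "apply") {
      kids <- xml2::xml_children(node)
      op <- xml2::xml_name(kids[[1L]])
      args <- lapply(kids[-1L], node_to_expr)
      fun <- switch(op, times = "*", divide = "/", plus = "+",
                    power = "^", minus = "-",
                    stop("unsupported MathML operator: ", op))
      expr <- args[[1L]]
      for (k in seq_along(args)[-1L])
        expr <- call(fun, expr, args[[k]])
      return(expr)
    }
    stop("unsupported MathML node: ", nm)
  }
  expr <- node_to_expr(xml2::xml_root(doc))
  function(values) eval(expr, envir = as.list(values))
}
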
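## ODE simulation of a model under assigned rate laws, the per-role
## initial-condition scheme, and initial-amount scans (dose-response
## style readouts of terminal amounts).

#' Default initial conditions by species role
#'
#' The initial-amount scheme of the fruiting model, in arbitrary
#' concentration units: genes 0.5, mRNA 1.0, proteins and complexes 2.0,
#' phenotypes and phenotypic responses 2.5, simple molecules and
#' receptors 0.5 (basal amounts).  An explicit per-species
#' `initial_amount` in the model overrides the role default.
#'
#' @param model A valid [fruit_model()].
#' @return Named numeric vector, one entry per species in model order.
#' @export
default_initial_conditions <- function(model) {
  stop_if_invalid(model)
  role_default <- c(gene = 0.5, mRNA = 1.0, protein = 2.0, complex = 2.0,
                    simple_molecule = 0.5, receptor = 0.5, phenotype = 2.5)
  st <- species_table(model)
  if (!nrow(st)) return(stats::setNames(numeric(), character()))
  amounts <- unname(role_default[st$role])
  explicit <- !is.na(st$initial_amount)
  amounts[explicit] <- st$initial_amount[explicit]
  stats::setNames(amounts, st$id)
}

#' Simulation settings
#'
#' @param t_end End time (arbitrary time units, default 10 - long enough
#'   for the curated model to approach steady behaviour).
#' @param n_points Number of output points including t = 0 (default 200).
#' @param rtol,atol Relative / absolute solver tolerances (defaults 1e-8
#'   and 1e-10).
#' @param clamp_negative If `TRUE` (default), values in `[-atol, 0)` are
#'   clamped to 0 and any excursion below `-atol` is an error.
#' @return A list of class `fn_settings`.
#' @export
simulation_settings <- function(t_end = 10, n_points = 200,
                                rtol = 1e-8, atol = 1e-10,
                                clamp_negative = TRUE) {
  stopifnot(t_end > 0, n_points >= 2, rtol > 0, atol > 0)
  structure(list(t_end = t_end, n_points = as.integer(n_points),
                 rtol = rtol, atol = atol,
                 clamp_negative = isTRUE(clamp_negative)),
            class = "fn_settings")
}

## Precompile laws into an index-based evaluator and build the
## stoichiometry matrix (species x reactions, products minus reactants).
compile_system <- function(model, laws) {
  sids <- vapply(model$species, `[[`, "", "id")
  rids <- vapply(model$reactions, `[[`, "", "id")
  missing <- setdiff(rids, names(laws))
  if (length(missing))
    stop("no rate law for reaction(s): ", paste(missing, collapse = ", "))
  nS <- length(sids); nR <- length(rids)
  S <- matrix(0, nS, nR, dimnames = list(sids, rids))
  for (r in model$reactions) {
    for (s in names(r$reactants)) S[s, r$id] <- S[s, r$id] - r$reactants[[s]]
    for (s in names(r$products)) S[s, r$id] <- S[s, r$id] + r$products[[s]]
  }
  constant <- vapply(model$species, `[[`, TRUE, "constant")
  S[constant, ] <- 0

  compiled <- lapply(rids, function(rid) {
    law <- laws[[rid]]
    tm <- law$terms
    p <- law$parameters
    pr <- function(nm) unname(p[[nm]])
    list(
      mm = law$form == "mm",
      k = if (law$form == "gma") pr(paste0("k_", rid)) else NA_real_,
      vmax = if (law$form == "mm") pr(paste0("V_max_", rid)) else NA_real_,
      km = if (law$form == "mm") pr(paste0("K_m_", rid)) else NA_real_,
      ri = match(names(tm$reactants), sids),
      rs = unname(tm$reactants),
      ei = match(tm$catalysts, sids),
      ai = match(tm$activators, sids),
      ka = vapply(tm$activators, function(a)
        pr(paste0("K_A_", rid, "_", a)), 0),
      ii = match(tm$inhibitors, sids),
      ki = vapply(tm$inhibitors, function(i)
        pr(paste0("K_I_", rid, "_", i)), 0))
  })

  rates <- function(y) {
    y <- pmax(y, 0)  # guard against solver round-off below zero
    vapply(compiled, function(cl) {
      if (cl$mm) {
        s <- y[cl$ri[[1L]]]
        v <- cl$vmax * s / (cl$km + s)
      } else {
        v <- cl$k
        if (length(cl$ri)) v <- v * prod(y[cl$ri]^cl$rs)
      }
      if (length(cl$ei)) v <- v * prod(y[cl$ei])
      if (length(cl$ai)) v <- v * prod(y[cl$ai] / (cl$ka + y[cl$ai]))
      if (length(cl$ii)) v <- v * prod(cl$ki / (cl$ki + y[cl$ii]))
      v
    }, 0)
  }
  list(S = S, rates = rates, sids = sids)
}

#' Integrate a model
#'
#' Solves `d[X]/dt = sum(produced) - sum(consumed)` over the assigned
#' rate laws with a stiff-capable implicit solver
#' ([deSolve::lsoda()], which switches to BDF when the problem is
#' stiff).  Constant species are held fixed.
#'
#' @param model A valid [fruit_model()].
#' @param laws Rate laws from [assign_all()] (every reaction must have
#'   one).
#' @param ics Named numeric vector of initial conditions; defaults to
#'   [default_initial_conditions()].  All values must be non-negative.
#' @param settings A [simulation_settings()] object.
#' @return A list of class `fn_trajectory` with `time` (length
#'   `n_points`) and `amounts` (matrix, one column per species).
#' @export
integrate_model <- function(model, laws, ics = NULL,
                            settings = simulation_settings()) {
  stop_if_invalid(model)
  stopifnot(inherits(settings, "fn_settings"))
  sys <- compile_system(model, laws)
  if (is.null(ics)) ics <- default_initial_conditions(model)
  missing <- setdiff(sys$sids, names(ics))
  if (length(missing))
    stop("initial conditions miss species: ",
         paste(missing, collapse = ", "))
  y0 <- ics[sys$sids]
  if (any(y0 < 0)) stop("initial conditions must be non-negative")

  times <- seq(0, settings$t_end, length.out = settings$n_points)
  deriv <- function(t, y, parms) list(as.numeric(sys$S %*% sys$rates(y)))
  sol <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                        rtol = settings$rtol, atol = settings$atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("solver failure near t = ", max(sol[, 1L]))
  amounts <- unclass(sol)[, -1L, drop = FALSE]
  if (settings$clamp_negative) {
    low <- min(amounts)
    if (low < -settings$atol * 100)
      stop("negative excursion beyond tolerance: min = ", low)
    amounts[amounts < 0] <- 0
  }
  structure(list(time = times, amounts = amounts, species = sys$sids),
            class = "fn_trajectory")
}

#' @export
print.fn_trajectory <- function(x, ...) {
  cat(sprintf("<fn_trajectory>: %d species over t = [0, %g], %d points\n",
              ncol(x$amounts), max(x$time), length(x$time)))
  invisible(x)
}

#' Trajectory as tidy data frame
#'
#' @param x An `fn_trajectory`.
#' @param row.names,optional Unused, for S3 compatibility.
#' @param ... Unused.
#' @return Long data.frame with columns `time`, `species`, `amount`.
#' @export
as.data.frame.fn_trajectory <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(time = rep(x$time, times = length(x$species)),
             species = rep(x$species, each = length(x$time)),
             amount = as.vector(x$amounts),
             stringsAsFactors = FALSE)
}

#' Terminal amounts of a trajectory
#' @param traj An `fn_trajectory`.
#' @return Named numeric vector of the amounts at `t_end`.
#' @export
terminal_state <- function(traj) {
  stopifnot(inherits(traj, "fn_trajectory"))
  stats::setNames(as.numeric(traj$amounts[nrow(traj$amounts), ]),
                  traj$species)
}

#' Initial-amount scan
#'
#' Repeats the integration over a grid of initial amounts for one species
#' (all other species at their defaults) and records the terminal amount
#' of a readout species: the dose-response readout used for the
#' hydrophobin/pinhead, Pofst/pinhead, PoWC1/fruit-body and
#' Pleurotolysin/aggregation claims.
#'
#' @param model A valid [fruit_model()].
#' @param laws Rate laws from [assign_all()].
#' @param varied Species id whose initial amount is scanned.
#' @param grid Non-empty numeric vector of non-negative initial amounts.
#' @param readout Species id whose terminal amount is recorded.
#' @param settings A [simulation_settings()] object.
#' @return A list of class `fn_dose_response` with fields `varied`,
#'   `grid`, `readout`, `terminal`.
#' @export
scan_initial <- function(model, laws, varied, grid, readout,
                         settings = simulation_settings()) {
  stop_if_invalid(model)
  sids <- vapply(model$species, `[[`, "", "id")
  if (!varied %in% sids) stop("unknown species '", varied, "'")
  if (!readout %in% sids) stop("unknown species '", readout, "'")
  stopifnot(length(grid) >= 1L, all(is.finite(grid)), all(grid >= 0))
  base_ics <- default_initial_conditions(model)
  terminal <- vapply(grid, function(v) {
    ics <- base_ics
    ics[[varied]] <- v
    traj <- integrate_model(model, laws, ics, settings)
    terminal_state(traj)[[readout]]
  }, 0)
  structure(list(varied = varied, grid = as.numeric(grid),
                 readout = readout, terminal = terminal),
            class = "fn_dose_response")
}

#' @export
print.fn_dose_response <- function(x, ...) {
  cat(sprintf("<fn_dose_response>: %s(0) in {%s} -> terminal %s\n",
              x$varied, paste(signif(x$grid, 4), collapse = ", "),
              x$readout))
  print(data.frame(initial = x$grid, terminal = signif(x$terminal, 6)),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.fn_dose_response <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(varied = x$varied, initial = x$grid, readout = x$readout,
             terminal = x$terminal, stringsAsFactors = FALSE)
}
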
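#' Assemble the ODE right-hand side of a model
#'
#' Returns the derivative function of the dynamic state: the
#' stoichiometry-weighted sum of all reaction rates. Boundary species
#' contribute to rates but have zero derivative by construction; clamped
#' species (see [agonist_clamp()] / [knockout()]) are held at their clamp
#' value with zero derivative.
#'
#' This is the plain-R reference evaluator built directly on
#' [mass_action_rate()] and [hill_rate()]; time-course integration uses an
#' equivalent compiled evaluator by default (see [simulate_time_course()]),
#' and the two are tested against each other.
#'
#' @param model A `cd4_model`. All species referenced by reactions must exist.
#' @return `function(t, state, boundary_levels)` returning `d(state)/dt`
#'   (named, in dynamic-species order). `state` may be named or positional in
#'   [dynamic_species()] order; `boundary_levels` defaults to
#'   [boundary_defaults()].
#' @export
assemble_rhs <- function(model) {
  sp_ids <- model$species$id
  for (rxn in model$reactions) {
    bad <- setdiff(reaction_refs(rxn), sp_ids)
    if (length(bad)) {
      stop("assemble_rhs: reaction '", rxn$id,
           "' references unknown species: ", paste(bad, collapse = ", "))
    }
    miss <- setdiff(reaction_param_names(rxn), names(model$parameters))
    if (length(miss)) {
      stop("assemble_rhs: reaction '", rxn$id,
           "' references unknown parameters: ", paste(miss, collapse = ", "))
    }
  }
  dyn <- dynamic_species(model)
  bnd_default <- boundary_defaults(model)
  clamps <- model_clamps(model)
  disabled <- model$metadata$disabled_reactions %||% character()
  pars <- model$parameters

  function(t, state, boundary_levels = bnd_default) {
    if (is.null(names(state))) names(state) <- dyn
    lev <- c(state[dyn], boundary_levels)
    if (length(clamps)) lev[names(clamps)] <- clamps
    d <- stats::setNames(numeric(length(dyn)), dyn)
    for (rxn in model$reactions) {
      rl <- rxn$rate_law
      if (rxn$id %in% disabled) next
      if (rl$kind == "mass_action") {
        sub_lev <- cbind(level = pmax(lev[names(rxn$substrates)], 0),
                         stoich = unname(rxn$substrates))
        rate <- mass_action_rate(pars[[rl$k]], sub_lev)
      } else {
        inh <- NULL
        if (length(rl$inhibitors)) {
          inh <- cbind(level = pmax(lev[names(rl$inhibitors)], 0),
                       ki = pars[unname(rl$inhibitors)])
        }
        rate <- hill_rate(pars[[rl$vmax]], pars[[rl$km]], pars[[rl$n]],
                          max(lev[[rl$driver]], 0), inh)
        if (length(rl$catalysts)) {
          rate <- rate * prod(pmax(lev[rl$catalysts], 0))
        }
      }
      for (s in names(rxn$substrates)) {
        if (s %in% dyn) d[[s]] <- d[[s]] - rxn$substrates[[s]] * rate
      }
      for (s in names(rxn$products)) {
        if (s %in% dyn) d[[s]] <- d[[s]] + rxn$products[[s]] * rate
      }
    }
    if (length(clamps)) d[intersect(names(clamps), dyn)] <- 0
    d
  }
}

# ---- compiled-plan construction -------------------------------------------

CD4_PLAN_LEN <- 4096L

# Flatten a model (plus resolved boundary levels) into the numeric plan
# vector interpreted by the compiled derivative function src/cd4_rhs.c.
# Returns the padded plan plus index maps that allow parameter values and
# boundary levels to be poked into the plan without recompiling (used by the
# optimizer and the sensitivity module).
compile_plan <- function(model, boundary_levels = boundary_defaults(model)) {
  sp <- model$species
  idx <- stats::setNames(seq_len(nrow(sp)), sp$id)
  dyn <- dynamic_species(model)
  state_pos <- stats::setNames(seq_along(dyn), dyn)
  clamps <- model_clamps(model)
  disabled <- model$metadata$disabled_reactions %||% character()
  pars <- model$parameters

  base <- sp$initial_level
  b_ids <- intersect(names(boundary_levels), sp$id)
  base[idx[b_ids]] <- boundary_levels[b_ids]

  vec <- c(nrow(sp), base, length(dyn), unname(idx[dyn]))
  param_pos <- list()
  note_par <- function(name, pos) {
    param_pos[[name]] <<- c(param_pos[[name]], pos)
  }

  vec <- c(vec, length(clamps))
  for (nm in names(clamps)) {
    st <- if (nm %in% dyn) state_pos[[nm]] else 0
    vec <- c(vec, idx[[nm]], st, clamps[[nm]])
  }

  vec <- c(vec, length(model$reactions))
  for (rxn in model$reactions) {
    rl <- rxn$rate_law
    enabled <- as.numeric(!(rxn$id %in% disabled))
    if (rl$kind == "mass_action") {
      vec <- c(vec, 1, enabled)
      note_par(rl$k, length(vec) + 1L)
      facs <- rxn$substrates
      vec <- c(vec, pars[[rl$k]], length(facs))
      for (s in names(facs)) vec <- c(vec, idx[[s]], facs[[s]])
    } else {
      vec <- c(vec, 2, enabled)
      note_par(rl$vmax, length(vec) + 1L)
      note_par(rl$km, length(vec) + 2L)
      note_par(rl$n, length(vec) + 3L)
      vec <- c(vec, pars[[rl$vmax]], pars[[rl$km]], pars[[rl$n]],
               idx[[rl$driver]], length(rl$catalysts))
      for (s in rl$catalysts) vec <- c(vec, idx[[s]])
      vec <- c(vec, length(rl$inhibitors))
      for (s in names(rl$inhibitors)) {
        note_par(rl$inhibitors[[s]], length(vec) + 2L)
        vec <- c(vec, idx[[s]], pars[[rl$inhibitors[[s]]]])
      }
    }
    net <- stats::setNames(numeric(0), character(0))
    for (s in names(rxn$substrates)) {
      if (s %in% dyn) net[s] <- (net[s] %|0|% 0) - rxn$substrates[[s]]
    }
    for (s in names(rxn$products)) {
      if (s %in% dyn) net[s] <- (net[s] %|0|% 0) + rxn$products[[s]]
    }
    net <- net[net != 0]
    vec <- c(vec, length(net))
    for (s in names(net)) vec <- c(vec, state_pos[[s]], net[[s]])
  }

  if (length(vec) > CD4_PLAN_LEN) {
    stop("compiled plan exceeds the fixed buffer (", length(vec), " > ",
         CD4_PLAN_LEN, ")")
  }
  boundary_pos <- stats::setNames(1L + unname(idx[boundary_species(model)]),
                                  boundary_species(model))
  list(vec = c(vec, numeric(CD4_PLAN_LEN - length(vec))),
       param_pos = param_pos,
       boundary_pos = boundary_pos,
       state_ids = dyn)
}

# Overwrite parameter values inside a compiled plan (no recompilation).
plan_set_parameters <- function(plan, params) {
  for (nm in names(params)) {
    pos <- plan$param_pos[[nm]]
    if (is.null(pos)) stop("parameter not in plan: ", nm)
    plan$vec[pos] <- params[[nm]]
  }
  plan
}

`%|0|%` <- function(a, b) if (is.na(a)) b else a
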
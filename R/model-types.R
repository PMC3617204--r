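#' @title Reaction-network model containers
#' @description Constructors for the species / rate-law / reaction / model
#'   domain types used throughout the package. Levels are dimensionless
#'   arbitrary units (a.u.); time is in hours.
#' @name model-types
NULL

SPECIES_ROLES <- c(
  "external_cytokine", "neutralizing_antibody", "receptor",
  "signal_transducer", "transcription_factor", "secreted_cytokine"
)

#' Define a species
#'
#' @param id Short unique token.
#' @param name Human-readable label.
#' @param role One of `r paste(SPECIES_ROLES, collapse = ", ")`.
#' @param initial_level Initial level in a.u. (>= 0). For boundary species this
#'   is the default input level, overridable by a [stimulus_recipe()].
#' @param is_boundary Boundary species are inputs held fixed (or scanned) and
#'   receive no ODE.
#' @return One-row data.frame.
#' @export
cd4_species <- function(id, name = id, role = "signal_transducer",
                        initial_level = 0, is_boundary = FALSE) {
  role <- match.arg(role, SPECIES_ROLES)
  data.frame(id = id, name = name, role = role,
             initial_level = initial_level, is_boundary = is_boundary,
             stringsAsFactors = FALSE)
}

#' Mass-action rate law
#'
#' @param k Name of the rate-constant entry in the model's parameter map.
#' @export
ma_law <- function(k) {
  structure(list(kind = "mass_action", k = k), class = "cd4_rate_law")
}

#' Hill rate law with optional catalysts
#'
#' The reaction rate is [hill_rate()] multiplied by the level of each catalyst
#' species (a unit-stoichiometry mass-action factor). Conserved activation
#' cycles list their substrate among the catalysts, which makes the rate
#' vanish smoothly as the substrate pool empties.
#'
#' @param vmax,km,n Names of the corresponding entries in the parameter map.
#' @param driver Species id whose level drives the Hill term.
#' @param inhibitors Named character vector: names are inhibiting species ids,
#'   values are the parameter names of their inhibition constants ki.
#' @param catalysts Character vector of species ids whose levels multiply the
#'   rate linearly.
#' @export
hill_law <- function(vmax, km, n, driver, inhibitors = character(),
                     catalysts = character()) {
  structure(list(kind = "hill", vmax = vmax, km = km, n = n, driver = driver,
                 inhibitors = inhibitors, catalysts = catalysts),
            class = "cd4_rate_law")
}

#' Define a reaction
#'
#' @param id Unique reaction id.
#' @param substrates,products Named numeric vectors: names are species ids,
#'   values stoichiometries. Boundary species may appear as substrates but are
#'   never modified by integration.
#' @param rate_law A [ma_law()] or [hill_law()].
#' @param modifiers Species ids referenced by the reaction but neither consumed
#'   nor produced (drivers, inhibitors, catalysts are added automatically).
#' @export
cd4_reaction <- function(id, substrates = numeric(), products = numeric(),
                         rate_law, modifiers = character()) {
  stopifnot(inherits(rate_law, "cd4_rate_law"))
  auto <- character()
  if (rate_law$kind == "hill") {
    auto <- c(rate_law$driver, names(rate_law$inhibitors), rate_law$catalysts)
  }
  structure(list(
    id = id,
    substrates = substrates,
    products = products,
    modifiers = unique(setdiff(c(modifiers, auto),
                               c(names(substrates), names(products)))),
    rate_law = rate_law
  ), class = "cd4_reaction")
}

#' Assemble a model definition
#'
#' @param species data.frame of species rows from [cd4_species()].
#' @param reactions List of [cd4_reaction()] objects.
#' @param parameters Named numeric vector of all kinetic constants.
#' @param metadata Optional list (calibration tag, expected structural counts,
#'   clamps applied by perturbations, ...).
#' @param time_unit Time unit label; the model is formulated in hours.
#' @return An object of class `cd4_model`.
#' @export
define_model <- function(species, reactions, parameters,
                         metadata = list(), time_unit = "h") {
  rownames(species) <- NULL
  structure(list(
    species = species,
    reactions = reactions,
    parameters = parameters,
    time_unit = time_unit,
    metadata = metadata
  ), class = "cd4_model")
}

#' @export
print.cd4_model <- function(x, ...) {
  cat("<cd4_model> ", n_species(x), " species (", n_odes(x), " dynamic), ",
      n_reactions(x), " reactions, ", length(x$parameters), " parameters\n",
      sep = "")
  if (!is.null(x$metadata$calibration)) {
    cat("  calibration:", x$metadata$calibration, "\n")
  }
  cl <- model_clamps(x)
  if (length(cl)) {
    cat("  clamps:", paste0(names(cl), "=", signif(cl, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Structural counts and id helpers
#' @param model A `cd4_model`.
#' @export
n_species <- function(model) nrow(model$species)

#' @rdname n_species
#' @export
n_reactions <- function(model) length(model$reactions)

#' @rdname n_species
#' @export
n_odes <- function(model) sum(!model$species$is_boundary)

#' @rdname n_species
#' @export
dynamic_species <- function(model) model$species$id[!model$species$is_boundary]

#' @rdname n_species
#' @export
boundary_species <- function(model) model$species$id[model$species$is_boundary]

#' Initial dynamic state as a named vector
#' @param model A `cd4_model`.
#' @export
initial_state <- function(model) {
  dyn <- !model$species$is_boundary
  stats::setNames(model$species$initial_level[dyn], model$species$id[dyn])
}

#' Default boundary input levels as a named vector
#' @param model A `cd4_model`.
#' @export
boundary_defaults <- function(model) {
  b <- model$species$is_boundary
  stats::setNames(model$species$initial_level[b], model$species$id[b])
}

#' Get or set kinetic constants by name
#' @param model A `cd4_model`.
#' @param name Parameter name.
#' @param value New value.
#' @export
set_parameter <- function(model, name, value) {
  miss <- setdiff(name, names(model$parameters))
  if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
  model$parameters[name] <- value
  model
}

#' @rdname set_parameter
#' @export
get_parameter <- function(model, name) {
  miss <- setdiff(name, names(model$parameters))
  if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
  model$parameters[name]
}

model_clamps <- function(model) {
  cl <- model$metadata$clamps
  if (is.null(cl)) numeric() else cl
}

# All species ids referenced by a reaction, by role.
reaction_refs <- function(rxn) {
  rl <- rxn$rate_law
  refs <- c(names(rxn$substrates), names(rxn$products), rxn$modifiers)
  if (rl$kind == "hill") {
    refs <- c(refs, rl$driver, names(rl$inhibitors), rl$catalysts)
  }
  unique(refs)
}

# Parameter names referenced by a reaction's rate law.
reaction_param_names <- function(rxn) {
  rl <- rxn$rate_law
  if (rl$kind == "mass_action") rl$k
  else c(rl$vmax, rl$km, rl$n, unname(rl$inhibitors))
}

#' Validate a model definition
#'
#' Produces a report listing species/reaction/ODE counts, dangling species or
#' parameter references, non-positive kinetic constants, negative initial
#' levels, role/boundary inconsistencies, duplicate ids and unreachable
#' species (no in- or out-edges). The report passes iff all checks hold; if
#' the model metadata carries `expected_counts`, the structural counts must
#' match exactly.
#'
#' @param model A `cd4_model`.
#' @return A `cd4_validation` object with elements `counts`, `checks`
#'   (data.frame of check / ok / detail) and `pass`.
#' @export
validate_model <- function(model) {
  sp <- model$species
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, ok = ok, detail = detail, stringsAsFactors = FALSE)
  }

  add("unique_species_ids", !anyDuplicated(sp$id),
      paste(sp$id[duplicated(sp$id)], collapse = ", "))
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  add("unique_reaction_ids", !anyDuplicated(rxn_ids),
      paste(rxn_ids[duplicated(rxn_ids)], collapse = ", "))
  add("nonnegative_initial_levels", all(sp$initial_level >= 0),
      paste(sp$id[sp$initial_level < 0], collapse = ", "))
  ext <- sp$role %in% c("external_cytokine", "neutralizing_antibody")
  add("external_inputs_are_boundary", all(sp$is_boundary[ext]),
      paste(sp$id[ext & !sp$is_boundary], collapse = ", "))

  dangling <- character()
  touched <- character()
  bad_par <- character()
  for (rxn in model$reactions) {
    refs <- reaction_refs(rxn)
    touched <- c(touched, refs)
    dangling <- c(dangling, setdiff(refs, sp$id))
    pn <- reaction_param_names(rxn)
    missing_p <- setdiff(pn, names(model$parameters))
    bad_par <- c(bad_par, missing_p)
    pv <- model$parameters[intersect(pn, names(model$parameters))]
    bad_par <- c(bad_par, names(pv)[!is.finite(pv) | pv <= 0])
    if (rxn$rate_law$kind == "hill") {
      nv <- model$parameters[rxn$rate_law$n]
      if (is.finite(nv) && nv < 1) bad_par <- c(bad_par, rxn$rate_law$n)
    }
  }
  add("no_dangling_species_references", length(dangling) == 0L,
      paste(unique(dangling), collapse = ", "))
  add("kinetic_constants_positive_and_present", length(bad_par) == 0L,
      paste(unique(bad_par), collapse = ", "))
  unreachable <- setdiff(sp$id, touched)
  add("no_unreachable_species", length(unreachable) == 0L,
      paste(unreachable, collapse = ", "))

  counts <- c(species = nrow(sp), reactions = length(model$reactions),
              odes = sum(!sp$is_boundary))
  exp_counts <- model$metadata$expected_counts
  if (!is.null(exp_counts)) {
    add("structural_counts_match_reference", all(counts == exp_counts),
        paste(counts, collapse = "/"))
  }

  checks <- do.call(rbind, checks)
  structure(list(counts = counts, checks = checks, pass = all(checks$ok)),
            class = "cd4_validation")
}

#' @export
print.cd4_validation <- function(x, ...) {
  cat("Model validation:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  counts: ", x$counts[["species"]], " species, ",
      x$counts[["reactions"]], " reactions, ",
      x$counts[["odes"]], " ODEs\n", sep = "")
  bad <- x$checks[!x$checks$ok, , drop = FALSE]
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad))) {
      cat("  FAIL ", bad$check[i],
          if (nzchar(bad$detail[i])) paste0(": ", bad$detail[i]) else "", "\n",
          sep = "")
    }
  }
  invisible(x)
}
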
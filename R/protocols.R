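#' Stimulus recipes: the external cytokine milieu
#'
#' A recipe maps boundary species (external cytokines, neutralizing
#' antibodies) to input doses in a.u.; it is the model's only input.
#'
#' @param doses Named non-negative numeric vector keyed by boundary species.
#' @param label Scenario name.
#' @export
stimulus_recipe <- function(doses = numeric(), label = "custom") {
  if (length(doses) && (is.null(names(doses)) || any(!nzchar(names(doses))))) {
    stop("`doses` must be a named vector of boundary species levels")
  }
  if (any(doses < 0)) stop("doses must be >= 0")
  structure(list(doses = doses, label = label), class = "cd4_recipe")
}

#' Canonical induction recipes
#'
#' The calibrated saturating dose (1 a.u.) per cytokine for each lineage:
#' Th1 gets external IFN-gamma, IL-12 and IL-18 plus anti-IL-4; Th2 gets
#' IL-4 plus anti-IFN-gamma; Th17 gets IL-6 plus TGF-beta; iTreg gets IL-2
#' plus TGF-beta. `"naive"` is the zero-dose milieu.
#'
#' @param lineage One of `"Th1"`, `"Th2"`, `"Th17"`, `"iTreg"`, `"naive"`.
#' @param dose Saturating dose applied to each listed cytokine.
#' @return A [stimulus_recipe()].
#' @export
canonical_recipe <- function(lineage = c("Th1", "Th2", "Th17", "iTreg", "naive"),
                             dose = 1) {
  lineage <- match.arg(lineage)
  doses <- switch(lineage,
    Th1 = c(IFNg_e = dose, IL12_e = dose, IL18_e = dose, aIL4 = dose),
    Th2 = c(IL4_e = dose, aIFNg = dose),
    Th17 = c(IL6_e = dose, TGFb_e = dose),
    iTreg = c(IL2_e = dose, TGFb_e = dose),
    naive = stats::setNames(numeric(0), character(0))
  )
  stimulus_recipe(doses, label = lineage)
}

# ---- perturbations ---------------------------------------------------------

#' In-silico perturbations
#'
#' `knockout(target)` blocks the target species' downstream signaling: the
#' species is clamped to zero in every rate evaluation (so Hill terms it
#' drives vanish, catalytic contributions vanish and inhibitions it exerts are
#' released) and reactions it drives are disabled. `agonist_clamp(target,
#' level)` holds the target species at an absolute level, emulating
#' ligand-mediated activation (pioglitazone-like agonism of PPARg clamps the
#' activated-PPARg node). `agonist_clamp(target, 0)` composed with
#' `knockout(target)` is idempotent with the knockout alone.
#'
#' @param target Species id.
#' @param level Clamp level in a.u. (>= 0).
#' @return A `cd4_perturbation`.
#' @export
knockout <- function(target) {
  structure(list(kind = "knockout", target = target, level = 0),
            class = "cd4_perturbation")
}

#' @rdname knockout
#' @export
agonist_clamp <- function(target, level) {
  if (!is.numeric(level) || level < 0) stop("clamp level must be >= 0")
  structure(list(kind = "agonist_clamp", target = target, level = level),
            class = "cd4_perturbation")
}

#' Apply a perturbation to a model
#'
#' @param model A `cd4_model`.
#' @param perturbation A [knockout()] or [agonist_clamp()].
#' @return The perturbed model (clamps and disabled reactions recorded in
#'   metadata).
#' @export
apply_perturbation <- function(model, perturbation) {
  stopifnot(inherits(perturbation, "cd4_perturbation"))
  tg <- perturbation$target
  if (!tg %in% model$species$id) stop("unknown perturbation target: ", tg)
  cl <- model_clamps(model)
  cl[tg] <- perturbation$level
  model$metadata$clamps <- cl
  if (perturbation$kind == "knockout") {
    driven <- vapply(model$reactions, function(r) {
      r$rate_law$kind == "hill" && r$rate_law$driver == tg
    }, logical(1))
    model$metadata$disabled_reactions <- unique(c(
      model$metadata$disabled_reactions,
      vapply(model$reactions[driven], `[[`, "", "id")))
  }
  model
}

# Wild-type counterpart of a perturbed model (classifier reference scale).
strip_perturbations <- function(model) {
  model$metadata$clamps <- NULL
  model$metadata$disabled_reactions <- NULL
  model
}

# Naive-milieu level of one species after `t_end` hours (basal tone). For a
# model in which the species is clamped this is just the clamp value.
basal_level <- function(model, species, t_end = 100) {
  cl <- model_clamps(model)
  if (species %in% names(cl)) return(unname(cl[[species]]))
  ep <- endpoint_state(simulate_time_course(model, canonical_recipe("naive"),
                                            t_end = t_end, n_points = 50))
  unname(ep[[species]])
}

# ---- named in-silico experiments ------------------------------------------

#' Induce a phenotype from the naive state
#'
#' Applies the canonical recipe for the lineage, integrates to `t_end` and
#' classifies the endpoint. An unclassifiable endpoint yields a
#' `naive_mixed` call with diagnostics, not an error.
#'
#' @param model A `cd4_model`.
#' @param lineage `"Th1"`, `"Th2"`, `"Th17"`, `"iTreg"` or `"naive"`.
#' @param t_end Horizon in hours.
#' @param reference_model Model defining the classifier's full-induction
#'   scale; defaults to `model` with any perturbations stripped.
#' @param ... Passed to [simulate_time_course()].
#' @return List with `trajectory` (a `cd4_trajectory`) and `call`
#'   (a `cd4_phenotype_call`).
#' @export
induce_phenotype <- function(model, lineage, t_end = 100,
                             reference_model = NULL, ...) {
  recipe <- canonical_recipe(lineage)
  traj <- simulate_time_course(model, recipe, t_end = t_end, ...)
  ref_model <- reference_model %||% strip_perturbations(model)
  refs <- classifier_reference(ref_model, t_end = t_end)
  call <- classify_phenotype(endpoint_state(traj), refs)
  list(trajectory = traj, call = call)
}

#' PPARg agonist dose scan in committed Th17 cells
#'
#' Drives the model to a committed Th17 state, then holds activated PPARg at
#' (basal level + agonist dose) for each ascending grid value and reports the
#' endpoint FOXP3, IL-17, RORgt and STAT3-P levels together with the
#' phenotype call per dose. A dose of 0 clamps at the basal tone and is
#' indistinguishable from the unperturbed cell.
#'
#' @param model A `cd4_model`.
#' @param agonist_grid Ascending non-negative agonist doses (a.u. above basal
#'   activated-PPARg tone).
#' @param t_commit Th17 commitment horizon (h) before the clamp.
#' @param t_scan Post-clamp horizon (h) per dose.
#' @param readouts Species reported at the post-clamp endpoint.
#' @param ... Passed to [simulate_time_course()].
#' @return A `cd4_scan` with an additional `calls` element (one phenotype
#'   label per grid value).
#' @export
ppar_activation_scan <- function(model, agonist_grid = seq(0, 3, length.out = 10),
                                 t_commit = 100, t_scan = 100,
                                 readouts = c("FOXP3", "IL17_s", "RORgt", "STAT3_P"),
                                 ...) {
  if (is.unsorted(agonist_grid)) stop("`agonist_grid` must be ascending")
  if (any(agonist_grid < 0)) stop("agonist doses must be >= 0")
  committed <- endpoint_state(
    simulate_time_course(model, canonical_recipe("Th17"), t_end = t_commit, ...))
  basal <- basal_level(model, "PPARg_a")
  refs <- classifier_reference(strip_perturbations(model))
  res <- matrix(NA_real_, nrow = length(agonist_grid), ncol = length(readouts),
                dimnames = list(NULL, readouts))
  calls <- character(length(agonist_grid))
  for (i in seq_along(agonist_grid)) {
    m_i <- apply_perturbation(model, agonist_clamp("PPARg_a",
                                                   basal + agonist_grid[i]))
    ep <- endpoint_state(simulate_time_course(m_i, canonical_recipe("Th17"),
                                              t_end = t_scan,
                                              init_state = committed, ...))
    res[i, ] <- ep[readouts]
    calls[i] <- classify_phenotype(ep, refs)$label
  }
  structure(list(parameter = "clamp:PPARg_a", grid = agonist_grid,
                 readouts = res, mode = "endpoint",
                 failures = rep(NA_character_, length(agonist_grid)),
                 calls = calls, basal = basal),
            class = "cd4_scan")
}

#' Compare wild-type and PPARg-knockout differentiation
#'
#' Induces the given lineage from the naive state in the intact model and in
#' a PPARg-deficient model (downstream signaling blocked) and returns paired
#' endpoint readouts.
#'
#' @param model A `cd4_model`.
#' @param lineage `"Th17"` or `"iTreg"`.
#' @param readouts Species to report (defaults to the lineage's informative
#'   markers).
#' @param t_end Horizon in hours.
#' @param ... Passed to [simulate_time_course()].
#' @return List with `wild_type` and `knockout` named endpoint vectors,
#'   `readouts` (two-row matrix) and the phenotype calls.
#' @export
ppar_knockout_compare <- function(model, lineage = c("Th17", "iTreg"),
                                  readouts = NULL, t_end = 100, ...) {
  lineage <- match.arg(lineage)
  if (is.null(readouts)) {
    readouts <- switch(lineage, Th17 = c("RORgt", "IL17_s", "STAT3_P"),
                       iTreg = c("FOXP3", "TGFb_s"))
  }
  ko_model <- apply_perturbation(model, knockout("PPARg_a"))
  wt <- induce_phenotype(model, lineage, t_end = t_end, ...)
  ko <- induce_phenotype(ko_model, lineage, t_end = t_end,
                         reference_model = strip_perturbations(model), ...)
  wt_ep <- endpoint_state(wt$trajectory)
  ko_ep <- endpoint_state(ko$trajectory)
  list(
    wild_type = wt_ep, knockout = ko_ep,
    readouts = rbind(wild_type = wt_ep[readouts], knockout = ko_ep[readouts]),
    calls = c(wild_type = wt$call$label, knockout = ko$call$label)
  )
}

#' Th17-to-iTreg plasticity switch
#'
#' Induces Th17 differentiation on `[0, t_switch]`, then activates PPARg by
#' clamping the activated-PPARg node at (basal + `agonist_level`) and
#' continues the simulation in the unchanged Th17 milieu. After the switch,
#' FOXP3 rises above its pre-switch level while IL-17, RORgt and STAT3-P fall
#' below theirs; with the default agonist dose the final state classifies as
#' iTreg. `agonist_level = 0` reproduces the uninterrupted Th17 trajectory.
#'
#' @param model A `cd4_model`.
#' @param t_switch Switch time (h); default: the time at which RORgt first
#'   reaches 95\% of its Th17-induction plateau ("fully differentiated").
#' @param agonist_level Agonist dose above basal activated-PPARg tone.
#' @param t_end Total horizon (h); default `t_switch + 100`.
#' @param n_points Output points per phase.
#' @param ... Passed to [simulate_time_course()].
#' @return A `cd4_trajectory` spanning both phases, with elements
#'   `t_switch`, `pre_switch` (state at the switch) and `call` (final
#'   phenotype).
#' @export
plasticity_switch <- function(model, t_switch = NULL, agonist_level = 2,
                              t_end = NULL, n_points = 500, ...) {
  recipe <- canonical_recipe("Th17")
  if (is.null(t_switch)) {
    probe <- simulate_time_course(model, recipe, t_end = 100,
                                  n_points = 400, ...)
    plateau <- endpoint_state(probe)[["RORgt"]]
    hit <- which(probe$state[, "RORgt"] >= 0.95 * plateau)
    t_switch <- probe$time[hit[1]]
  }
  if (is.null(t_end)) t_end <- t_switch + 100
  if (t_switch <= 0 || t_switch >= t_end) {
    stop("`t_switch` must lie strictly inside (0, t_end)")
  }
  phase1 <- simulate_time_course(model, recipe, t_end = t_switch,
                                 n_points = n_points, ...)
  pre <- endpoint_state(phase1)
  basal <- basal_level(model, "PPARg_a")
  m2 <- apply_perturbation(model, agonist_clamp("PPARg_a",
                                                basal + agonist_level))
  phase2 <- simulate_time_course(m2, recipe, t_end = t_end - t_switch,
                                 n_points = n_points, init_state = pre, ...)
  refs <- classifier_reference(strip_perturbations(model))
  out <- phase1
  out$time <- c(phase1$time, t_switch + phase2$time[-1])
  out$state <- rbind(phase1$state, phase2$state[-1, , drop = FALSE])
  out$recipe_label <- "Th17 + PPARg agonist switch"
  out$t_switch <- t_switch
  out$pre_switch <- pre
  out$agonist_level <- agonist_level
  out$call <- classify_phenotype(endpoint_state(out), refs)
  out
}
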
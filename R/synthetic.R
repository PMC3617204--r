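#' Specification for the synthetic calibration-data generator
#'
#' Describes a set of stimulus-response experiments to simulate from known
#' ground-truth parameters: which recipes to run, when and which species to
#' observe, and the noise level. Noise is multiplicative log-normal with
#' median 1 — log-deviations have mean zero, so the generator is unbiased in
#' log-space — with `sigma = sqrt(log(1 + cv^2))` so that the coefficient of
#' variation of replicates equals `cv`.
#'
#' @param recipes List of [stimulus_recipe()] objects.
#' @param times Observation times in hours (within `t_end`).
#' @param species Observed dynamic species ids.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0;
#'   `cv = 0` reproduces the simulation exactly).
#' @param seed RNG seed recorded in the dataset provenance.
#' @param parameter_overrides Optional named vector of ground-truth parameter
#'   values applied before simulating.
#' @param t_end Simulation horizon (defaults to the last observation time).
#' @export
generator_spec <- function(recipes, times, species, cv = 0.05, seed = 1,
                           parameter_overrides = NULL, t_end = NULL) {
  if (cv < 0) stop("`cv` must be >= 0")
  if (any(times < 0)) stop("observation times must be >= 0")
  t_end <- t_end %||% max(times)
  if (any(times > t_end)) {
    stop("observation times beyond the simulation horizon (t_end = ",
         t_end, " h)")
  }
  structure(list(recipes = recipes, times = sort(unique(times)),
                 species = species, cv = cv, seed = seed,
                 parameter_overrides = parameter_overrides, t_end = t_end),
            class = "cd4_generator_spec")
}

#' Generate a synthetic calibration dataset
#'
#' Simulates every recipe in the spec, samples the observed species at the
#' stated times, applies multiplicative log-normal noise and tags the result
#' with full provenance (generator seed, noise level, ground-truth
#' overrides), so any downstream result is re-derivable.
#'
#' @param model A `cd4_model` (ground truth, after applying any overrides in
#'   the spec).
#' @param spec A [generator_spec()].
#' @return A [calibration_dataset()] with provenance `source = "synthetic"`.
#' @export
generate_calibration_dataset <- function(model, spec) {
  stopifnot(inherits(spec, "cd4_generator_spec"))
  if (!is.null(spec$parameter_overrides)) {
    model <- set_parameter(model, names(spec$parameter_overrides),
                           spec$parameter_overrides)
  }
  bad <- setdiff(spec$species, dynamic_species(model))
  if (length(bad)) stop("observed species not dynamic in model: ",
                        paste(bad, collapse = ", "))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  sigma <- sqrt(log(1 + spec$cv^2))

  experiments <- lapply(spec$recipes, function(recipe) {
    traj <- simulate_time_course(model, recipe,
                                 times = sort(unique(c(0, spec$times))))
    rows <- match(spec$times, traj$time)
    obs <- expand.grid(time = spec$times, species = spec$species,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sim <- traj$state[cbind(rows[match(obs$time, spec$times)],
                            match(obs$species, colnames(traj$state)))]
    noise <- if (spec$cv > 0) exp(stats::rnorm(nrow(obs), 0, sigma)) else 1
    obs$value <- sim * noise
    obs$weight <- 1
    list(recipe = recipe, observations = obs[, c("species", "time",
                                                 "value", "weight")])
  })
  calibration_dataset(experiments, provenance = list(
    source = "synthetic", seed = spec$seed, cv = spec$cv,
    parameter_overrides = spec$parameter_overrides, t_end = spec$t_end))
}

#' Expected fate table for the canonical recipes
#'
#' Derives, from the model structure and the lineage marker panel, the
#' machine-readable fixture used by the protocol tests: per lineage, the
#' markers that must rise under its canonical recipe (master regulator,
#' signature cytokine, and the STAT/SMAD driver of the master regulator) and
#' the opposing master regulators that must stay suppressed.
#'
#' @param model A `cd4_model` that passes [validate_model()].
#' @return List of 4 rows (Th1, Th2, Th17, iTreg), each with `lineage`,
#'   `up` and `suppressed` character vectors.
#' @export
generate_fate_fixture <- function(model) {
  v <- validate_model(model)
  if (!v$pass) stop("model fails validation; fate fixture not generated")
  markers <- lineage_markers()
  masters <- vapply(markers, `[[`, "", 1)
  driver_of <- function(master) {
    for (rxn in model$reactions) {
      if (rxn$rate_law$kind == "hill" &&
          master %in% names(rxn$products)) {
        return(rxn$rate_law$driver)
      }
    }
    character(0)
  }
  lapply(names(markers), function(lin) {
    list(lineage = lin,
         up = unique(c(markers[[lin]], driver_of(masters[[lin]]))),
         suppressed = unname(masters[setdiff(names(masters), lin)]))
  })
}
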
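#' Calibration datasets
#'
#' A calibration dataset couples stimulus recipes to observed
#' stimulus-response measurements (species level at a time point, with a
#' positive weight), the shape produced by the synthetic generator and fitted
#' by [fit_particle_swarm()].
#'
#' @param experiments List of experiments, each a list with elements
#'   `recipe` (a [stimulus_recipe()]) and `observations` (data.frame with
#'   columns `species`, `time`, `value`, `weight`).
#' @param provenance List tagging the data source (`"real"` or
#'   `"synthetic"`, generator seed, noise level).
#' @export
calibration_dataset <- function(experiments, provenance = list(source = "real")) {
  for (ex in experiments) {
    stopifnot(inherits(ex$recipe, "cd4_recipe"),
              is.data.frame(ex$observations))
    obs <- ex$observations
    if (!all(c("species", "time", "value", "weight") %in% names(obs))) {
      stop("observations need columns species, time, value, weight")
    }
    if (any(obs$weight <= 0)) stop("observation weights must be > 0")
    if (any(obs$time < 0)) stop("observation times must be >= 0")
  }
  structure(list(experiments = experiments, provenance = provenance),
            class = "cd4_dataset")
}

#' @export
print.cd4_dataset <- function(x, ...) {
  n_obs <- sum(vapply(x$experiments, function(e) nrow(e$observations), 0L))
  cat("<cd4_dataset> ", length(x$experiments), " experiments, ", n_obs,
      " observations (", x$provenance$source %||% "unknown", ")\n", sep = "")
  invisible(x)
}

# Precompiled weighted-SSE evaluator. Each experiment gets its own compiled
# plan (boundary levels differ per recipe); parameter values are poked into
# the plans without recompilation, which keeps swarm optimization cheap.
objective_builder <- function(model, dataset, rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(dataset, "cd4_dataset"))
  dyn <- dynamic_species(model)
  y0 <- unname(initial_state(model))
  setups <- lapply(dataset$experiments, function(ex) {
    obs <- ex$observations
    bad <- setdiff(unique(obs$species), dyn)
    if (length(bad)) stop("observed species not dynamic in model: ",
                          paste(bad, collapse = ", "))
    times <- sort(unique(c(0, obs$time)))
    list(plan = compile_plan(model, resolve_boundary(model, ex$recipe)),
         times = times,
         row = match(obs$time, times),
         col = match(obs$species, dyn),
         value = obs$value, weight = obs$weight)
  })
  function(params) {
    total <- 0
    for (s in setups) {
      plan <- if (length(params)) plan_set_parameters(s$plan, params) else s$plan
      out <- tryCatch(
        deSolve::ode(y = y0, times = s$times, func = "cd4_derivs",
                     parms = plan$vec, dllname = "cd4sim",
                     initfunc = "cd4_init", method = "lsoda",
                     rtol = rtol, atol = atol),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(out) || nrow(out) != length(s$times)) {
        return(structure(1e10, failed = TRUE))
      }
      sim <- out[cbind(s$row, s$col + 1L)]
      total <- total + sum(s$weight * (sim - s$value)^2)
    }
    total
  }
}

#' Weighted least-squares calibration objective
#'
#' \deqn{\sum_{obs} w\,(y_{sim} - y_{obs})^2} with each experiment simulated
#' by [simulate_time_course()] under its recipe at the candidate parameter
#' values. A solver failure yields a large penalty value flagged with
#' `attr(, "failed")` so population optimizers can continue.
#'
#' @param model A `cd4_model`.
#' @param params Named numeric vector of parameter values to apply (may be a
#'   subset of the model's parameters).
#' @param dataset A [calibration_dataset()].
#' @return Weighted SSE (>= 0).
#' @export
objective <- function(model, params, dataset) {
  fn <- objective_builder(model, dataset)
  fn(params)
}

#' Global-best particle swarm minimizer
#'
#' Standard constriction-style PSO (inertia 0.729, cognitive and social
#' weights 1.494) with reflecting bounds. Fully reproducible for a given
#' seed; the best-so-far trace is nonincreasing by construction.
#'
#' @param fn Objective function of a numeric vector.
#' @param lower,upper Bounds (finite, equal length).
#' @param n_particles Swarm size.
#' @param iterations Number of iterations.
#' @param seed RNG seed.
#' @param w,c1,c2 Inertia, cognitive and social weights.
#' @return List with `par`, `value`, `trace` (best objective per iteration)
#'   and `evaluations`.
#' @export
pso_optimize <- function(fn, lower, upper, n_particles = 50,
                         iterations = 3000, seed = 1,
                         w = 0.729, c1 = 1.494, c2 = 1.494) {
  stopifnot(length(lower) == length(upper), all(is.finite(c(lower, upper))),
            all(upper > lower))
  d <- length(lower)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  rng <- upper - lower
  x <- matrix(stats::runif(n_particles * d, lower, upper),
              nrow = n_particles, byrow = TRUE)
  v <- matrix(stats::runif(n_particles * d, -rng, rng) * 0.1,
              nrow = n_particles, byrow = TRUE)
  pbest <- x
  pval <- apply(x, 1, fn)
  g <- which.min(pval)
  gbest <- x[g, ]
  gval <- pval[g]
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    r1 <- matrix(stats::runif(n_particles * d), n_particles)
    r2 <- matrix(stats::runif(n_particles * d), n_particles)
    v <- w * v + c1 * r1 * (pbest - x) +
      c2 * r2 * (matrix(gbest, n_particles, d, byrow = TRUE) - x)
    x <- x + v
    for (j in seq_len(d)) {            # reflect into bounds
      lo <- x[, j] < lower[j]
      hi <- x[, j] > upper[j]
      x[lo, j] <- pmin(2 * lower[j] - x[lo, j], upper[j])
      x[hi, j] <- pmax(2 * upper[j] - x[hi, j], lower[j])
      v[lo | hi, j] <- -0.5 * v[lo | hi, j]
    }
    val <- apply(x, 1, fn)
    improved <- val < pval
    pbest[improved, ] <- x[improved, ]
    pval[improved] <- val[improved]
    g <- which.min(pval)
    if (pval[g] < gval) {
      gval <- pval[g]
      gbest <- pbest[g, ]
    }
    trace[it] <- gval
  }
  list(par = gbest, value = gval, trace = trace,
       evaluations = n_particles * (iterations + 1L))
}

#' Fit parameters by particle swarm optimization
#'
#' Minimizes the weighted least-squares [objective()] over the chosen free
#' parameters, searched in log-space within positive finite bounds. Default
#' settings mirror the full calibration protocol (swarm of 50 particles,
#' 3000 iterations); reduced settings (e.g. 30 x 300) are appropriate for
#' routine parameter-recovery checks.
#'
#' @param model A `cd4_model`.
#' @param dataset A [calibration_dataset()].
#' @param free_params Character vector of parameter names to fit (nonempty).
#' @param bounds List with named numeric vectors `lower` and `upper`
#'   (positive, finite) for the free parameters.
#' @param swarm_size,iterations PSO settings.
#' @param seed RNG seed (fits are fully reproducible given the seed).
#' @param ... Passed to [pso_optimize()].
#' @return A `cd4_fit`: fitted `par`, `objective` value, best-so-far
#'   `trace` and the `settings` used.
#' @export
fit_particle_swarm <- function(model, dataset, free_params, bounds,
                               swarm_size = 50, iterations = 3000,
                               seed = 1, ...) {
  if (!length(free_params)) stop("`free_params` must be nonempty")
  miss <- setdiff(free_params, names(model$parameters))
  if (length(miss)) stop("free_params not in model: ", paste(miss, collapse = ", "))
  lower <- bounds$lower[free_params]
  upper <- bounds$upper[free_params]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower <= 0)) {
    stop("bounds must be finite and positive for log-space search")
  }
  fn <- objective_builder(model, dataset)
  failures <- 0L
  wrapped <- function(z) {
    val <- fn(stats::setNames(10^z, free_params))
    if (isTRUE(attr(val, "failed"))) failures <<- failures + 1L
    as.numeric(val)
  }
  res <- pso_optimize(wrapped, log10(lower), log10(upper),
                      n_particles = swarm_size, iterations = iterations,
                      seed = seed, ...)
  if (res$value >= 1e10) {
    stop("all swarm evaluations hit the solver-failure penalty; ",
         "revise the parameter bounds")
  }
  structure(list(
    par = stats::setNames(10^res$par, free_params),
    objective = res$value,
    trace = res$trace,
    settings = list(swarm_size = swarm_size, iterations = iterations,
                    seed = seed, bounds = bounds, log_space = TRUE,
                    solver_failures = failures)
  ), class = "cd4_fit")
}

#' @export
print.cd4_fit <- function(x, ...) {
  cat("<cd4_fit> objective = ", signif(x$objective, 6), " after ",
      x$settings$iterations, " iterations x ", x$settings$swarm_size,
      " particles\n", sep = "")
  print(signif(x$par, 4))
  invisible(x)
}
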
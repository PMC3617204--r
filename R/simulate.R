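#' Integrate a model over time
#'
#' Deterministic time-course simulation of the dynamic species under a fixed
#' cytokine milieu. Boundary species are held at the recipe's (resolved)
#' levels throughout; clamped species are held at their clamp value. The
#' integrator is deSolve's stiff-capable `lsoda` with tight default
#' tolerances (`rtol = 1e-8`, `atol = 1e-10`); the default horizon is 100 h
#' with 1000 output points.
#'
#' @param model A `cd4_model`.
#' @param recipe A [stimulus_recipe()] of external inputs, or `NULL` for the
#'   model's default (naive) boundary levels.
#' @param t_end Simulation horizon in hours (> 0).
#' @param n_points Number of output points after t = 0.
#' @param times Optional explicit output-time grid (overrides `t_end` /
#'   `n_points`); must start at 0 and increase strictly.
#' @param init_state Optional named initial dynamic state (defaults to the
#'   model's initial levels).
#' @param rtol,atol,method Solver settings passed to [deSolve::ode()].
#' @param use_compiled Use the compiled right-hand side (default); set to
#'   `FALSE` to integrate with the plain-R evaluator from [assemble_rhs()].
#' @return A `cd4_trajectory`: time grid (h), state matrix
#'   (time x dynamic species, a.u.), boundary levels used and solver metadata.
#' @export
simulate_time_course <- function(model, recipe = NULL, t_end = 100,
                                 n_points = 1000, times = NULL,
                                 init_state = NULL,
                                 rtol = 1e-8, atol = 1e-10,
                                 method = "lsoda", use_compiled = TRUE) {
  if (is.null(times)) {
    if (!is.numeric(t_end) || t_end <= 0) stop("`t_end` must be > 0")
    times <- seq(0, t_end, length.out = n_points + 1L)
  }
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("`times` must start at 0 and be strictly increasing")
  }
  boundary <- resolve_boundary(model, recipe)
  y0 <- initial_state(model)
  if (!is.null(init_state)) {
    if (is.null(names(init_state))) names(init_state) <- names(y0)
    y0[names(init_state)] <- init_state
  }
  clamps <- model_clamps(model)
  if (length(clamps)) {
    cl_dyn <- intersect(names(clamps), names(y0))
    y0[cl_dyn] <- clamps[cl_dyn]
  }

  if (use_compiled) {
    plan <- compile_plan(model, boundary)
    out <- deSolve::ode(y = unname(y0), times = times, func = "cd4_derivs",
                        parms = plan$vec, dllname = "cd4sim",
                        initfunc = "cd4_init", method = method,
                        rtol = rtol, atol = atol)
  } else {
    rhs <- assemble_rhs(model)
    out <- deSolve::ode(y = y0, times = times,
                        func = function(t, y, p) list(unname(rhs(t, y, boundary))),
                        parms = NULL, method = method, rtol = rtol, atol = atol)
  }

  istate <- attr(out, "istate")
  success <- !is.null(istate) && istate[1] >= 0 && nrow(out) == length(times)
  if (!success) {
    last_t <- out[nrow(out), 1]
    stop("solver failed at t = ", signif(last_t, 6), " h (istate = ",
         istate[1], ")")
  }
  state <- out[, -1, drop = FALSE]
  colnames(state) <- names(y0)
  neg <- min(state)
  structure(list(
    time = out[, 1],
    state = state,
    boundary = boundary,
    recipe_label = if (is.null(recipe)) "default" else recipe$label,
    solver = list(method = method, rtol = rtol, atol = atol,
                  success = TRUE, compiled = use_compiled,
                  min_level = neg)
  ), class = "cd4_trajectory")
}

#' @export
print.cd4_trajectory <- function(x, ...) {
  cat("<cd4_trajectory> ", length(x$time), " time points on [0, ",
      max(x$time), "] h, ", ncol(x$state), " dynamic species (recipe: ",
      x$recipe_label, ")\n", sep = "")
  invisible(x)
}

#' Tidy a trajectory into long format
#' @param x A `cd4_trajectory`.
#' @param row.names,optional,... Ignored (data.frame method signature).
#' @return data.frame with columns `time`, `species`, `level`.
#' @export
as.data.frame.cd4_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    time = rep(x$time, times = ncol(x$state)),
    species = rep(colnames(x$state), each = length(x$time)),
    level = as.vector(x$state),
    stringsAsFactors = FALSE
  )
}

#' Final state of a trajectory
#' @param trajectory A `cd4_trajectory`.
#' @return Named vector of dynamic-species levels at the last time point.
#' @export
endpoint_state <- function(trajectory) {
  trajectory$state[nrow(trajectory$state), ]
}

# Resolve the boundary levels for a recipe: model defaults overridden by the
# recipe doses, with neutralizing antibodies clamping their target cytokine's
# effective level to zero (model metadata `neutralizers`, e.g.
# c(aIFNg = "IFNg_e")).
resolve_boundary <- function(model, recipe = NULL) {
  boundary <- boundary_defaults(model)
  if (!is.null(recipe)) {
    stopifnot(inherits(recipe, "cd4_recipe"))
    bad <- setdiff(names(recipe$doses), names(boundary))
    if (length(bad)) {
      stop("recipe doses must key boundary species; not boundary: ",
           paste(bad, collapse = ", "))
    }
    boundary[names(recipe$doses)] <- recipe$doses
  }
  neut <- model$metadata$neutralizers
  for (ab in names(neut)) {
    if (!is.na(boundary[ab]) && boundary[ab] > 0) boundary[neut[[ab]]] <- 0
  }
  boundary
}

#' Find a steady state
#'
#' Integrates forward in chunks until the right-hand side norm falls below
#' `tol`, and returns the settled state. Consistency with the long-time limit
#' of [simulate_time_course()] is definitional and is exercised in the test
#' suite for all four induction recipes.
#'
#' @param model A `cd4_model`.
#' @param recipe Optional [stimulus_recipe()].
#' @param tol Convergence tolerance on `max(abs(d state/dt))` (a.u./h).
#' @param t_chunk Chunk length in hours.
#' @param max_time Give up beyond this total time (hours).
#' @param init_state Optional starting state.
#' @param ... Passed to [simulate_time_course()].
#' @return Named steady-state vector of the dynamic species.
#' @export
steady_state <- function(model, recipe = NULL, tol = 1e-8, t_chunk = 250,
                         max_time = 2e4, init_state = NULL, ...) {
  rhs <- assemble_rhs(model)
  boundary <- resolve_boundary(model, recipe)
  state <- init_state
  t_total <- 0
  repeat {
    traj <- simulate_time_course(model, recipe, t_end = t_chunk,
                                 n_points = 50, init_state = state, ...)
    state <- endpoint_state(traj)
    t_total <- t_total + t_chunk
    if (max(abs(rhs(t_total, state, boundary))) < tol) return(state)
    if (t_total >= max_time) {
      stop("steady_state: no convergence after ", t_total,
           " h; consider a time-course with a longer horizon instead")
    }
  }
}

#' Scan a parameter, input dose or clamp level
#'
#' Re-simulates the model once per grid value and collects endpoint (or
#' steady-state) readouts. `parameter` may be a kinetic-constant name, a
#' boundary species id (dose scan), or `"clamp:<species>"` to hold a species
#' at each grid value (used for the activated-PPARg concentration scans).
#' Each grid point restarts from the same initial state unless `init_state`
#' is supplied (continue-from, used by the plasticity protocol).
#'
#' @param model A `cd4_model`.
#' @param recipe Optional [stimulus_recipe()].
#' @param parameter Scanned quantity (see Details).
#' @param grid Ascending numeric grid.
#' @param readouts Character vector of dynamic species to report.
#' @param mode `"endpoint"` (default, level at `t_end`) or `"steady_state"`.
#' @param t_end,init_state,... Passed to [simulate_time_course()].
#' @return A `cd4_scan`: grid, readout matrix (one row per grid value) and
#'   per-point failure messages (scan continues past solver failures).
#' @export
parameter_scan <- function(model, recipe = NULL, parameter, grid,
                           readouts, mode = c("endpoint", "steady_state"),
                           t_end = 100, init_state = NULL, ...) {
  mode <- match.arg(mode)
  if (!length(grid)) stop("`grid` must be nonempty")
  if (is.unsorted(grid)) stop("`grid` must be ascending")
  res <- matrix(NA_real_, nrow = length(grid), ncol = length(readouts),
                dimnames = list(NULL, readouts))
  failures <- rep(NA_character_, length(grid))
  for (i in seq_along(grid)) {
    m_i <- scan_apply(model, parameter, grid[i])
    ep <- tryCatch({
      if (mode == "endpoint") {
        endpoint_state(simulate_time_course(m_i, recipe, t_end = t_end,
                                            init_state = init_state, ...))
      } else {
        steady_state(m_i, recipe, init_state = init_state, ...)
      }
    }, error = function(e) e)
    if (inherits(ep, "error")) {
      failures[i] <- conditionMessage(ep)
    } else {
      res[i, ] <- ep[readouts]
    }
  }
  structure(list(parameter = parameter, grid = grid, readouts = res,
                 mode = mode, failures = failures),
            class = "cd4_scan")
}

#' @export
print.cd4_scan <- function(x, ...) {
  cat("<cd4_scan> ", x$parameter, " over ", length(x$grid), " values; ",
      "readouts: ", paste(colnames(x$readouts), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Combined scan and time course
#'
#' Like [parameter_scan()] but retains the full trajectory per grid value,
#' reproducing the combined parameter-scan/time-course simulation mode (each
#' returned trajectory corresponds to one incremented value of the scanned
#' quantity).
#'
#' @inheritParams parameter_scan
#' @return List of `cd4_trajectory`, one per grid value, named by grid value.
#' @export
scan_time_course <- function(model, recipe = NULL, parameter, grid,
                             t_end = 100, init_state = NULL, ...) {
  if (!length(grid)) stop("`grid` must be nonempty")
  out <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    m_i <- scan_apply(model, parameter, grid[i])
    out[[i]] <- simulate_time_course(m_i, recipe, t_end = t_end,
                                     init_state = init_state, ...)
  }
  names(out) <- signif(grid, 8)
  out
}

# Apply one scan value: kinetic constant, boundary dose, or species clamp.
scan_apply <- function(model, parameter, value) {
  if (startsWith(parameter, "clamp:")) {
    sp <- sub("^clamp:", "", parameter)
    if (!sp %in% model$species$id) stop("unknown clamp species: ", sp)
    cl <- model_clamps(model)
    cl[sp] <- value
    model$metadata$clamps <- cl
    model
  } else if (parameter %in% names(model$parameters)) {
    set_parameter(model, parameter, value)
  } else if (parameter %in% boundary_species(model)) {
    model$species$initial_level[model$species$id == parameter] <- value
    model
  } else {
    stop("unknown scan parameter: ", parameter)
  }
}
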
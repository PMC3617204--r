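#' Local sensitivity analysis (control coefficients)
#'
#' Normalized local sensitivities of readout levels to kinetic constants,
#' \deqn{C_{y,p} = (p / y)\,(\partial y / \partial p),}
#' estimated by central finite differences with per-parameter step
#' `max(delta_factor * |p|, delta_min)`. Readouts are evaluated on
#' time-course endpoints at `t_eval` (default 100 h) or at steady state.
#' Where a baseline readout is (numerically) zero the coefficient is reported
#' as the unnormalized derivative and flagged.
#'
#' @param model A `cd4_model`.
#' @param recipe Optional [stimulus_recipe()] defining the milieu.
#' @param readouts Character vector of dynamic species.
#' @param parameters Parameter names to perturb (default: all).
#' @param delta_factor Relative finite-difference step (default 1e-4).
#' @param delta_min Absolute step floor (default 1e-12).
#' @param t_eval Evaluation time in hours (endpoint mode).
#' @param mode `"endpoint"` or `"steady_state"`.
#' @param ... Passed to [simulate_time_course()].
#' @return A `cd4_sensitivity`: `coefficients` (readout x parameter matrix),
#'   `unnormalized` (logical matrix flagging zero-baseline entries),
#'   `baseline` readout levels and the evaluation metadata.
#' @export
local_sensitivities <- function(model, recipe = NULL, readouts,
                                parameters = names(model$parameters),
                                delta_factor = 1e-4, delta_min = 1e-12,
                                t_eval = 100,
                                mode = c("endpoint", "steady_state"), ...) {
  mode <- match.arg(mode)
  if (delta_factor <= 0) stop("`delta_factor` must be > 0")
  missing_p <- setdiff(parameters, names(model$parameters))
  if (length(missing_p)) stop("unknown parameters: ",
                              paste(missing_p, collapse = ", "))
  missing_r <- setdiff(readouts, dynamic_species(model))
  if (length(missing_r)) stop("unknown readouts: ",
                              paste(missing_r, collapse = ", "))

  eval_readouts <- function(m) {
    if (mode == "endpoint") {
      ep <- endpoint_state(simulate_time_course(m, recipe,
                                                times = c(0, t_eval), ...))
    } else {
      ep <- steady_state(m, recipe, ...)
    }
    ep[readouts]
  }
  y0 <- eval_readouts(model)
  zero_base <- abs(y0) < 1e-12

  C <- matrix(NA_real_, nrow = length(readouts), ncol = length(parameters),
              dimnames = list(readouts, parameters))
  for (j in seq_along(parameters)) {
    p <- parameters[j]
    p0 <- model$parameters[[p]]
    h <- max(delta_factor * abs(p0), delta_min)
    yp <- eval_readouts(set_parameter(model, p, p0 + h))
    ym <- eval_readouts(set_parameter(model, p, p0 - h))
    dydp <- (yp - ym) / (2 * h)
    C[, j] <- ifelse(zero_base, dydp, (p0 / y0) * dydp)
  }
  structure(list(
    coefficients = C,
    unnormalized = matrix(zero_base, nrow = length(readouts),
                          ncol = length(parameters),
                          dimnames = dimnames(C)),
    baseline = y0,
    settings = list(delta_factor = delta_factor, delta_min = delta_min,
                    t_eval = t_eval, mode = mode)
  ), class = "cd4_sensitivity")
}

#' @export
print.cd4_sensitivity <- function(x, ...) {
  cat("<cd4_sensitivity> ", nrow(x$coefficients), " readouts x ",
      ncol(x$coefficients), " parameters (", x$settings$mode, ", t = ",
      x$settings$t_eval, " h)\n", sep = "")
  invisible(x)
}

#' Rank parameters by sensitivity
#'
#' Orders parameters by aggregate influence, `max(|C|)` over readouts, with a
#' stable alphabetical tie-break.
#'
#' @param report A `cd4_sensitivity` from [local_sensitivities()].
#' @return data.frame with columns `parameter` and `score`, most influential
#'   first.
#' @export
rank_parameters <- function(report) {
  C <- report$coefficients
  if (any(!is.finite(C))) stop("sensitivity report contains non-finite entries")
  score <- apply(abs(C), 2, max)
  ord <- order(-score, colnames(C), method = "radix")
  data.frame(parameter = colnames(C)[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}
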
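#' Mass-action reaction rate
#'
#' Rate of an elementary reaction under the law of mass action:
#' \deqn{v = k \prod_i S_i^{\nu_i}}
#' where \eqn{S_i} are substrate levels (arbitrary units) and \eqn{\nu_i}
#' their stoichiometric coefficients. Products are formed "as a proportion of
#' the participating molecules", so the rate is linear in each unit-stoichiometry
#' substrate and homogeneous of degree one in \code{k}.
#'
#' @param k Rate constant (> 0), in 1/h per appropriate power of a.u.
#' @param substrate_levels Either a numeric vector of levels (stoichiometry 1
#'   for each) or a two-column matrix / data.frame with columns \code{level}
#'   and \code{stoich}.
#' @return The reaction rate (a.u./h), a non-negative scalar for non-negative
#'   levels.
#' @examples
#' mass_action_rate(2, 3)                      # 6
#' mass_action_rate(0.5, cbind(level = 2, stoich = 2))  # 0.5 * 2^2 = 2
#' @export
mass_action_rate <- function(k, substrate_levels) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("mass_action_rate: `k` must be a single finite value > 0")
  }
  if (is.null(substrate_levels) || (is.numeric(substrate_levels) && length(substrate_levels) == 0L)) {
    return(k)
  }
  if (is.data.frame(substrate_levels) || is.matrix(substrate_levels)) {
    lev <- as.numeric(substrate_levels[, 1])
    sto <- as.numeric(substrate_levels[, 2])
  } else {
    lev <- as.numeric(substrate_levels)
    sto <- rep(1, length(lev))
  }
  if (any(!is.finite(lev)) || any(lev < 0)) {
    stop("mass_action_rate: substrate levels must be finite and >= 0")
  }
  if (any(sto <= 0)) stop("mass_action_rate: stoichiometries must be > 0")
  k * prod(lev^sto)
}

#' Hill-function reaction rate
#'
#' Saturating, optionally cooperative activation by a driver species with
#' multiplicative saturating inhibition:
#' \deqn{v = v_{max}\,\frac{D^n}{K_m^n + D^n}\,\prod_j \frac{k_{i,j}}{k_{i,j} + I_j}}
#' The rate equals \code{vmax/2} at \code{driver_level == km} when no
#' inhibitors are present, and is bounded in \code{[0, vmax]}.
#'
#' The Hill term is evaluated through the log-ratio \eqn{(D/K_m)^n} so that
#' large Hill coefficients (e.g. n = 50) do not overflow.
#'
#' @param vmax Maximal rate (a.u./h, > 0).
#' @param km Half-saturation driver level (a.u., > 0).
#' @param n Hill coefficient (dimensionless, >= 1).
#' @param driver_level Level of the driving species (a.u., >= 0).
#' @param inhibitors Optional inhibitors: numeric vector of levels paired with
#'   \code{ki} values via a two-column matrix/data.frame with columns
#'   \code{level} and \code{ki}, or \code{NULL}.
#' @return The rate (a.u./h) in \code{[0, vmax]}.
#' @examples
#' hill_rate(1, 0.5, 1, 0.5)                       # 0.5
#' hill_rate(1, 1, 2, 1, cbind(level = 1, ki = 1)) # 0.25
#' @export
hill_rate <- function(vmax, km, n, driver_level, inhibitors = NULL) {
  if (!is.finite(vmax) || vmax <= 0) stop("hill_rate: `vmax` must be > 0")
  if (!is.finite(km) || km <= 0) stop("hill_rate: `km` must be > 0")
  if (!is.finite(n) || n < 1) stop("hill_rate: `n` must be >= 1")
  if (!is.finite(driver_level) || driver_level < 0) {
    stop("hill_rate: `driver_level` must be finite and >= 0")
  }
  occ <- hill_occupancy(driver_level, km, n)
  inh <- 1
  if (!is.null(inhibitors) && NROW(inhibitors) > 0L) {
    lev <- as.numeric(inhibitors[, 1])
    ki <- as.numeric(inhibitors[, 2])
    if (any(!is.finite(ki)) || any(ki <= 0)) stop("hill_rate: inhibition constants must be > 0")
    if (any(!is.finite(lev)) || any(lev < 0)) stop("hill_rate: inhibitor levels must be >= 0")
    inh <- prod(ki / (ki + lev))
  }
  vmax * occ * inh
}

# Fractional occupancy D^n / (km^n + D^n), evaluated in log space for
# numerical stability at large n.
hill_occupancy <- function(driver_level, km, n) {
  if (driver_level == 0) return(0)
  lr <- n * (log(driver_level) - log(km))
  if (lr > 500) return(1)
  r <- exp(lr)
  r / (1 + r)
}
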
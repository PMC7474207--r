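#' Langevin / Brownian dynamics parameters (reduced units)
#'
#' The engine integrates overdamped Langevin (Brownian) dynamics by default:
#' positions move with mobility `dt/gamma` under the systematic force plus
#' Gaussian noise of per-coordinate variance `2 kT dt / gamma`, the
#' fluctuation-dissipation pairing of a noise dispersion `2 gamma kT`. The
#' standard thermostat of the model family is `kT = 0.3` eps with damping
#' `gamma = 2 m / tau` and time step `0.005 tau`.
#'
#' @param kT thermal energy, eps
#' @param gamma damping coefficient (default `2 * mass`, i.e. 2m/tau)
#' @param dt time step, tau
#' @param mass bead mass, reduced
#' @param seed integer seed
#' @param overdamped logical; the inertial (BAOAB) integrator is available
#'   for the 1D validation systems only
#' @return a `LangevinParams` list
#' @export
langevin_params <- function(kT = 0.3, gamma = 2 * mass, dt = 0.005, mass = 1,
                            seed = 1, overdamped = TRUE) {
  stopifnot(dt > 0, kT >= 0, gamma > 0, mass > 0)
  structure(list(kT = kT, gamma = gamma, dt = dt, mass = mass,
                 seed = as.integer(seed), overdamped = overdamped),
            class = "LangevinParams")
}

#' End-to-end distance (the reaction coordinate)
#'
#' Euclidean distance between the first and last Ca bead.
#'
#' @param x a `CAlphaStructure`, an n x 3 coordinate matrix, or a list with a
#'   `positions` element
#' @return distance in A
#' @export
end_to_end <- function(x) {
  if (inherits(x, "CAlphaStructure")) x <- ca_coords(x)
  if (is.list(x) && !is.null(x$positions)) x <- x$positions
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least two residues")
  sqrt(sum((x[n, ] - x[1, ])^2))
}

#' Propagate the coarse-grained system
#'
#' Advances `n_steps` Brownian-dynamics steps and records the end-to-end
#' distance at `stride`. Blow-ups (non-finite or absurd coordinates) raise
#' an error naming the step.
#'
#' @param topology `GoTopology`
#' @param positions starting n x 3 coordinates; default native
#' @param params `LangevinParams`
#' @param n_steps number of steps
#' @param stride recording stride (steps)
#' @param seed overrides `params$seed` when given
#' @return list with final `positions` and recorded `time`, `end_to_end`
#' @export
run_dynamics <- function(topology, positions = NULL, params = langevin_params(),
                         n_steps = 1000, stride = 10, seed = NULL) {
  if (is.null(positions)) positions <- topology$native_positions
  if (is.null(seed)) seed <- params$seed
  if (!params$overdamped)
    stop("the coarse-grained engine is overdamped-only")
  cpp_cg_run(.cpp_topology(topology), as.matrix(positions), params$kT,
             params$gamma, params$dt, seed, n_steps, as.integer(stride))
}

.POTENTIALS <- c(free = 0L, harmonic = 1L, quartic = 2L, linear = 3L)

#' Simulate a 1D validation system
#'
#' One-dimensional Brownian (or, optionally, inertial BAOAB Langevin)
#' dynamics in an analytic potential, used to validate the integrator and
#' the free-energy estimators against quadrature oracles. Potentials:
#' `"free"` (V = 0), `"harmonic"` (V = p/2 x^2), `"quartic"` (V = p x^4),
#' `"linear"` (V = p x).
#'
#' @param potential potential name
#' @param p potential parameter
#' @param x0 starting coordinate
#' @param params `LangevinParams`
#' @param n_steps,n_equil total and discarded steps
#' @param stride sampling stride
#' @param k_umb,center optional harmonic umbrella bias
#' @param seed overrides `params$seed`
#' @return numeric vector of sampled coordinates
#' @export
simulate_1d <- function(potential = "harmonic", p = 1, x0 = 0,
                        params = langevin_params(), n_steps = 1e5,
                        n_equil = 0, stride = 1, k_umb = 0, center = 0,
                        seed = NULL) {
  pot <- .POTENTIALS[match.arg(potential, names(.POTENTIALS))]
  if (is.null(seed)) seed <- params$seed
  cpp_bd1d_sample(pot, p, x0, params$kT, params$gamma, params$dt, seed,
                  n_steps, n_equil, as.integer(stride), k_umb, center,
                  !params$overdamped, params$mass)
}

#' Boltzmann quadrature oracle for 1D potentials
#'
#' Numerically normalised equilibrium density, CDF, or per-interval
#' log-weights for the analytic 1D potentials; this is the independent
#' reference the sampling estimators are checked against.
#'
#' @param potential,p potential as in [simulate_1d()]
#' @param kT thermal energy
#' @param lower,upper integration domain
#' @return list with functions `pdf(x)`, `cdf(x)` and
#'   `interval_weight(a, b)` (unnormalised Boltzmann integrals)
#' @export
boltzmann_1d <- function(potential = "harmonic", p = 1, kT = 0.3,
                         lower = -Inf, upper = Inf) {
  potential <- match.arg(potential, names(.POTENTIALS))
  V <- switch(potential,
              free = function(x) 0 * x,
              harmonic = function(x) 0.5 * p * x^2,
              quartic = function(x) p * x^4,
              linear = function(x) p * x)
  w <- function(x) exp(-V(x) / kT)
  Z <- integrate(w, lower, upper, rel.tol = 1e-10)$value
  pdf <- function(x) w(x) / Z
  cdf <- Vectorize(function(x)
    integrate(pdf, lower, x, rel.tol = 1e-9)$value)
  interval_weight <- function(a, b)
    integrate(w, a, b, rel.tol = 1e-10)$value
  list(pdf = pdf, cdf = cdf, interval_weight = interval_weight, Z = Z, V = V)
}
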
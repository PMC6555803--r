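#' Saturated torque amplitude from the reorientation time
#'
#' The deterministic alignment dynamics `dphi/dt = -omega_max sin(phi)` has
#' the characteristic reorientation time
#' `tau = (2 / omega_max) * |ln((cos(phi_max) + 1) / sin(phi_max))|`,
#' the time to traverse from `phi = phi_max` to its supplement
#' `phi = pi - phi_max`. This inverts that relation for `omega_max`. The
#' absolute value fixes the sign for reference angles above pi/2.
#'
#' @param tau Reorientation time (s, > 0).
#' @param phi_max Reference angle (rad) in (0, pi), not pi/2 (where the
#'   traversal time degenerates to 0).
#' @return Torque amplitude omega_max (rad/s).
#' @examples
#' omega_max_from_tau(3.3, 3)   # ~1.604 rad/s
#' @export
omega_max_from_tau <- function(tau, phi_max = 3) {
  check_phi_max(phi_max)
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0))
    stop("tau must be finite and > 0", call. = FALSE)
  2 * abs(log((cos(phi_max) + 1) / sin(phi_max))) / tau
}

#' Reorientation time from the torque amplitude
#'
#' Inverse of [omega_max_from_tau()]; the round trip is an identity.
#'
#' @param omega_max Torque amplitude (rad/s, > 0).
#' @inheritParams omega_max_from_tau
#' @return Reorientation time tau (s).
#' @export
tau_from_omega <- function(omega_max, phi_max = 3) {
  check_phi_max(phi_max)
  if (!is.numeric(omega_max) || any(!is.finite(omega_max)) ||
      any(omega_max <= 0))
    stop("omega_max must be finite and > 0", call. = FALSE)
  2 * abs(log((cos(phi_max) + 1) / sin(phi_max))) / omega_max
}

check_phi_max <- function(phi_max) {
  if (!is.numeric(phi_max) || length(phi_max) != 1L || !is.finite(phi_max) ||
      phi_max <= 0 || phi_max >= pi)
    stop("phi_max must lie in (0, pi)", call. = FALSE)
  if (isTRUE(all.equal(phi_max, pi / 2, tolerance = 1e-12)))
    stop("phi_max = pi/2 degenerates the reorientation-time relation",
         call. = FALSE)
  invisible(phi_max)
}

#' Closed-form noise-free alignment trajectory
#'
#' Exact solution of the restoring alignment equation
#' `dphi/dt = -omega_max sin(phi)`:
#' `phi(t) = arccos(tanh(omega_max * (t - t_bar)))`, where `t_bar` is the
#' time at which `phi = pi/2`. phi decreases monotonically from pi (as
#' t -> -Inf) toward 0, i.e. the particle axis relaxes onto the local
#' gradient direction.
#'
#' @param omega_max Torque amplitude (rad/s, > 0).
#' @param t_bar Time at which phi = pi/2 (s).
#' @param t Time(s) at which to evaluate (s); vectorized.
#' @return Angle(s) phi in (0, pi) (rad).
#' @export
reorientation_closed_form <- function(omega_max, t_bar, t) {
  stopifnot(is.numeric(omega_max), length(omega_max) == 1L, omega_max > 0)
  acos(tanh(omega_max * (t - t_bar)))
}

#' Noise-free alignment traversal time by ODE integration
#'
#' Integrates `dphi/dt = -omega_max sin(phi)` from `phi_from` until the
#' angle crosses `phi_to`, using an adaptive solver with root finding, and
#' returns the elapsed time. For `phi_from = phi_max` and
#' `phi_to = pi - phi_max` this reproduces [tau_from_omega()]; the two
#' routes are independent (closed form vs numerical integration).
#'
#' @param omega_max Torque amplitude (rad/s, > 0).
#' @param phi_from Initial angle (rad), in (0, pi).
#' @param phi_to Target angle (rad), in (0, pi), below `phi_from`.
#' @param rtol,atol Solver tolerances.
#' @return Elapsed time (s).
#' @export
alignment_traversal_time <- function(omega_max, phi_from = 3,
                                     phi_to = pi - 3,
                                     rtol = 1e-10, atol = 1e-12) {
  stopifnot(omega_max > 0, phi_from > 0, phi_from < pi,
            phi_to > 0, phi_to < phi_from)
  t_max <- (50 / omega_max)
  out <- deSolve::lsodar(
    y = c(phi = phi_from), times = c(0, t_max),
    func = function(t, y, p) list(-omega_max * sin(y)),
    rootfunc = function(t, y, p) y - phi_to,
    rtol = rtol, atol = atol)
  troot <- attr(out, "troot")
  if (is.null(troot) || length(troot) == 0L)
    stop("alignment did not reach phi_to within the integration horizon",
         call. = FALSE)
  troot[1]
}

#' Propulsion speed from local light intensity
#'
#' Linear map `v_p = v_p_max * I / I_ref`, clipped below at 0. The
#' calibration anchor `I_ref` is the peak intensity at which the particle
#' reaches its maximal speed; by default the species' stored reference
#' (0.625 uW/um^2 for the presets, where v_p_max = 2 um/s). Valid in the
#' positive-phototaxis regime (I above the reversal intensity), which the
#' species asserts.
#'
#' @param species A [particle_species()].
#' @param I Intensity (uW/um^2, >= 0); vectorized.
#' @param I_ref Calibration intensity (uW/um^2, > 0).
#' @return Propulsion speed(s) (um/s).
#' @export
speed_from_intensity <- function(species, I, I_ref = species$I_ref) {
  stopifnot(inherits(species, "particle_species"), I_ref > 0)
  if (any(I < 0)) stop("intensity must be >= 0", call. = FALSE)
  pmax(0, species$v_p_max * I / I_ref)
}

#' Define an active-particle species
#'
#' Bundles the physical parameters of one particle type. Exactly one of
#' `tau` or `omega_max` must be given; the other is derived through the
#' reorientation-time relation (both may be given if mutually consistent to
#' 1e-9 relative). The translational diffusion coefficient defaults to the
#' bulk-sphere Stokes-Einstein ratio `D_t = D_r * sigma^2 / 3`.
#'
#' @param sigma Particle diameter (um, > 0).
#' @param v_p_max Maximum propulsion speed (um/s, > 0), reached at the
#'   calibration intensity `I_ref`.
#' @param D_r Rotational diffusion coefficient (1/s, > 0).
#' @param D_t Translational diffusion coefficient (um^2/s, > 0); default
#'   `D_r * sigma^2 / 3`.
#' @param tau Reorientation time (s) at the reference angle `phi_max`.
#' @param omega_max Saturated aligning-torque amplitude (rad/s).
#' @param phi_max Reference angle for the tau calibration (rad), default 3.
#' @param I_ref Calibration intensity for the speed map (uW/um^2), default
#'   0.625.
#' @param grad_saturation Gradient magnitude (uW/um^3) above which the
#'   torque amplitude saturates at `omega_max`. `Inf` (default) treats every
#'   gradient as saturated, matching operation well above the saturation
#'   threshold; a finite value enables a linear sub-saturation ramp.
#' @param name Species label.
#' @return A `particle_species` object. The flag `I_r_exceeded` is TRUE:
#'   the model only covers the positive-phototaxis regime.
#' @seealso [species_preset()] for the built-in "small" and "big" particles.
#' @export
particle_species <- function(sigma, v_p_max = 2, D_r, D_t = NULL,
                             tau = NULL, omega_max = NULL, phi_max = 3,
                             I_ref = 0.625, grad_saturation = Inf,
                             name = "custom") {
  if (is.null(tau) && is.null(omega_max))
    stop("provide tau or omega_max", call. = FALSE)
  check_phi_max(phi_max)
  if (is.null(omega_max)) omega_max <- omega_max_from_tau(tau, phi_max)
  if (is.null(tau)) tau <- tau_from_omega(omega_max, phi_max)
  if (is.null(D_t)) D_t <- D_r * sigma^2 / 3
  sp <- structure(
    list(name = name, sigma = sigma, v_p_max = v_p_max, D_r = D_r,
         D_t = D_t, tau = tau, phi_max = phi_max, omega_max = omega_max,
         I_ref = I_ref, grad_saturation = grad_saturation,
         I_r_exceeded = TRUE),
    class = "particle_species")
  validate_species(sp)
}

validate_species <- function(sp) {
  pos <- c("sigma", "v_p_max", "D_r", "D_t", "tau", "omega_max", "I_ref")
  for (f in pos) {
    v <- sp[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("species: %s must be a positive number", f),
           call. = FALSE)
  }
  check_phi_max(sp$phi_max)
  if (!(is.numeric(sp$grad_saturation) && (is.infinite(sp$grad_saturation) ||
        sp$grad_saturation > 0)))
    stop("species: grad_saturation must be > 0 or Inf", call. = FALSE)
  om <- omega_max_from_tau(sp$tau, sp$phi_max)
  if (abs(om - sp$omega_max) / om > 1e-9)
    stop("species: tau and omega_max are inconsistent with the ",
         "reorientation-time relation", call. = FALSE)
  sp
}

#' Built-in particle species presets
#'
#' Parameters of the two colloid types the model is calibrated for. Both
#' share the same maximum propulsion speed (propulsion depends on the cap
#' thickness, not the diameter); the aligning torque grows with diameter,
#' so the big species reorients faster while decorrelating more slowly.
#'
#' * `"small"`: sigma = 3.25 um, 1/D_r = 50 s, tau = 3.3 s
#' * `"big"`:   sigma = 4.9 um, 1/D_r = 115 s, tau = 1.83 s
#'
#' Both use v_p_max = 2 um/s, phi_max = 3 rad, I_ref = 0.625 uW/um^2.
#'
#' @param name `"small"` or `"big"`.
#' @param ... Overrides passed to [particle_species()] (e.g. `v_p_max`,
#'   `D_t`). Overriding `omega_max` replaces the preset `tau`.
#' @return A `particle_species`.
#' @examples
#' sp <- species_preset("small")
#' sp$omega_max   # ~1.604 rad/s
#' @export
species_preset <- function(name = c("small", "big"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    small = list(sigma = 3.25, v_p_max = 2, D_r = 1 / 50, tau = 3.3,
                 name = "small"),
    big = list(sigma = 4.9, v_p_max = 2, D_r = 1 / 115, tau = 1.83,
               name = "big"))
  dots <- list(...)
  if ("omega_max" %in% names(dots) && !("tau" %in% names(dots)))
    defaults$tau <- NULL
  do.call(particle_species, modifyList(defaults, dots))
}

#' @export
print.particle_species <- function(x, ...) {
  cat(sprintf(
    paste0("<particle_species> %s: sigma = %g um, v_p_max = %g um/s,\n",
           "  D_r = %.4g 1/s (1/D_r = %.3g s), D_t = %.4g um^2/s,\n",
           "  tau = %g s at phi_max = %g rad (omega_max = %.4g rad/s)\n"),
    x$name, x$sigma, x$v_p_max, x$D_r, 1 / x$D_r, x$D_t, x$tau, x$phi_max,
    x$omega_max))
  invisible(x)
}
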
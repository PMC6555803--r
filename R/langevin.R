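#' Initial-orientation policies
#'
#' Describe how the initial orientation theta0 of each replicate is chosen:
#' a fixed angle, uniform on (-pi, pi], or uniform within a bin
#' `center +/- halfwidth` (the convention used when resolving observables
#' by initial orientation; default halfwidth 0.2 rad).
#'
#' @param value Fixed angle (rad).
#' @param center Bin center (rad).
#' @param halfwidth Bin half-width (rad, > 0), default 0.2.
#' @return A `theta0_spec` object.
#' @name theta0
NULL

#' @rdname theta0
#' @export
theta0_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(kind = "fixed", value = value), class = "theta0_spec")
}

#' @rdname theta0
#' @export
theta0_uniform <- function() {
  structure(list(kind = "uniform"), class = "theta0_spec")
}

#' @rdname theta0
#' @export
theta0_bin <- function(center, halfwidth = 0.2) {
  stopifnot(is.finite(center), is.finite(halfwidth), halfwidth > 0)
  structure(list(kind = "bin", center = center, halfwidth = halfwidth),
            class = "theta0_spec")
}

as_theta0_spec <- function(x) {
  if (inherits(x, "theta0_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(theta0_fixed(x))
  if (identical(x, "uniform")) return(theta0_uniform())
  stop("theta0 must be a number, \"uniform\", or a theta0_*() spec",
       call. = FALSE)
}

draw_theta0 <- function(spec) {
  switch(spec$kind,
    fixed = wrap_angle_r(spec$value),
    uniform = runif(1, -pi, pi),
    bin = wrap_angle_r(runif(1, spec$center - spec$halfwidth,
                             spec$center + spec$halfwidth)))
}

wrap_angle_r <- function(a) {
  a <- (a + pi) %% (2 * pi)
  a[a <= 0] <- a[a <= 0] + 2 * pi
  a - pi
}

#' Simulation configuration
#'
#' Bundles species, light field, integration settings and initial
#' conditions for [simulate_trajectory()] / [simulate_ensemble()]. The time
#' step must satisfy the stability bounds `dt <= 0.1 / omega_max` and
#' `dt <= 0.1 / D_r` so that neither the deterministic torque nor the
#' rotational diffusion rotates the particle by more than ~0.1 rad per step.
#'
#' @param species A [particle_species()].
#' @param field A `light_field`.
#' @param t_end Duration (s, > 0).
#' @param dt Time step (s), default 0.01.
#' @param seed Integer seed for the replicate's noise (and theta0 draw).
#' @param x0,y0 Initial position (um).
#' @param theta0 Initial orientation: a number (fixed), `"uniform"`, or a
#'   [theta0_fixed()] / [theta0_uniform()] / [theta0_bin()] spec.
#' @param save_every Store every `save_every`-th step (default: every
#'   ~0.1 s of simulated time).
#' @return A `sim_config` object.
#' @export
sim_config <- function(species, field, t_end, dt = 0.01, seed = 1L,
                       x0 = 0, y0 = 0, theta0 = theta0_uniform(),
                       save_every = NULL) {
  stopifnot(inherits(species, "particle_species"),
            inherits(field, "light_field"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (dt > 0.1 / species$omega_max || dt > 0.1 / species$D_r)
    stop(sprintf(
      "dt = %g violates the stability bound min(0.1/omega_max, 0.1/D_r) = %g",
      dt, min(0.1 / species$omega_max, 0.1 / species$D_r)), call. = FALSE)
  if (is.null(save_every)) save_every <- max(1L, as.integer(round(0.1 / dt)))
  save_every <- as.integer(save_every)
  stopifnot(save_every >= 1L)
  n_steps <- as.integer(ceiling(t_end / dt - 1e-9))
  # keep sampling uniform: round the step count up to a save multiple
  n_steps <- as.integer(ceiling(n_steps / save_every) * save_every)
  structure(
    list(species = species, field = field, dt = dt, t_end = n_steps * dt,
         n_steps = n_steps, save_every = save_every,
         seed = as.integer(seed), x0 = x0, y0 = y0,
         theta0 = as_theta0_spec(theta0)),
    class = "sim_config")
}

#' Simulate one particle trajectory
#'
#' Euler-Maruyama integration of the overdamped Langevin equations: the
#' position advances at the intensity-set propulsion speed along the
#' particle axis plus translational noise, and the orientation relaxes
#' toward the local gradient direction at rate `omega_max sin(phi)` plus
#' rotational noise (phi is the angle between the axis and the gradient;
#' the torque vanishes where the gradient does). Bit-reproducible for a
#' fixed seed and dt.
#'
#' @param config A [sim_config()].
#' @param noise Optional `n_steps x 3` matrix of standard-normal deviates
#'   (columns: x, y, theta); when supplied, `theta0` must be a fixed value
#'   and the RNG is not touched. Intended for noise-mapping checks.
#' @return An `ap_trajectory`: a data frame with columns `t, x, y, theta,
#'   intensity, v_p` (uniform sampling interval `dt * save_every`, first
#'   row at t = 0) and attributes `species`, `field`, `dt`, `save_every`,
#'   `seed`, `theta0`.
#' @export
simulate_trajectory <- function(config, noise = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$species
  fp <- field_pars(config$field)
  if (is.null(noise)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(config$seed)
    th0 <- draw_theta0(config$theta0)
    noise <- matrix(rnorm(config$n_steps * 3L), config$n_steps, 3L)
  } else {
    if (config$theta0$kind != "fixed")
      stop("explicit noise requires a fixed theta0", call. = FALSE)
    th0 <- config$theta0$value
    noise <- as.matrix(noise)
  }
  m <- integrate_langevin_cpp(
    config$x0, config$y0, th0, config$dt, config$n_steps,
    config$save_every,
    fp$type, fp$center, fp$u, fp$w, fp$I_max, fp$n_pulses, fp$gap,
    fp$baseline,
    sp$v_p_max, sp$I_ref, sp$D_t, sp$D_r, sp$omega_max, sp$grad_saturation,
    noise)
  traj <- as.data.frame(m)
  attr(traj, "species") <- sp
  attr(traj, "field") <- config$field
  attr(traj, "dt") <- config$dt
  attr(traj, "save_every") <- config$save_every
  attr(traj, "seed") <- config$seed
  attr(traj, "theta0") <- th0
  class(traj) <- c("ap_trajectory", "data.frame")
  traj
}

#' Simulate an ensemble of independent replicates
#'
#' Runs [simulate_trajectory()] `n_reps` times with per-replicate seeds
#' `seed_base + 0:(n_reps - 1)`; each replicate draws its own initial
#' orientation from the config's theta0 policy.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicates (>= 1).
#' @param seed_base First replicate seed (default: the config seed).
#' @param keep_trajectories Keep the full per-replicate trajectories
#'   (default TRUE). With FALSE only the summary `info` table is retained,
#'   which is enough for displacement statistics and saves memory on long
#'   runs.
#' @return An `ap_ensemble`: list with `info` (data frame: rep, seed,
#'   theta0, x0, x_f, y_f, theta_f), `trajectories` (list or NULL),
#'   `config`, `seed_base`.
#' @export
simulate_ensemble <- function(config, n_reps, seed_base = config$seed,
                              keep_trajectories = TRUE) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  n_reps <- as.integer(n_reps)
  seeds <- as.integer(seed_base) + seq_len(n_reps) - 1L
  trajs <- if (keep_trajectories) vector("list", n_reps) else NULL
  info <- data.frame(rep = seq_len(n_reps), seed = seeds, theta0 = NA_real_,
                     x0 = config$x0, x_f = NA_real_, y_f = NA_real_,
                     theta_f = NA_real_)
  for (i in seq_len(n_reps)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    tr <- simulate_trajectory(cfg_i)
    last <- nrow(tr)
    info$theta0[i] <- attr(tr, "theta0")
    info$x_f[i] <- tr$x[last]
    info$y_f[i] <- tr$y[last]
    info$theta_f[i] <- tr$theta[last]
    if (keep_trajectories) trajs[[i]] <- tr
  }
  structure(list(info = info, trajectories = trajs, config = config,
                 seed_base = as.integer(seed_base)),
            class = "ap_ensemble")
}

#' @export
print.ap_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ap_trajectory> %d samples, t in [0, %g] s, seed %d, theta0 = %.3f\n",
    nrow(x), x$t[nrow(x)], attr(x, "seed"), attr(x, "theta0")))
  invisible(x)
}

#' @export
print.ap_ensemble <- function(x, ...) {
  cat(sprintf(
    "<ap_ensemble> %d replicates (seeds %d..%d), t_end = %g s%s\n",
    nrow(x$info), min(x$info$seed), max(x$info$seed), x$config$t_end,
    if (is.null(x$trajectories)) ", summary only" else ""))
  invisible(x)
}

#' @export
plot.ap_trajectory <- function(x, ...) {
  plot(x$t, x$x, type = "l", xlab = "t (s)", ylab = "x (um)", ...)
  invisible(x)
}
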
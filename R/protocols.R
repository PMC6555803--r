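#' Geometry and duration for a pulse protocol
#'
#' Places the particle at x = 0 outside the pulse support with the (first)
#' pulse approaching from -x at speed `u` (> 0), its leading edge starting
#' `lead_gap` ahead of the particle. The run duration is the time for the
#' trailing edge of the last pulse to sweep past `x = drift_allow` (an
#' allowance for how far the particle may drift along +x), plus a settle
#' time.
#'
#' @param species A `particle_species` (used to pick the drift allowance).
#' @param u Pulse speed (um/s, > 0).
#' @param w Pulse width (um).
#' @param n_pulses,gap Train parameters (see [pulse_train()]).
#' @param lead_gap Initial distance from the leading edge to the particle
#'   (um), default 5.
#' @param drift_allow Forward-drift allowance (um); default 120 for slow
#'   pulses (u < v_p_max, where the particle can surf) else 30.
#' @param settle Extra time after the last pulse has passed (s), default 2.
#' @return List with `field` (a [pulse_train()]) and `t_end` (s).
#' @keywords internal
pulse_protocol_setup <- function(species, u, w, n_pulses = 1L, gap = 0,
                                 lead_gap = 5, drift_allow = NULL,
                                 settle = 2) {
  stopifnot(u > 0)
  if (is.null(drift_allow))
    drift_allow <- if (u < species$v_p_max) 120 else 30
  field <- pulse_train(center = -(lead_gap + w / 2), u = u, w = w,
                       n_pulses = n_pulses, gap = gap)
  spacing <- pulse_spacing(field)
  t_end <- (drift_allow + w + lead_gap + (n_pulses - 1) * spacing) / u +
    settle
  list(field = field, t_end = t_end)
}

resolve_species <- function(x) {
  if (inherits(x, "particle_species")) x else species_preset(x)
}

#' Run a canned simulation protocol
#'
#' Parameterized reproductions of the model's standard numerical
#' experiments, each returning a tidy summary table (one row per grid
#' point) that is bit-identical across runs with the same `seed_base`.
#' Available protocols:
#'
#' * `"single_pulse_sweep"`: mean displacement after one pulse passage over
#'   a grid of `u_over_vp` and `w_over_sigma`, optionally resolved by
#'   initial-orientation bins and/or capped at a finite observation window.
#' * `"pulse_train_interval"`: total displacement after a train of
#'   `n_pulses` pulses as a function of the inter-pulse interval
#'   (`T_Dr` = T in units of 1/D_r), optionally per theta0 bin, with
#'   orientation histograms prior to each pulse.
#' * `"train_speed_sweep"`: steady-state drift velocity (linear fit) under
#'   a long pulse train for a grid of `v_p_max` values.
#' * `"sorting_mixture"`: two species under one shared train; per-species
#'   displacement statistics plus a [sorting_summary()] attribute.
#' * `"static_trap"`: localization about a static triangular profile.
#'
#' @param name Protocol name (see above).
#' @param ... Protocol parameters (see the per-protocol defaults in the
#'   implementation; all have sensible defaults).
#' @param n_reps Replicates per grid point (default 50; the figure-level
#'   protocols are intended for >= 20).
#' @param seed_base Base seed; grid point i uses replicate seeds starting
#'   at `seed_base + (i - 1) * n_reps`.
#' @param dt Integration step (s), default 0.01.
#' @return A data frame (class `ap_protocol_result`) with one row per grid
#'   point and an attribute `manifest` recording the protocol name,
#'   parameters and seed. Some protocols attach further result attributes
#'   (`orientation`, `sorting`).
#' @export
run_protocol <- function(name, ..., n_reps = 50, seed_base = 1L,
                         dt = 0.01) {
  fun <- switch(name,
    single_pulse_sweep = protocol_single_pulse_sweep,
    pulse_train_interval = protocol_pulse_train_interval,
    train_speed_sweep = protocol_train_speed_sweep,
    sorting_mixture = protocol_sorting_mixture,
    static_trap = protocol_static_trap,
    stop(sprintf("unknown protocol '%s'", name), call. = FALSE))
  res <- fun(..., n_reps = n_reps, seed_base = as.integer(seed_base),
             dt = dt)
  manifest <- list(protocol = name, n_reps = n_reps,
                   seed_base = as.integer(seed_base), dt = dt,
                   params = list(...))
  attr(res, "manifest") <- manifest
  class(res) <- c("ap_protocol_result", class(res))
  res
}

protocol_single_pulse_sweep <- function(species = "small",
                                        u_over_vp = c(0.125, 0.25, 0.5, 1,
                                                      2, 5),
                                        w_over_sigma = c(2.5, 4, 7),
                                        theta0_bins = NULL,
                                        window = NULL,
                                        n_reps, seed_base, dt) {
  sp <- resolve_species(species)
  grid <- expand.grid(u_over_vp = u_over_vp, w_over_sigma = w_over_sigma,
                      KEEP.OUT.ATTRS = FALSE)
  bins <- if (is.null(theta0_bins)) list(NULL) else theta0_bins
  rows <- list()
  gi <- 0L
  for (r in seq_len(nrow(grid))) {
    u <- grid$u_over_vp[r] * sp$v_p_max
    w <- grid$w_over_sigma[r] * sp$sigma
    setup <- pulse_protocol_setup(sp, u, w)
    for (bin in bins) {
      gi <- gi + 1L
      th0 <- if (is.null(bin)) theta0_uniform() else theta0_bin(bin)
      cfg <- sim_config(sp, setup$field, t_end = setup$t_end, dt = dt,
                        theta0 = th0)
      ens <- simulate_ensemble(cfg, n_reps,
                               seed_base = seed_base + (gi - 1L) * n_reps,
                               keep_trajectories = !is.null(window))
      s <- mean_displacement(ens, window = window)
      rows[[gi]] <- data.frame(
        protocol = "single_pulse_sweep", species = sp$name,
        u = u, u_over_vp = grid$u_over_vp[r], w = w,
        w_over_sigma = grid$w_over_sigma[r], n_pulses = 1L, gap = 0,
        theta0_bin = if (is.null(bin)) NA_real_ else bin,
        mean_dx = s$mean, sd_dx = s$sd, n = s$n,
        seed_base = seed_base + (gi - 1L) * n_reps)
    }
  }
  do.call(rbind, rows)
}

protocol_pulse_train_interval <- function(species = "small",
                                          T_Dr = c(0.1, 0.6, 10),
                                          u_over_vp = 1,
                                          w_over_sigma = 4,
                                          n_pulses = 10L,
                                          theta0_bins = list(0, pi),
                                          orientation = FALSE,
                                          n_reps, seed_base, dt) {
  sp <- resolve_species(species)
  u <- u_over_vp * sp$v_p_max
  w <- w_over_sigma * sp$sigma
  bins <- if (is.null(theta0_bins)) list(NULL) else theta0_bins
  rows <- list()
  orient <- list()
  gi <- 0L
  for (Tfrac in T_Dr) {
    gap <- Tfrac / sp$D_r
    setup <- pulse_protocol_setup(sp, u, w, n_pulses = n_pulses, gap = gap)
    save_every <- max(1L, as.integer(round(
      max(0.1, setup$t_end / 5000) / dt)))
    for (bin in bins) {
      gi <- gi + 1L
      th0 <- if (is.null(bin)) theta0_uniform() else theta0_bin(bin)
      cfg <- sim_config(sp, setup$field, t_end = setup$t_end, dt = dt,
                        theta0 = th0, save_every = save_every)
      ens <- simulate_ensemble(cfg, n_reps,
                               seed_base = seed_base + (gi - 1L) * n_reps,
                               keep_trajectories = orientation)
      s <- mean_displacement(ens)
      rows[[gi]] <- data.frame(
        protocol = "pulse_train_interval", species = sp$name,
        u = u, u_over_vp = u_over_vp, w = w, w_over_sigma = w_over_sigma,
        n_pulses = as.integer(n_pulses), gap = gap, T_Dr = Tfrac,
        theta0_bin = if (is.null(bin)) NA_real_ else bin,
        mean_dx = s$mean, sd_dx = s$sd, n = s$n,
        seed_base = seed_base + (gi - 1L) * n_reps)
      if (orientation) {
        # orientation just before each pulse's leading edge reaches x = 0
        spacing <- pulse_spacing(setup$field)
        lead_gap <- -(setup$field$center + w / 2)
        t_k <- (spacing * (seq_len(n_pulses) - 1L) + lead_gap) / u
        t_k <- pmax(0, t_k - 2 * save_every * dt)
        orient[[sprintf("T_Dr=%g|theta0=%s", Tfrac,
                        if (is.null(bin)) "all" else format(bin))]] <-
          orientation_distribution(ens, t_k)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (orientation) attr(res, "orientation") <- orient
  res
}

protocol_train_speed_sweep <- function(species = "small",
                                       v_p_max = c(0.5, 1, 2, 3, 5, 10),
                                       u = 1, gap = 50,
                                       w_over_sigma = 4,
                                       n_pulses = 25L,
                                       n_reps, seed_base, dt) {
  sp0 <- resolve_species(species)
  w <- w_over_sigma * sp0$sigma
  rows <- list()
  for (i in seq_along(v_p_max)) {
    sp <- species_preset(sp0$name, v_p_max = v_p_max[i])
    setup <- pulse_protocol_setup(sp, u, w, n_pulses = n_pulses, gap = gap,
                                  drift_allow = 100)
    save_every <- max(1L, as.integer(round(
      max(0.1, setup$t_end / 5000) / dt)))
    cfg <- sim_config(sp, setup$field, t_end = setup$t_end, dt = dt,
                      theta0 = theta0_uniform(), save_every = save_every)
    sb <- seed_base + (i - 1L) * n_reps
    ens <- simulate_ensemble(cfg, n_reps, seed_base = sb)
    window <- c(0.1, 0.9) * setup$t_end
    slopes <- vapply(ens$trajectories, function(tr)
      mean_drift_velocity(tr, window = window)$slope, numeric(1))
    rows[[i]] <- data.frame(
      protocol = "train_speed_sweep", species = sp$name,
      v_p_max = v_p_max[i], u = u, w = w, gap = gap,
      n_pulses = as.integer(n_pulses),
      mean_V = mean(slopes), sd_V = sd(slopes), n = n_reps,
      seed_base = sb)
  }
  do.call(rbind, rows)
}

protocol_sorting_mixture <- function(species = c("small", "big"),
                                     u = 2, gap = 5, w = NULL,
                                     n_pulses = 20L, times = NULL,
                                     n_reps, seed_base, dt) {
  sp_a <- resolve_species(species[[1]])
  sp_b <- resolve_species(species[[2]])
  # one shared physical light field; width defaults to 4 sigma of species A
  if (is.null(w)) w <- 4 * sp_a$sigma
  setup <- pulse_protocol_setup(sp_a, u, w, n_pulses = n_pulses, gap = gap,
                                drift_allow = 60)
  mk <- function(sp, sb) {
    cfg <- sim_config(sp, setup$field, t_end = setup$t_end, dt = dt,
                      theta0 = theta0_uniform())
    simulate_ensemble(cfg, n_reps, seed_base = sb)
  }
  ens_a <- mk(sp_a, seed_base)
  ens_b <- mk(sp_b, seed_base + n_reps)
  if (is.null(times)) times <- setup$t_end * c(0.25, 0.5, 0.75, 1)
  sorting <- sorting_summary(ens_a, ens_b, times,
                             labels = c(sp_a$name, sp_b$name))
  rows <- rbind(
    cbind(data.frame(protocol = "sorting_mixture", species = sp_a$name),
          mean_displacement(ens_a),
          data.frame(seed_base = seed_base)),
    cbind(data.frame(protocol = "sorting_mixture", species = sp_b$name),
          mean_displacement(ens_b),
          data.frame(seed_base = seed_base + n_reps)))
  rows$u <- u
  rows$w <- w
  rows$gap <- gap
  rows$n_pulses <- as.integer(n_pulses)
  attr(rows, "sorting") <- sorting
  rows
}

protocol_static_trap <- function(species = "small", w_over_sigma = 4,
                                 t_end = 300, transient = 50,
                                 n_reps, seed_base, dt) {
  sp <- resolve_species(species)
  w <- w_over_sigma * sp$sigma
  field <- static_triangle(center = 0, w = w)
  cfg <- sim_config(sp, field, t_end = t_end, dt = dt,
                    x0 = w / 2, theta0 = theta0_uniform())
  ens <- simulate_ensemble(cfg, n_reps, seed_base = seed_base)
  stats <- t(vapply(ens$trajectories, function(tr) {
    sel <- tr$t >= transient
    c(mean_x = mean(tr$x[sel]), mean_abs_x = mean(abs(tr$x[sel])),
      frac_inside = mean(abs(tr$x[sel]) < w / 2))
  }, numeric(3)))
  data.frame(protocol = "static_trap", species = sp$name, w = w,
             t_end = t_end, transient = transient,
             mean_x = mean(stats[, "mean_x"]),
             mean_abs_x = mean(stats[, "mean_abs_x"]),
             frac_inside = mean(stats[, "frac_inside"]),
             n = n_reps, seed_base = seed_base)
}
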
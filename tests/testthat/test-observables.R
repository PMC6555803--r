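test_that("mean displacement is plain arithmetic over replicates", {
  expect_equal(mean_displacement(fake_ensemble(c(0, 0, 0)))$mean, 0)
  s <- mean_displacement(fake_ensemble(c(1, -3)))
  expect_equal(s$mean, -1)
  expect_equal(s$n, 2L)
})

test_that("an empty orientation bin yields an explicitly empty result", {
  ens <- fake_ensemble(c(1, 2, 3), theta0 = c(0, 0.1, -0.1))
  s <- mean_displacement(ens, theta0 = pi, halfwidth = 0.2)
  expect_equal(s$n, 0L)
  expect_true(is.na(s$mean))
  # and the bin filter wraps on the circle
  ens2 <- fake_ensemble(c(5, -7), theta0 = c(pi - 0.05, -pi + 0.05))
  expect_equal(mean_displacement(ens2, theta0 = pi, halfwidth = 0.2)$n, 2L)
})

test_that("window capping truncates each displacement at first exit", {
  # ballistic limit: every replicate exits through +window exactly
  spb <- noise_free("small")
  cfg <- sim_config(spb, uniform_field(0.625), t_end = 60, theta0 = 0)
  ens <- simulate_ensemble(cfg, 3, seed_base = 3)
  s <- mean_displacement(ens, window = 50)
  expect_equal(s$mean, 50)
  expect_gt(mean_displacement(ens)$mean, 50)   # uncapped: ~120 um
  # noisy ensemble: capped displacements never exceed the window
  sp <- species_preset("small")
  cfg2 <- sim_config(sp, uniform_field(0.625), t_end = 120,
                     theta0 = "uniform")
  ens2 <- simulate_ensemble(cfg2, 10, seed_base = 3)
  expect_lte(abs(mean_displacement(ens2, window = 30)$mean), 30)
})

test_that("a swept-over motionless tracer splits w/2u residence per slope", {
  sp <- tracer_species()
  f <- triangular_pulse(center = -11.5, u = 2, w = 13)
  cfg <- sim_config(sp, f, t_end = 15, dt = 1e-3, theta0 = 0, save_every = 1)
  tr <- simulate_trajectory(cfg)
  rt <- residence_times(tr)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$t_front, 3.25, tolerance = 0.01)  # (w/2)/u
  expect_equal(rt$t_back, 3.25, tolerance = 0.01)
})

test_that("noise-free counter-aligned passage matches the quadrature oracle", {
  sp <- noise_free("small")
  u <- 2
  w <- 13
  f <- triangular_pulse(center = -(5 + w / 2), u = u, w = w)
  cfg <- sim_config(sp, f, t_end = 15, dt = 1e-3, theta0 = pi,
                    save_every = 1)
  tr <- simulate_trajectory(cfg)
  rt <- residence_times(tr)
  # relative speed through either slope is u + v_p(xi), v_p linear in xi
  oracle <- integrate(function(xi) 1 / (u + sp$v_p_max * 2 * xi / w),
                      0, w / 2)$value
  expect_equal(oracle, 2.2527, tolerance = 1e-4)
  expect_equal(rt$t_front, oracle, tolerance = 0.03)
  expect_equal(rt$t_back, oracle, tolerance = 0.03)
})

test_that("a receding pulse never yields residence intervals", {
  sp <- tracer_species()
  f <- triangular_pulse(center = 20, u = 2, w = 13)   # moving away
  cfg <- sim_config(sp, f, t_end = 10, theta0 = 0)
  rt <- residence_times(simulate_trajectory(cfg))
  expect_equal(nrow(rt), 0L)
})

test_that("residence times over all passages conserve total in-pulse time", {
  sp <- species_preset("small")
  f <- pulse_train(center = -11.5, u = 2, w = 13, n_pulses = 3, gap = 4)
  cfg <- sim_config(sp, f, t_end = 60, seed = 8, theta0 = "uniform")
  tr <- simulate_trajectory(cfg)
  rt <- residence_times(tr)
  dt_s <- attr(tr, "dt") * attr(tr, "save_every")
  expect_equal(sum(rt$t_front) + sum(rt$t_back),
               dt_s * sum(tr$intensity > 0))
})

test_that("orientation histograms normalize and detect (non)uniformity", {
  sp <- species_preset("small")
  f <- uniform_field(0)
  # delta at theta = pi mixing under fast rotational diffusion
  spfast <- particle_species(sigma = 3.25, v_p_max = 1e-9, D_r = 0.5,
                             tau = 3.3, name = "fast")
  cfg <- sim_config(spfast, f, t_end = 20, theta0 = pi)
  ens <- simulate_ensemble(cfg, 120, seed_base = 2)
  od <- orientation_distribution(ens, sample_times = c(0, 20))
  h0 <- od$histogram[od$histogram$time == 0, ]
  width <- 2 * pi / nrow(h0)
  expect_equal(sum(h0$density) * width, 1)
  expect_equal(sum(h0$prob), 1)
  expect_equal(sum(h0$prob > 0), 1L)       # all mass in the theta = pi bin
  u <- od$uniformity
  expect_lt(u$p_value[u$time == 0], 0.01)  # delta: clearly non-uniform
  # after t >> 1/D_r the delta has decorrelated to uniform
  expect_gt(u$p_value[u$time == 20], 0.01)
  expect_error(orientation_distribution(ens, 50), "span")
})

test_that("drift fit recovers exact slopes and flags unusable windows", {
  tr <- structure(data.frame(t = 0:100, x = 3 + 0.5 * (0:100), y = 0,
                             theta = 0, intensity = 0, v_p = 0),
                  class = c("ap_trajectory", "data.frame"))
  fit <- suppressWarnings(mean_drift_velocity(tr))  # exact fit: zero residuals
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 3)
  expect_equal(fit$r_squared, 1)
  expect_error(mean_drift_velocity(tr, window = c(0, 0.5)), "window")
  f <- pulse_train(center = 0, u = 1, w = 13, n_pulses = 5, gap = 50)
  expect_error(mean_drift_velocity(tr, window = c(0, 100), field = f),
               "window too short")
  # pure Brownian motion (D_t = 0.07 um^2/s) drifts far slower than any
  # pulse-driven transport; for BM over [0, T] the fitted slope has
  # s.d. sqrt(12 D_t / T) ~ 0.065 here
  sp <- species_preset("small")
  slopes <- vapply(31:36, function(s) {
    cfg <- sim_config(sp, uniform_field(0), t_end = 200, seed = s,
                      theta0 = 0)
    mean_drift_velocity(simulate_trajectory(cfg))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 4 * sqrt(12 * sp$D_t / 200) / sqrt(6))
})

test_that("sorting metrics: identical ensembles overlap fully, shifts set the gap", {
  sp <- species_preset("small")
  f <- triangular_pulse(center = -11.5, u = 2, w = 13)
  cfg <- sim_config(sp, f, t_end = 20, theta0 = "uniform")
  ens <- simulate_ensemble(cfg, 20, seed_base = 6)
  s_same <- sorting_summary(ens, ens, times = 20)
  expect_equal(s_same$metrics$gap, 0)
  expect_equal(s_same$metrics$overlap, 1)
  # add +10 um of extra displacement to every trajectory (a ramp, so the
  # start point is unchanged and the time-20 displacement shifts by +10)
  ens_shift <- ens
  ens_shift$trajectories <- lapply(ens$trajectories, function(tr) {
    tr2 <- tr
    tr2$x <- tr$x + seq(0, 10, length.out = nrow(tr))
    tr2
  })
  s_shift <- sorting_summary(ens, ens_shift, times = 20)
  expect_equal(s_shift$metrics$gap, 10, tolerance = 1e-9)
  expect_lt(s_shift$metrics$overlap, 1)
})
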
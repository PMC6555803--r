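test_that("deterministic limit advances x by v_p * dt per step", {
  sp <- noise_free("small")
  f <- uniform_field(0.625)          # v_p = v_p_max everywhere, no torque
  cfg <- sim_config(sp, f, t_end = 1, dt = 0.01, theta0 = 0, save_every = 1)
  tr <- simulate_trajectory(cfg)
  expect_equal(tr$x, 2 * tr$t, tolerance = 1e-6)
  expect_equal(tr$y, rep(0, nrow(tr)), tolerance = 1e-6)
  expect_equal(tr$v_p, rep(2, nrow(tr)))
})

test_that("time steps violating the stability bound are rejected", {
  sp <- species_preset("small")      # omega_max ~1.6 -> bound ~0.062 s
  f <- uniform_field(0.625)
  expect_error(sim_config(sp, f, t_end = 1, dt = 0.1), "stability bound")
  expect_silent(sim_config(sp, f, t_end = 1, dt = 0.05))
})

test_that("noise-free alignment on one slope follows the tanh closed form", {
  sp <- noise_free("small", v_p_max = 1e-9)   # rotate in place
  f <- static_triangle(center = 0, w = 200)   # particle sits on back slope
  phi0 <- 2.8
  om <- sp$omega_max
  cfg <- sim_config(sp, f, t_end = 4, dt = 1e-3, x0 = -50, theta0 = phi0,
                    save_every = 10)
  tr <- simulate_trajectory(cfg)
  t_bar <- -atanh(cos(phi0)) / om
  expect_equal(tr$theta, reorientation_closed_form(om, t_bar, tr$t),
               tolerance = 5e-3)
})

test_that("passive displacement increments have variance 2 D_t dt", {
  sp <- species_preset("small")      # D_t = 0.0704; v_p = 0 in darkness
  f <- uniform_field(0)
  cfg <- sim_config(sp, f, t_end = 100, dt = 0.01, seed = 4, theta0 = 0,
                    save_every = 1)
  tr <- simulate_trajectory(cfg)
  n <- nrow(tr) - 1
  v <- var(diff(tr$x))
  target <- 2 * sp$D_t * 0.01
  se <- target * sqrt(2 / (n - 1))
  expect_lt(abs(v - target), 5 * se)
  expect_equal(tr$v_p, rep(0, n + 1))
})

test_that("mirrored field, orientation and noise give the mirror trajectory", {
  sp <- species_preset("small")
  f <- triangular_pulse(center = -11.5, u = 2, w = 13)
  fm <- triangular_pulse(center = 11.5, u = -2, w = 13)
  th0 <- 0.7
  cfg <- sim_config(sp, f, t_end = 20, dt = 0.01, theta0 = th0)
  set.seed(99)
  noise <- matrix(rnorm(cfg$n_steps * 3), cfg$n_steps, 3)
  tr <- simulate_trajectory(cfg, noise = noise)
  cfg_m <- sim_config(sp, fm, t_end = 20, dt = 0.01, theta0 = pi - th0)
  noise_m <- noise %*% diag(c(-1, 1, -1))
  tr_m <- simulate_trajectory(cfg_m, noise = noise_m)
  expect_equal(tr_m$x, -tr$x, tolerance = 1e-10)
  expect_equal(tr_m$y, tr$y, tolerance = 1e-10)
  # orientations mirror: theta' = pi - theta (compare on the circle)
  expect_equal(cos(tr_m$theta), -cos(tr$theta), tolerance = 1e-10)
  expect_equal(sin(tr_m$theta), sin(tr$theta), tolerance = 1e-10)
})

test_that("trajectories are bit-reproducible and ensembles derive seeds", {
  sp <- species_preset("small")
  f <- triangular_pulse(center = -11.5, u = 2, w = 13)
  cfg <- sim_config(sp, f, t_end = 10, seed = 21, theta0 = "uniform")
  expect_identical(simulate_trajectory(cfg), simulate_trajectory(cfg))
  ens1 <- simulate_ensemble(cfg, 3, seed_base = 21)
  ens2 <- simulate_ensemble(cfg, 3, seed_base = 21)
  expect_identical(ens1$info, ens2$info)
  # a one-replicate ensemble reduces to simulate_trajectory
  one <- simulate_ensemble(cfg, 1, seed_base = 21)
  tr <- simulate_trajectory(cfg)
  expect_identical(one$trajectories[[1]], tr)
  expect_equal(one$info$x_f, tr$x[nrow(tr)])
})

test_that("free active motion matches the 2-D ABP mean-squared displacement", {
  # MSD(t) = 4 D_t t + (2 v^2 / D_r^2)(D_r t + exp(-D_r t) - 1)
  sp <- particle_species(sigma = 3.25, v_p_max = 2, D_r = 0.2, D_t = 0.05,
                         tau = 2, name = "abp")
  f <- uniform_field(0.625)
  cfg <- sim_config(sp, f, t_end = 20, dt = 0.01, theta0 = "uniform")
  n <- 150
  ens <- simulate_ensemble(cfg, n, seed_base = 5)
  tg <- ens$trajectories[[1]]$t
  for (lag in c(0.5, 2, 6, 20)) {
    i <- which.min(abs(tg - lag))
    sq <- vapply(ens$trajectories, function(tr)
      (tr$x[i] - tr$x[1])^2 + (tr$y[i] - tr$y[1])^2, numeric(1))
    msd_th <- 4 * sp$D_t * lag +
      (2 * sp$v_p_max^2 / sp$D_r^2) * (sp$D_r * lag + exp(-sp$D_r * lag) - 1)
    se <- sd(sq) / sqrt(n)
    expect_lt(abs(mean(sq) - msd_th), 3 * se)
  }
})

test_that("ensemble standard error scales like 1/sqrt(n)", {
  sp <- species_preset("small")
  f <- uniform_field(0.625)
  cfg <- sim_config(sp, f, t_end = 5, theta0 = "uniform")
  se_of <- function(n, sb) {
    ens <- simulate_ensemble(cfg, n, seed_base = sb,
                             keep_trajectories = FALSE)
    sd(ens$info$x_f - ens$info$x0) / sqrt(n)
  }
  se25 <- se_of(25, 1)
  se100 <- se_of(100, 100)
  se400 <- se_of(400, 300)
  expect_gt(se25 / se400, 2)     # nominal ratio 4
  expect_lt(se25 / se400, 8)
  expect_gt(se25 / se100, 1.1)   # nominal ratio 2
  expect_lt(se25 / se100, 4)
})

test_that("trajectories stay finite with wrapped orientations", {
  set.seed(11)
  for (i in 1:5) {
    sp <- particle_species(sigma = runif(1, 2, 6),
                           v_p_max = runif(1, 0.5, 5),
                           D_r = runif(1, 0.005, 0.5),
                           tau = runif(1, 0.5, 5))
    f <- pulse_train(center = runif(1, -30, -10), u = runif(1, 0.5, 5),
                     w = runif(1, 5, 25), n_pulses = sample(1:3, 1),
                     gap = runif(1, 0, 10))
    cfg <- sim_config(sp, f, t_end = 30, dt = 0.01, seed = i,
                      theta0 = "uniform")
    tr <- simulate_trajectory(cfg)
    expect_true(all(is.finite(as.matrix(tr))))
    expect_true(all(tr$theta > -pi & tr$theta <= pi))
    expect_true(all(diff(tr$t) > 0))
  }
})
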
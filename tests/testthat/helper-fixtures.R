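# Shared fixtures: species variants used across tests.

# effectively noise-free variant of a preset (validator requires > 0)
noise_free <- function(base = "small", ...) {
  species_preset(base, D_t = 1e-15, D_r = 1e-15, ...)
}

# an (almost) motionless tracer: negligible propulsion and noise, so the
# pulse sweeps over a fixed point
tracer_species <- function() {
  particle_species(sigma = 3.25, v_p_max = 1e-9, D_r = 1e-15, D_t = 1e-15,
                   tau = 3.3, name = "tracer")
}

# build an ap_ensemble by hand from displacement values (for observable
# arithmetic tests that do not need dynamics)
fake_ensemble <- function(displacements, theta0 = NULL) {
  n <- length(displacements)
  if (is.null(theta0)) theta0 <- rep(0, n)
  structure(list(
    info = data.frame(rep = seq_len(n), seed = seq_len(n),
                      theta0 = theta0, x0 = 0, x_f = displacements,
                      y_f = 0, theta_f = theta0),
    trajectories = NULL, config = NULL, seed_base = 1L),
    class = "ap_ensemble")
}
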
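#' Load a run configuration
#'
#' Reads a YAML run configuration, validates it against the schema below,
#' fills defaults, and builds the corresponding package objects. Unknown
#' keys are rejected with a field-level message. All quantities use the
#' package's fixed units (um, s, uW/um^2, rad).
#'
#' ```yaml
#' seed: 1
#' species:                 # preset name plus optional overrides
#'   preset: small          # or full particle_species() arguments
#'   v_p_max: 2.0
#' field:
#'   type: pulse            # pulse | train | static | uniform
#'   u: 2.0
#'   w: 13.0                # or w_over_sigma (multiples of species sigma)
#'   I_max: 0.625
#'   n_pulses: 10           # train only
#'   gap: 5.0               # train only
#'   center: -11.5
#'   baseline: 0
#'   I: 0.625               # uniform only
#' dynamics:
#'   dt: 0.01
#'   t_end: 100
#'   save_every: 10
#'   x0: 0
#'   y0: 0
#'   theta0: uniform        # number | uniform | {center: 3.14, halfwidth: 0.2}
#' protocol:
#'   name: single_pulse_sweep
#'   n_reps: 25
#'   args: {}
#' output:
#'   dir: results
#' ```
#'
#' @param path Path to a YAML file.
#' @return An `ap_run_config`: list with `species`, `field`, `dynamics`,
#'   `protocol`, `output`, `seed`, and `raw` (the normalized configuration
#'   list, round-trippable through [save_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' Build a run configuration from a list
#'
#' @param raw A list following the schema in [load_config()].
#' @return An `ap_run_config`.
#' @export
as_run_config <- function(raw) {
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)
  check_keys(raw, c("seed", "species", "field", "dynamics", "protocol",
                    "output"), "top level")
  seed <- as.integer(raw$seed %||% 1L)

  sp_block <- raw$species %||% list(preset = "small")
  check_keys(sp_block,
             c("preset", "sigma", "v_p_max", "D_r", "D_t", "tau",
               "omega_max", "phi_max", "I_ref", "grad_saturation", "name"),
             "species")
  species <- config_species(sp_block)

  field <- NULL
  if (!is.null(raw$field)) {
    check_keys(raw$field,
               c("type", "u", "w", "w_over_sigma", "I_max", "n_pulses",
                 "gap", "center", "baseline", "I"), "field")
    field <- config_field(raw$field, species)
  }

  dyn <- raw$dynamics %||% list()
  check_keys(dyn, c("dt", "t_end", "save_every", "x0", "y0", "theta0"),
             "dynamics")
  dyn <- list(dt = dyn$dt %||% 0.01, t_end = dyn$t_end %||% 100,
              save_every = dyn$save_every,
              x0 = dyn$x0 %||% 0, y0 = dyn$y0 %||% 0,
              theta0 = config_theta0(dyn$theta0 %||% "uniform"))

  proto <- NULL
  if (!is.null(raw$protocol)) {
    check_keys(raw$protocol, c("name", "n_reps", "args"), "protocol")
    if (is.null(raw$protocol$name))
      stop("config field protocol.name is required", call. = FALSE)
    proto <- list(name = raw$protocol$name,
                  n_reps = raw$protocol$n_reps %||% 50,
                  args = raw$protocol$args %||% list())
  }

  out_block <- raw$output %||% list()
  check_keys(out_block, c("dir"), "output")

  structure(
    list(species = species, field = field, dynamics = dyn,
         protocol = proto, output = list(dir = out_block$dir %||% "."),
         seed = seed, raw = normalize_raw(raw)),
    class = "ap_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(block, allowed, where) {
  if (is.null(block)) return(invisible())
  if (!is.list(block))
    stop(sprintf("config block '%s' must be a mapping", where),
         call. = FALSE)
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop(sprintf("unknown config key%s in %s: %s",
                 if (length(bad) > 1L) "s" else "", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible()
}

config_species <- function(block) {
  preset <- block$preset
  args <- block[setdiff(names(block), "preset")]
  tryCatch({
    if (!is.null(preset)) do.call(species_preset, c(list(preset), args))
    else do.call(particle_species, args)
  }, error = function(e)
    stop(sprintf("config field species: %s", conditionMessage(e)),
         call. = FALSE))
}

config_field <- function(block, species) {
  type <- block$type %||% "pulse"
  if (!is.null(block$w_over_sigma) && is.null(block$w))
    block$w <- block$w_over_sigma * species$sigma
  err <- function(e)
    stop(sprintf("config field field: %s", conditionMessage(e)),
         call. = FALSE)
  tryCatch(switch(type,
    pulse = triangular_pulse(center = block$center %||% 0,
                             u = block$u %||% 0, w = block$w,
                             I_max = block$I_max %||% 0.625,
                             baseline = block$baseline %||% 0),
    train = pulse_train(center = block$center %||% 0, u = block$u,
                        w = block$w, I_max = block$I_max %||% 0.625,
                        n_pulses = block$n_pulses %||% 1L,
                        gap = block$gap %||% 0,
                        baseline = block$baseline %||% 0),
    static = static_triangle(center = block$center %||% 0, w = block$w,
                             I_max = block$I_max %||% 0.625,
                             baseline = block$baseline %||% 0),
    uniform = uniform_field(block$I %||% block$I_max %||% 0.625),
    stop(sprintf("unknown field type '%s'", type), call. = FALSE)),
    error = err)
}

config_theta0 <- function(x) {
  if (is.list(x)) {
    check_keys(x, c("center", "halfwidth"), "dynamics.theta0")
    return(theta0_bin(x$center, x$halfwidth %||% 0.2))
  }
  as_theta0_spec(x)
}

# canonical ordering + defaults so that save -> load round-trips exactly
normalize_raw <- function(raw) {
  if (is.null(raw$seed)) raw$seed <- 1L
  keys <- c("seed", "species", "field", "dynamics", "protocol", "output")
  raw[intersect(keys, names(raw))]
}

#' Save a run configuration to YAML
#'
#' Writes the normalized configuration; `load_config(save_config(cfg))`
#' reproduces `cfg`.
#'
#' @param config An `ap_run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "ap_run_config"))
  writeLines(yaml::as.yaml(config$raw, precision = 15L), path)
  invisible(path)
}

#' Short content hash of a run configuration
#'
#' FNV-1a (32-bit) hash of the canonical JSON serialization of the
#' normalized configuration; used to tag output artifacts so they can be
#' matched to the exact configuration that produced them.
#'
#' @param config An `ap_run_config` (or any list).
#' @return An 8-character hex string.
#' @export
config_hash <- function(config) {
  raw_list <- if (inherits(config, "ap_run_config")) config$raw else config
  s <- jsonlite::toJSON(raw_list, auto_unbox = TRUE, digits = NA)
  fnv1a32(charToRaw(as.character(s)))
}

fnv1a32 <- function(bytes) {
  h <- 2166136261
  prime <- 16777619
  two32 <- 2^32
  for (b in as.integer(bytes)) {
    # xor on the low 32 bits, in double arithmetic (values exceed int range)
    h <- xor32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% two32
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

xor32 <- function(a, b) {
  # bitwXor for doubles holding 32-bit unsigned values
  r <- 0
  p <- 1
  for (i in 1:32) {
    ab <- a %% 2
    bb <- b %% 2
    r <- r + p * ((ab + bb) %% 2)
    a <- (a - ab) / 2
    b <- (b - bb) / 2
    p <- p * 2
  }
  r
}

#' Write / read a trajectory as CSV
#'
#' Plain tabular text with columns `t, x, y, theta, intensity, v_p`. A
#' sidecar JSON manifest (same path with extension `.json`) records the
#' seed, sampling interval, initial orientation, field and species
#' parameters, the config hash when available, and a small summary block.
#'
#' @param trajectory An `ap_trajectory`.
#' @param path CSV output path.
#' @param config_hash Optional hash string to embed in the manifest.
#' @return `path`, invisibly (`write_trajectory`); a data frame
#'   (`read_trajectory`).
#' @export
write_trajectory <- function(trajectory, path, config_hash = NULL) {
  stopifnot(inherits(trajectory, "ap_trajectory"))
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  manifest <- list(
    seed = attr(trajectory, "seed"),
    dt = attr(trajectory, "dt"),
    save_every = attr(trajectory, "save_every"),
    theta0 = attr(trajectory, "theta0"),
    species = unclass(attr(trajectory, "species")),
    field = unclass(attr(trajectory, "field")),
    config_hash = config_hash,
    summary = trajectory_summary(trajectory))
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

manifest_path <- function(path) sub("\\.[^.]*$", "", path) |>
  paste0(".json")

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tr <- read.csv(path)
  class(tr) <- c("ap_trajectory", "data.frame")
  mp <- manifest_path(path)
  if (file.exists(mp)) {
    m <- jsonlite::read_json(mp, simplifyVector = TRUE)
    attr(tr, "seed") <- m$seed
    attr(tr, "dt") <- m$dt
    attr(tr, "save_every") <- m$save_every
    attr(tr, "theta0") <- m$theta0
  }
  tr
}

#' Summary statistics of a single trajectory
#'
#' Displacement, path duration, mean propulsion speed and drift slope --
#' the quantities the `analyze` CLI subcommand recomputes from a stored
#' trajectory.
#'
#' @param trajectory A trajectory data frame with `t, x, y, v_p`.
#' @return A named list.
#' @export
trajectory_summary <- function(trajectory) {
  n <- nrow(trajectory)
  list(t_end = trajectory$t[n],
       displacement_x = trajectory$x[n] - trajectory$x[1],
       displacement_y = trajectory$y[n] - trajectory$y[1],
       mean_v_p = mean(trajectory$v_p),
       drift_slope = mean_drift_velocity(trajectory)$slope)
}
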
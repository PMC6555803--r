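#' Triangular traveling light pulse
#'
#' A one-dimensional triangular intensity profile of full base width `w` and
#' peak intensity `I_max`, translating rigidly at speed `u` along x. The
#' profile consists of two identical linear segments with constant and
#' opposite gradients; intensity vanishes outside `|x - x_c(t)| >= w/2`.
#'
#' @param center Pulse center position at t = 0 (um).
#' @param u Pulse speed (um/s, signed; positive = toward +x).
#' @param w Full base width (um); must be > 0.
#' @param I_max Peak intensity (uW/um^2); must be > 0. Default 0.625.
#' @param baseline Ambient intensity outside pulse support (uW/um^2),
#'   default 0 (the particle is passive there).
#' @return A `light_field` object.
#' @seealso [pulse_train()], [static_triangle()], [uniform_field()],
#'   [intensity_at()], [gradient_at()]
#' @examples
#' p <- triangular_pulse(center = 0, u = 2, w = 13)
#' intensity_at(p, x = 0, t = 0)    # peak: 0.625
#' gradient_at(p, x = 3, t = 0)     # front slope: -2 * 0.625 / 13
#' @export
triangular_pulse <- function(center = 0, u = 0, w, I_max = 0.625,
                             baseline = 0) {
  pulse_train(center = center, u = u, w = w, I_max = I_max,
              n_pulses = 1L, gap = 0, baseline = baseline)
}

#' Periodic train of traveling triangular pulses
#'
#' A sequence of `n_pulses` identical triangular pulses. `gap` is the
#' quiescent time interval between the trailing edge of one pulse and the
#' leading edge of the next, as seen at a fixed point; the spatial
#' center-to-center spacing is therefore `w + |u| * gap` and consecutive
#' pulses never overlap. The pulse with index 1 leads (reaches a fixed point
#' first); later pulses trail behind it opposite to the propagation
#' direction.
#'
#' @inheritParams triangular_pulse
#' @param n_pulses Number of pulses (>= 1).
#' @param gap Quiescent interval T between consecutive pulses (s, >= 0).
#' @return A `light_field` object.
#' @export
pulse_train <- function(center = 0, u, w, I_max = 0.625, n_pulses, gap,
                        baseline = 0) {
  n_pulses <- as.integer(n_pulses)
  stopifnot(is.numeric(w), length(w) == 1L, is.numeric(I_max),
            length(I_max) == 1L, length(u) == 1L, length(center) == 1L,
            length(gap) == 1L, length(baseline) == 1L)
  if (!is.finite(w) || w <= 0) stop("field: w must be > 0", call. = FALSE)
  if (!is.finite(I_max) || I_max <= 0)
    stop("field: I_max must be > 0", call. = FALSE)
  if (n_pulses < 1L) stop("field: n_pulses must be >= 1", call. = FALSE)
  if (!is.finite(gap) || gap < 0) stop("field: gap must be >= 0", call. = FALSE)
  if (baseline < 0) stop("field: baseline must be >= 0", call. = FALSE)
  if (n_pulses > 1L && u == 0)
    stop("field: a multi-pulse train requires u != 0", call. = FALSE)
  structure(
    list(type = "train", center = center, u = u, w = w, I_max = I_max,
         n_pulses = n_pulses, gap = gap, baseline = baseline),
    class = "light_field")
}

#' Static triangular intensity profile (motility trap)
#'
#' Convenience constructor for a non-traveling triangular profile, i.e. a
#' [triangular_pulse()] with u = 0.
#'
#' @inheritParams triangular_pulse
#' @return A `light_field` object.
#' @export
static_triangle <- function(center = 0, w, I_max = 0.625, baseline = 0) {
  triangular_pulse(center = center, u = 0, w = w, I_max = I_max,
                   baseline = baseline)
}

#' Spatially uniform light field
#'
#' Constant intensity everywhere, zero gradient (no aligning torque). Used
#' for free active-Brownian-particle limits and calibration checks.
#'
#' @param I Intensity level (uW/um^2, >= 0).
#' @return A `light_field` object.
#' @export
uniform_field <- function(I) {
  stopifnot(is.numeric(I), length(I) == 1L, is.finite(I), I >= 0)
  structure(list(type = "uniform", I_max = I), class = "light_field")
}

#' @export
print.light_field <- function(x, ...) {
  if (x$type == "uniform") {
    cat(sprintf("<light_field> uniform, I = %g uW/um^2\n", x$I_max))
  } else {
    cat(sprintf(
      "<light_field> %s: w = %g um, I_max = %g uW/um^2, u = %g um/s",
      if (x$n_pulses > 1L) sprintf("train of %d pulses", x$n_pulses)
      else if (x$u == 0) "static triangle" else "traveling pulse",
      x$w, x$I_max, x$u))
    if (x$n_pulses > 1L)
      cat(sprintf(", gap T = %g s (spacing %g um)", x$gap, pulse_spacing(x)))
    cat(sprintf(", center(0) = %g um\n", x$center))
  }
  invisible(x)
}

#' Center-to-center spacing of a pulse train
#'
#' Equals `w + |u| * gap`, so that `gap` is the quiescent interval at a
#' fixed point.
#'
#' @param field A `light_field` of type train.
#' @return Spacing (um).
#' @export
pulse_spacing <- function(field) {
  stopifnot(inherits(field, "light_field"), field$type == "train")
  field$w + abs(field$u) * field$gap
}

#' Center position of one pulse at time t
#'
#' @param field A `light_field` (train type).
#' @param t Time(s) (s); vectorized.
#' @param pulse Pulse index (1 = leading pulse).
#' @return Center position(s) (um): `center - dir * spacing * (pulse - 1) +
#'   u * t` with `dir = sign(u)` (+1 for a static profile).
#' @export
pulse_center <- function(field, t, pulse = 1L) {
  stopifnot(inherits(field, "light_field"), field$type == "train")
  pulse <- as.integer(pulse)
  if (pulse < 1L || pulse > field$n_pulses)
    stop("pulse index out of range", call. = FALSE)
  dir <- if (field$u >= 0) 1 else -1
  field$center - dir * pulse_spacing(field) * (pulse - 1L) + field$u * t
}

field_eval <- function(field, x, t) {
  n <- max(length(x), length(t))
  x <- rep_len(x, n)
  t <- rep_len(t, n)
  if (field$type == "uniform")
    return(list(I = rep.int(field$I_max, n), g = numeric(n)))
  I <- rep.int(field$baseline, n)
  g <- numeric(n)
  slope <- 2 * field$I_max / field$w
  for (k in seq_len(field$n_pulses)) {
    d <- x - pulse_center(field, t, k)
    inside <- abs(d) < field$w / 2
    if (any(inside)) {
      I[inside] <- I[inside] + field$I_max * (1 - 2 * abs(d[inside]) / field$w)
      g[inside & d > 0] <- -slope
      g[inside & d < 0] <- slope
    }
  }
  list(I = I, g = g)
}

#' Light intensity at a position and time
#'
#' For triangular pulses: `I_max * (1 - 2|x - x_c(t)|/w)` where positive
#' (plus any baseline), 0 outside the support; for trains, the sum over the
#' (non-overlapping) pulses.
#'
#' @param field A `light_field`.
#' @param x Position(s) (um).
#' @param t Time(s) (s).
#' @return Intensity (uW/um^2), vectorized over `x`/`t`.
#' @export
intensity_at <- function(field, x, t = 0) {
  stopifnot(inherits(field, "light_field"))
  field_eval(field, x, t)$I
}

#' Signed intensity gradient at a position and time
#'
#' `+2 I_max / w` on the back slope (x < x_c), `-2 I_max / w` on the front
#' slope (x > x_c), and 0 outside the support, exactly at the apex, and at
#' the support edges (measure-zero convention that keeps the torque
#' defined everywhere).
#'
#' @inheritParams intensity_at
#' @return Gradient (uW/um^3), vectorized.
#' @export
gradient_at <- function(field, x, t = 0) {
  stopifnot(inherits(field, "light_field"))
  field_eval(field, x, t)$g
}

# parameters handed to the C++ integrator
field_pars <- function(field) {
  if (field$type == "uniform") {
    list(type = 1L, center = 0, u = 0, w = 1, I_max = field$I_max,
         n_pulses = 1L, gap = 0, baseline = 0)
  } else {
    list(type = 0L, center = field$center, u = field$u, w = field$w,
         I_max = field$I_max, n_pulses = field$n_pulses, gap = field$gap,
         baseline = field$baseline)
  }
}
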
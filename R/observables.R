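#' Ensemble-mean displacement
#'
#' Mean of the final x-displacement `x_f - x_0` over the replicates of an
#' ensemble, optionally restricted to replicates whose initial orientation
#' falls in a bin `theta0 +/- halfwidth`, and optionally truncated at the
#' exit of a finite observation window (emulating a finite field of view:
#' each replicate's displacement is capped at the first crossing of
#' `|x - x_0| >= window`).
#'
#' The ensemble must extend past the time at which the last pulse has fully
#' swept over every particle, so that `x_f` is a post-interaction position.
#'
#' @param ensemble An `ap_ensemble`.
#' @param theta0 Optional bin center (rad); `NULL` uses all replicates.
#' @param halfwidth Bin half-width (rad), default 0.2.
#' @param window Optional observation half-width (um, > 0); requires stored
#'   trajectories.
#' @return A one-row data frame: `mean`, `sd`, `n`, `theta0_bin`, `window`.
#'   An empty bin yields `n = 0` with `NA` statistics (explicitly empty,
#'   not zero).
#' @export
mean_displacement <- function(ensemble, theta0 = NULL, halfwidth = 0.2,
                              window = NULL) {
  stopifnot(inherits(ensemble, "ap_ensemble"))
  info <- ensemble$info
  keep <- rep_len(TRUE, nrow(info))
  if (!is.null(theta0))
    keep <- abs(wrap_angle_r(info$theta0 - theta0)) <= halfwidth
  idx <- which(keep)
  if (length(idx) == 0L)
    return(data.frame(mean = NA_real_, sd = NA_real_, n = 0L,
                      theta0_bin = if (is.null(theta0)) NA_real_ else theta0,
                      window = if (is.null(window)) NA_real_ else window))
  if (is.null(window)) {
    d <- info$x_f[idx] - info$x0[idx]
  } else {
    stopifnot(window > 0)
    if (is.null(ensemble$trajectories))
      stop("window capping requires stored trajectories", call. = FALSE)
    d <- vapply(idx, function(i) {
      tr <- ensemble$trajectories[[i]]
      dx <- tr$x - tr$x[1]
      hit <- which(abs(dx) >= window)
      if (length(hit)) sign(dx[hit[1]]) * window else dx[length(dx)]
    }, numeric(1))
  }
  data.frame(mean = mean(d), sd = if (length(d) > 1L) sd(d) else 0,
             n = length(d),
             theta0_bin = if (is.null(theta0)) NA_real_ else theta0,
             window = if (is.null(window)) NA_real_ else window)
}

#' Residence times on the front and back slopes of each pulse passage
#'
#' Splits each passage of the particle through a pulse into the time spent
#' on the front slope (the side facing the propagation direction, x > x_c
#' for u > 0) and on the back slope. A passage is a maximal contiguous run
#' of samples inside one pulse's support; time is attributed in units of
#' the sampling interval.
#'
#' @param trajectory An `ap_trajectory`.
#' @param field The light field (default: the trajectory's own field).
#' @return A data frame with one row per passage: `passage`, `pulse`
#'   (index within the train), `t_enter`, `t_exit`, `t_front`, `t_back`.
#'   Zero rows if the particle never enters a pulse.
#' @export
residence_times <- function(trajectory, field = attr(trajectory, "field")) {
  stopifnot(inherits(trajectory, "ap_trajectory"),
            inherits(field, "light_field"))
  if (field$type != "train")
    stop("residence times are defined for pulse fields", call. = FALSE)
  t <- trajectory$t
  x <- trajectory$x
  dt_s <- attr(trajectory, "dt") * attr(trajectory, "save_every")
  pulse_idx <- integer(length(t))
  side <- integer(length(t))  # +1 front (toward propagation), -1 back/apex
  dir <- if (field$u >= 0) 1 else -1
  for (k in seq_len(field$n_pulses)) {
    d <- x - pulse_center(field, t, k)
    inside <- abs(d) < field$w / 2 & pulse_idx == 0L
    pulse_idx[inside] <- k
    side[inside] <- ifelse(dir * d[inside] > 0, 1L, -1L)
  }
  r <- rle(pulse_idx)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  inruns <- which(r$values > 0L)
  if (length(inruns) == 0L)
    return(data.frame(passage = integer(), pulse = integer(),
                      t_enter = numeric(), t_exit = numeric(),
                      t_front = numeric(), t_back = numeric()))
  out <- data.frame(passage = seq_along(inruns),
                    pulse = r$values[inruns],
                    t_enter = t[starts[inruns]],
                    t_exit = t[ends[inruns]],
                    t_front = NA_real_, t_back = NA_real_)
  for (j in seq_along(inruns)) {
    sel <- starts[inruns[j]]:ends[inruns[j]]
    out$t_front[j] <- dt_s * sum(side[sel] > 0L)
    out$t_back[j] <- dt_s * sum(side[sel] < 0L)
  }
  out
}

#' Orientation distribution of an ensemble at given times
#'
#' Circular histogram of the particle orientations theta across replicates
#' at each requested sample time, plus a resampling-based uniformity check:
#' the mean resultant length of the observed angles is compared with its
#' null distribution under uniform angles (same n), giving a Monte Carlo
#' p-value (small p = inconsistent with uniform).
#'
#' @param ensemble An `ap_ensemble` with stored trajectories.
#' @param sample_times Times (s) within the trajectory span.
#' @param n_bins Number of histogram bins over (-pi, pi], default 24.
#' @param resamples Monte Carlo resamples for the uniformity null,
#'   default 500.
#' @param resample_seed Seed for the resampling (kept separate from the
#'   simulation seeds), default 1.
#' @return List of class `ap_orientation_dist`: `histogram` (data frame:
#'   time, bin_mid, bin_lo, bin_hi, count, prob, density) and `uniformity`
#'   (data frame: time, n, resultant_length, p_value). Each histogram's
#'   density integrates to 1.
#' @export
orientation_distribution <- function(ensemble, sample_times, n_bins = 24,
                                     resamples = 500, resample_seed = 1) {
  stopifnot(inherits(ensemble, "ap_ensemble"))
  if (is.null(ensemble$trajectories))
    stop("orientation distributions require stored trajectories",
         call. = FALSE)
  t_grid <- ensemble$trajectories[[1]]$t
  if (any(sample_times < min(t_grid) - 1e-9 |
          sample_times > max(t_grid) + 1e-9))
    stop("sample_times outside trajectory span", call. = FALSE)
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  width <- 2 * pi / n_bins
  hist_rows <- vector("list", length(sample_times))
  unif_rows <- vector("list", length(sample_times))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(resample_seed)
  for (j in seq_along(sample_times)) {
    i <- which.min(abs(t_grid - sample_times[j]))
    th <- vapply(ensemble$trajectories, function(tr) tr$theta[i], numeric(1))
    # bins are (lo, hi]; theta is wrapped to (-pi, pi]
    cnt <- tabulate(findInterval(th, breaks, left.open = TRUE,
                                 all.inside = TRUE), nbins = n_bins)
    n <- length(th)
    hist_rows[[j]] <- data.frame(
      time = sample_times[j],
      bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
      bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
      count = cnt, prob = cnt / n, density = cnt / n / width)
    R_obs <- resultant_length(th)
    R_null <- vapply(seq_len(resamples), function(b)
      resultant_length(runif(n, -pi, pi)), numeric(1))
    unif_rows[[j]] <- data.frame(
      time = sample_times[j], n = n, resultant_length = R_obs,
      p_value = (1 + sum(R_null >= R_obs)) / (1 + resamples))
  }
  structure(list(histogram = do.call(rbind, hist_rows),
                 uniformity = do.call(rbind, unif_rows)),
            class = "ap_orientation_dist")
}

resultant_length <- function(theta) {
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

#' Mean drift velocity by linear fit
#'
#' Least-squares slope of x(t) over a fit window; the steady-state drift
#' velocity of a particle carried by a pulse train. When `field` is given,
#' the window must cover at least three pulse periods `w/|u| + T` so the
#' fit averages over the train's cycle.
#'
#' @param trajectory An `ap_trajectory` (or any data frame with `t`, `x`).
#' @param window Length-2 numeric `c(t_min, t_max)`; default the full span.
#' @param field Optional `light_field` used to validate the window length.
#' @return A one-row data frame: `slope` (um/s), `intercept`, `r_squared`,
#'   `slope_se`, `t_min`, `t_max`, `n`.
#' @export
mean_drift_velocity <- function(trajectory, window = NULL, field = NULL) {
  t <- trajectory$t
  if (is.null(window)) window <- range(t)
  stopifnot(length(window) == 2L, window[2] > window[1])
  if (window[1] < min(t) - 1e-9 || window[2] > max(t) + 1e-9)
    stop("fit window outside trajectory span", call. = FALSE)
  if (!is.null(field) && field$type == "train" && field$u != 0) {
    period <- field$w / abs(field$u) + field$gap
    if (diff(window) < 3 * period)
      stop(sprintf(
        "window too short: %g s < 3 pulse periods (%g s)",
        diff(window), 3 * period), call. = FALSE)
  }
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 3L)
    stop("window too short: need at least 3 samples", call. = FALSE)
  fit <- lm(x ~ t, data = data.frame(t = t[sel], x = trajectory$x[sel]))
  sm <- summary(fit)
  data.frame(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             r_squared = sm$r.squared,
             slope_se = sm$coefficients[2, 2],
             t_min = window[1], t_max = window[2], n = sum(sel))
}

#' Sorting summary for two co-driven species
#'
#' Displacement distributions P(x - x_0) of two ensembles (e.g. small and
#' big particles sharing one pulse train) at requested times, with the mean
#' gap (species B minus species A) and the overlap coefficient of the two
#' histograms (1 = identical, 0 = disjoint).
#'
#' @param ensemble_a,ensemble_b `ap_ensemble`s with stored trajectories on
#'   a common time base.
#' @param times Times (s) at which to evaluate.
#' @param n_bins Histogram bins, default 30.
#' @param labels Species labels, default `c("a", "b")`.
#' @return List of class `ap_sorting_summary`: `distributions` (data frame:
#'   species, time, bin_mid, count, prob, density) and `metrics` (data
#'   frame: time, mean_a, mean_b, gap, overlap).
#' @export
sorting_summary <- function(ensemble_a, ensemble_b, times, n_bins = 30,
                            labels = c("a", "b")) {
  stopifnot(inherits(ensemble_a, "ap_ensemble"),
            inherits(ensemble_b, "ap_ensemble"))
  if (is.null(ensemble_a$trajectories) || is.null(ensemble_b$trajectories))
    stop("sorting summaries require stored trajectories", call. = FALSE)
  disp_at <- function(ens, tt) {
    tg <- ens$trajectories[[1]]$t
    i <- which.min(abs(tg - tt))
    vapply(ens$trajectories, function(tr) tr$x[i] - tr$x[1], numeric(1))
  }
  dist_rows <- list()
  met_rows <- list()
  for (tt in times) {
    da <- disp_at(ensemble_a, tt)
    db <- disp_at(ensemble_b, tt)
    rng <- range(c(da, db))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1L)
    width <- diff(breaks[1:2])
    pa <- tabulate(findInterval(da, breaks, all.inside = TRUE),
                   nbins = n_bins) / length(da)
    pb <- tabulate(findInterval(db, breaks, all.inside = TRUE),
                   nbins = n_bins) / length(db)
    mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
    dist_rows[[length(dist_rows) + 1L]] <- data.frame(
      species = rep(labels, each = n_bins), time = tt,
      bin_mid = c(mid, mid),
      count = c(pa * length(da), pb * length(db)),
      prob = c(pa, pb), density = c(pa, pb) / width)
    met_rows[[length(met_rows) + 1L]] <- data.frame(
      time = tt, mean_a = mean(da), mean_b = mean(db),
      gap = mean(db) - mean(da), overlap = sum(pmin(pa, pb)))
  }
  structure(list(distributions = do.call(rbind, dist_rows),
                 metrics = do.call(rbind, met_rows),
                 labels = labels),
            class = "ap_sorting_summary")
}
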
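#' Sensor noise model
#'
#' Noise applied to the agent's idiothetic senses.  The compass reading gets
#' bounded white Gaussian noise (`heading_sd`; a compass is an absolute
#' reference, so its error never accumulates) plus a systematic
#' heading-dependent deviation of RMS amplitude `heading_sys_amp` — the
#' classic compass deviation curve (hard/soft-iron distortion, and the
#' angular discretization of the heading code), drawn once per run as a
#' two-harmonic Fourier series in heading.  Because the deviation is the
#' same every time a heading recurs, its contributions to the integrated
#' position add coherently, so position error grows with distance run even
#' though the heading error itself stays bounded — the drift that washes
#' out uncalibrated grid patterns after a few minutes.  Odometric step
#' length gets multiplicative white noise (`step_sd_fraction`) plus a
#' slowly drifting scale bias (random walk, increment `step_bias_sd`).
#'
#' @param heading_sd white compass noise SD in radians (default 1 degree).
#' @param heading_sys_amp RMS amplitude of the systematic heading deviation
#'   in radians (default 1 degree).
#' @param step_sd_fraction multiplicative step-length noise SD (default 2\%).
#' @param step_bias_sd per-step SD of the odometry scale-bias random walk
#'   (dimensionless, default 3e-4).
#' @return an object of class `sensor_noise_model`.
#' @export
sensor_noise_model <- function(heading_sd = pi / 180,
                               heading_sys_amp = pi / 180,
                               step_sd_fraction = 0.02,
                               step_bias_sd = 3e-4) {
  stopifnot(heading_sd >= 0, heading_sys_amp >= 0,
            step_sd_fraction >= 0, step_bias_sd >= 0)
  structure(list(heading_sd = heading_sd, heading_sys_amp = heading_sys_amp,
                 step_sd_fraction = step_sd_fraction,
                 step_bias_sd = step_bias_sd),
            class = "sensor_noise_model")
}

# Draw the per-run systematic compass-deviation function: a two-harmonic
# Fourier series in heading with random phases, scaled to RMS `amp`.
draw_deviation_curve <- function(amp) {
  if (amp <= 0) return(function(h) 0 * h)
  a <- stats::rnorm(2); ph <- stats::runif(2, 0, 2 * pi)
  a <- a / sqrt(sum(a^2) / 2) * amp   # RMS over heading = amp
  function(h) a[1] * cos(h + ph[1]) + a[2] * cos(2 * h + ph[2])
}

#' Noise-free sensors
#' @return a `sensor_noise_model` with all SDs zero.
#' @export
noise_free <- function() sensor_noise_model(0, 0, 0, 0)

new_trajectory <- function(df) {
  stopifnot(all(c("t", "x", "y", "heading", "step_true", "step_meas",
                  "heading_meas", "event") %in% names(df)))
  structure(df, class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x), "samples,",
      sprintf("%.1f s, path length %.1f m\n",
              x$t[nrow(x)] - x$t[1], sum(x$step_true)))
  ev <- table(x$event[x$event != ""])
  if (length(ev)) cat("  events:", paste(names(ev), ev, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Random-walk exploration trajectory
#'
#' Synthesizes a bounded-random-walk exploration path: constant speed, heading
#' performing a Gaussian random walk, with a reflective deflection toward the
#' arena interior whenever the agent comes within `arena$avoid_dist` of a wall
#' (the surrogate for the robot's proximity-sensor avoidance loop).  Measured
#' (noisy) heading and step columns are filled from `noise`.
#'
#' @param arena an `arena_config`.
#' @param n_steps number of steps.
#' @param speed linear speed in m/s (default 0.2).
#' @param dt time step in seconds (default 0.1).
#' @param turn_sd per-step SD of the heading random walk in radians.
#' @param noise a `sensor_noise_model`.
#' @param seed integer RNG seed; identical (config, seed) gives a
#'   bit-identical trajectory.
#' @param start,start_heading initial pose (defaults: arena centroid, 0).
#' @return a `trajectory` data.frame with columns `t, x, y, heading,
#'   step_true, step_meas, heading_meas, event`.
#' @export
generate_random_walk <- function(arena, n_steps, speed = 0.2, dt = 0.1,
                                 turn_sd = 0.15, noise = noise_free(),
                                 seed = 1L, start = NULL,
                                 start_heading = 0) {
  stopifnot(speed > 0, dt > 0, n_steps >= 1)
  set.seed(seed)
  ctr <- polygon_centroid(arena$boundary)
  if (is.null(start)) start <- ctr
  step <- speed * dt
  x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
  hd <- numeric(n_steps + 1)
  x[1] <- start[1]; y[1] <- start[2]; hd[1] <- wrap_angle(start_heading)
  turns <- stats::rnorm(n_steps, 0, turn_sd)
  poly <- arena$boundary
  for (k in seq_len(n_steps)) {
    h <- wrap_angle(hd[k] + turns[k])
    cx <- x[k] + step * cos(h); cy <- y[k] + step * sin(h)
    if (!point_in_polygon(cx, cy, poly) ||
        boundary_distance(cx, cy, poly) < arena$avoid_dist) {
      # deflect toward the interior
      h <- wrap_angle(atan2(ctr[2] - y[k], ctr[1] - x[k]))
      cx <- x[k] + step * cos(h); cy <- y[k] + step * sin(h)
      if (!point_in_polygon(cx, cy, poly)) { cx <- x[k]; cy <- y[k] }
    }
    x[k + 1] <- cx; y[k + 1] <- cy; hd[k + 1] <- h
  }
  traj <- data.frame(t = (0:n_steps) * dt, x = x, y = y, heading = hd,
                     step_true = c(0, sqrt(diff(x)^2 + diff(y)^2)),
                     step_meas = 0, heading_meas = hd,
                     event = "", stringsAsFactors = FALSE)
  apply_sensor_noise(new_trajectory(traj), noise, seed = seed + 1L)
}

#' Apply sensor noise to a trajectory
#'
#' Fills the `heading_meas` and `step_meas` columns: measured heading is the
#' true heading plus the per-run systematic deviation curve plus white
#' compass noise; measured step is the true step scaled by (1 + accumulated
#' scale bias + white noise), clamped at zero (a wheel cannot run backward
#' during a forward command).
#'
#' @param traj a `trajectory`.
#' @param noise a `sensor_noise_model`.
#' @param seed integer RNG seed for the noise sequence.
#' @return the trajectory with measured columns filled.
#' @export
apply_sensor_noise <- function(traj, noise, seed = 1L) {
  set.seed(seed)
  n <- nrow(traj)
  dev <- draw_deviation_curve(noise$heading_sys_amp)
  traj$heading_meas <- wrap_angle(traj$heading + dev(traj$heading) +
                                    stats::rnorm(n, 0, noise$heading_sd))
  sbias <- cumsum(stats::rnorm(n, 0, noise$step_bias_sd))
  traj$step_meas <- pmax(0, traj$step_true *
                           (1 + sbias + stats::rnorm(n, 0, noise$step_sd_fraction)))
  traj
}

#' One-step sensor reading
#'
#' Pure single-step version of the noise model (no bias state): measured
#' heading is the true heading plus wrapped Gaussian noise; measured step is
#' the true step with multiplicative Gaussian noise clamped at zero.
#'
#' @param pose list/vector with a `heading` element (radians).
#' @param true_step true displacement length in metres.
#' @param noise a `sensor_noise_model`.
#' @return list with `heading` and `step`.
#' @export
sense <- function(pose, true_step, noise) {
  list(heading = wrap_angle(pose[["heading"]] +
                              stats::rnorm(1, 0, noise$heading_sd)),
       step = max(0, true_step * (1 + stats::rnorm(1, 0, noise$step_sd_fraction))))
}

#' Kidnap (teleport) the agent
#'
#' Moves the agent's true pose to `new_pose` without generating any odometric
#' or compass signal: the displacement does not appear in `step_true` /
#' `step_meas`, so downstream path integration is blind to the jump.  The
#' sample is tagged with a `kidnap` event.
#'
#' @param traj a `trajectory`.
#' @param at index of the sample at which the jump happens.
#' @param new_pose list/vector with `x`, `y` (and optionally `heading`).
#' @param arena `arena_config` used to validate the target pose.
#' @return the modified trajectory: all samples from `at` on are translated.
#' @export
apply_kidnap <- function(traj, at, new_pose, arena) {
  if (!point_in_polygon(new_pose[["x"]], new_pose[["y"]], arena$boundary))
    stop("kidnap target outside the arena boundary")
  n <- nrow(traj)
  stopifnot(at >= 1, at <= n)
  dx <- new_pose[["x"]] - traj$x[at]
  dy <- new_pose[["y"]] - traj$y[at]
  idx <- at:n
  traj$x[idx] <- traj$x[idx] + dx
  traj$y[idx] <- traj$y[idx] + dy
  traj$event[at] <- trimws(paste(traj$event[at], "kidnap"))
  traj
}

#' Write / read a trajectory as CSV
#'
#' Plain-text interchange format: columns `t, x, y, heading, step_true,
#' step_meas, heading_meas, event` (seconds / metres / radians).
#'
#' @param traj a `trajectory`.
#' @param path file path.
#' @return `read_trajectory_csv` returns a `trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$event[is.na(df$event)] <- ""
  new_trajectory(df)
}
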
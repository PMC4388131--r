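# Config-driven experiment runner: wires environment, path integration,
# grid cells and place cells into the closed sensory-motor loop and runs the
# simulated protocols (exploration +/- periodic homing recalibration,
# place-field parameter sweeps, two-room localization and kidnapping).

#' Experiment presets
#'
#' Returns the documented default configuration for a simulated protocol:
#'
#' * `exp1` — 30 min random exploration, noisy sensors, no recalibration.
#' * `exp2` — as exp1 plus periodic homing recalibration (default 60 s).
#' * `exp4` — 30 min with 1-min recalibration, then 30 min without.
#' * `exp6` — WTA place cell from 3 binary grid layers on a straight
#'   crossing (the three-steps stair).
#' * `exp7` — sweep of discretization factor and grid-cell count over the
#'   generated place field.
#' * `exp8` — two-room path: VPC/PredVPC/MPC traces along the learned path.
#' * `exp9` — generalization: the exp8 bank replayed on parallel paths.
#' * `exp10` — kidnap from the path into the far room.
#' * `exp11` — kidnap from the end of the path back to the start room.
#'
#' @param id one of `"exp1","exp2","exp4","exp6","exp7","exp8","exp9",
#'   "exp10","exp11"`.
#' @param seed integer seed stored in the config.
#' @return an object of class `experiment_config` (a named list; any entry
#'   may be overridden before calling [run_experiment()]).
#' @export
preset <- function(id, seed = 1L) {
  base <- list(
    id = id, seed = as.integer(seed),
    speed = 0.2, dt = 0.1, turn_sd = 0.15,
    noise = sensor_noise_model(),
    pi = list(N = 60, alpha = 0.01, D_max = 1, mode = "signed_projection"),
    grids = list(moduli = c(4, 9, 25), N_E = 60,
                 pairs = list(c(1, 11), c(3, 13), c(5, 15)),
                 diffusion_sigma = 0),
    learning = learning_params(),
    azimuth_sigma = 10 * pi / 180,
    images_per_panorama = 15, landmarks_per_image = 5)
  tworoom <- function(b) {
    b$grids$diffusion_sigma <- 1     # analog grid responses for place cells
    b$noise <- noise_free()
    c(b, list(arena = two_room_arena(), n_places = 19, place_spacing = 1.5))
  }
  cfg <- switch(
    id,
    exp1 = c(base, list(arena = hex_arena(4), duration_s = 1800,
                        recal_period_s = NA_real_)),
    exp2 = c(base, list(arena = hex_arena(4), duration_s = 1800,
                        recal_period_s = 60)),
    exp4 = c(base, list(arena = hex_arena(4), duration_s = 3600,
                        recal_period_s = 60, recal_until_s = 1800)),
    exp6 = c(base, list(line_extent = 3, line_angle = pi / 6,
                        line_step = 0.02)),
    exp7 = c(base, list(line_extent = 6, line_angle = pi / 6,
                        line_step = 0.02,
                        discretizations = c(120, 60, 30),
                        cell_counts = c(12, 48, 192))),
    exp8 = c(tworoom(base), list(training_laps = 3)),
    exp9 = c(tworoom(base), list(training_laps = 3,
                                 path_offsets = c(-0.8, -0.4, 0, 0.4, 0.8))),
    exp10 = c(tworoom(base), list(training_laps = 3,
                                  kidnap_from = 9.75, kidnap_to = 21)),
    exp11 = c(tworoom(base), list(training_laps = 3,
                                  kidnap_from = 27, kidnap_to = 0)),
    stop("unknown experiment id: ", id))
  structure(cfg, class = "experiment_config")
}

#' Protocol arithmetic summary
#'
#' Derived quantities of a protocol: the number of landmarks per visual
#' panorama, the time to cross the arena at the configured speed, and the
#' longest path the agent can run between recalibrations.
#'
#' @param config an `experiment_config`.
#' @return list with `panorama_landmarks`, `arena_diameter_m`,
#'   `traversal_s`, `max_recal_path_m`.
#' @export
protocol_summary <- function(config) {
  diam <- if (!is.null(config$arena)) {
    b <- config$arena$boundary
    max(stats::dist(b))
  } else NA_real_
  list(panorama_landmarks = config$images_per_panorama * config$landmarks_per_image,
       arena_diameter_m = diam,
       traversal_s = diam / config$speed,
       max_recal_path_m = if (is.null(config$recal_period_s) ||
                              is.na(config$recal_period_s)) NA_real_
                          else config$recal_period_s * config$speed)
}

# ---- shared helpers ---------------------------------------------------------

pi_from_config <- function(config, range_m) {
  do.call(pi_field, c(config$pi, list(range_m = range_m)))
}

grids_from_config <- function(config) {
  do.call(grid_population, config$grids)
}

arena_range_m <- function(arena) {
  b <- arena$boundary
  2 * max(stats::dist(b))          # field spans twice the arena diameter
}

# Resample a waypoint polyline at constant arc-length steps.
path_positions <- function(waypoints, step) {
  lens <- sqrt(rowSums(diff(waypoints)^2))
  cum <- c(0, cumsum(lens))
  s <- seq(0, cum[length(cum)], by = step)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, length(lens))
  frac <- (s - cum[i]) / lens[i]
  pos <- waypoints[i, , drop = FALSE] +
    (waypoints[i + 1, , drop = FALSE] - waypoints[i, , drop = FALSE]) * frac
  hd <- atan2(waypoints[i + 1, 2] - waypoints[i, 2],
              waypoints[i + 1, 1] - waypoints[i, 1])
  list(x = pos[, 1], y = pos[, 2], heading = wrap_angle(hd), s = s)
}

# Fast VPC evaluation when every cell stores the same appearance set in the
# same order (arena protocols): stored azimuths as an M x K matrix.
vpc_fast <- function(stored_az, obs_az, sigma) {
  d <- abs(angle_diff(matrix(obs_az, nrow(stored_az), ncol(stored_az),
                             byrow = TRUE), stored_az))
  rowMeans(exp(-d^2 / (2 * sigma^2)))
}

#' Homing attraction bank
#'
#' Learns the sensory-motor attraction field used for periodic homing:
#' the goal cell itself (recruited first, so its stored profile is the PI
#' zero state when the integrator starts at the goal) plus `n_guides` place
#' cells on a ring around the goal, each associated with the direction
#' pointing at the goal.
#'
#' @param arena an `arena_config`.
#' @param field a signed-mode `pi_field` whose origin is the goal.
#' @param n_guides ring size (default 6).
#' @param ring_radius ring radius in metres (default 1.2).
#' @return a `place_cell_bank` with place-action associations.
#' @export
homing_bank <- function(arena, field, n_guides = 6, ring_radius = 1.2) {
  g <- arena$goal
  bank <- place_cell_bank(0)
  f0 <- set_pi(field, pi_profile_at(field, c(0, 0)))
  obs <- landmark_azimuths(list(x = g[1], y = g[2]), arena, visible_only = TRUE)
  bank <- recruit_vpc(bank, obs, f0, action = NA_real_)
  for (k in seq_len(n_guides)) {
    ang <- 2 * pi * (k - 1) / n_guides
    p <- g + ring_radius * c(cos(ang), sin(ang))
    fk <- set_pi(field, pi_profile_at(field, p - g))
    obs <- landmark_azimuths(list(x = p[1], y = p[2]), arena,
                             visible_only = TRUE)
    bank <- recruit_vpc(bank, obs, fk,
                        action = wrap_angle(atan2(g[2] - p[2], g[1] - p[1])))
  }
  bank
}

#' Closed-loop homing run
#'
#' Repeatedly applies the homing controller from a start point until the
#' agent enters the goal zone (or `max_steps` is exhausted).
#'
#' @param bank a `place_cell_bank` with place-action associations.
#' @param arena an `arena_config`.
#' @param start length-2 start position.
#' @param speed,dt kinematics (m/s, s).
#' @param max_steps step budget.
#' @param azimuth_sigma VPC tuning SD.
#' @return list with `reached` (logical), `path` (matrix), `steps`.
#' @export
run_homing <- function(bank, arena, start, speed = 0.2, dt = 0.1,
                       max_steps = 2000, azimuth_sigma = 10 * pi / 180) {
  p <- as.numeric(start)
  path <- matrix(NA_real_, max_steps + 1, 2)
  path[1, ] <- p
  for (k in seq_len(max_steps)) {
    if (sqrt(sum((p - arena$goal)^2)) <= arena$goal_radius)
      return(list(reached = TRUE, path = path[1:k, , drop = FALSE], steps = k - 1))
    h <- homing_controller(bank, list(x = p[1], y = p[2]), arena, azimuth_sigma)
    cand <- p + speed * dt * c(cos(h), sin(h))
    if (point_in_polygon(cand[1], cand[2], arena$boundary)) p <- cand
    path[k + 1, ] <- p
  }
  list(reached = sqrt(sum((p - arena$goal)^2)) <= arena$goal_radius,
       path = path, steps = max_steps)
}

# ---- arena protocols (exp1 / exp2 / exp4) -----------------------------------

simulate_arena_experiment <- function(config) {
  arena <- config$arena
  set.seed(config$seed)
  n_steps <- ceiling(config$duration_s / config$dt)
  step_len <- config$speed * config$dt
  field <- pi_from_config(config, arena_range_m(arena))
  pop <- grids_from_config(config)
  bank <- homing_bank(arena, field)
  sigma <- config$azimuth_sigma
  stored_az <- do.call(rbind, lapply(bank$constellations, `[[`, "azimuth"))
  params <- config$learning
  ctr <- polygon_centroid(arena$boundary)
  poly <- arena$boundary

  recal_on <- !is.na(config$recal_period_s %||% NA_real_)
  recal_until <- config$recal_until_s %||% Inf
  period <- if (recal_on) config$recal_period_s else Inf

  # noise sequences
  turns <- stats::rnorm(n_steps, 0, config$turn_sd)
  dev <- draw_deviation_curve(config$noise$heading_sys_amp)
  wnoise <- stats::rnorm(n_steps, 0, config$noise$heading_sd)
  sbias <- cumsum(stats::rnorm(n_steps, 0, config$noise$step_bias_sd))
  snoise <- stats::rnorm(n_steps, 0, config$noise$step_sd_fraction)

  x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
  hd <- numeric(n_steps + 1)
  x[1] <- arena$goal[1]; y[1] <- arena$goal[2]; hd[1] <- 0
  phases <- lapply(pop, function(sp) matrix(NA_integer_, n_steps, 2))
  events <- character(n_steps)
  homing <- FALSE
  last_recal_t <- 0
  landmarks <- arena$landmarks

  for (k in seq_len(n_steps)) {
    t_now <- k * config$dt
    p <- c(x[k], y[k])
    recal_active <- recal_on && t_now <= recal_until
    if (recal_active && !homing && (t_now - last_recal_t) >= period)
      homing <- TRUE
    if (homing) {
      az <- wrap_angle(atan2(landmarks$y - p[2], landmarks$x - p[1]))
      act <- vpc_fast(stored_az, az, sigma)
      aa <- ifelse(is.na(bank$actions), -Inf, act)
      h <- bank$actions[which.max(aa)]
    } else {
      h <- wrap_angle(hd[k] + turns[k])
    }
    cand <- p + step_len * c(cos(h), sin(h))
    if (!point_in_polygon(cand[1], cand[2], poly) ||
        boundary_distance(cand[1], cand[2], poly) < arena$avoid_dist) {
      h <- wrap_angle(atan2(ctr[2] - p[2], ctr[1] - p[1]))
      cand <- p + step_len * c(cos(h), sin(h))
      if (!point_in_polygon(cand[1], cand[2], poly)) cand <- p
    }
    x[k + 1] <- cand[1]; y[k + 1] <- cand[2]; hd[k + 1] <- h
    true_step <- sqrt(sum((cand - p)^2))
    h_meas <- wrap_angle(h + dev(h) + wnoise[k])
    s_meas <- max(0, true_step * (1 + sbias[k] + snoise[k]))
    field <- update_pi(field, h_meas, s_meas)
    for (l in seq_along(pop)) phases[[l]][k, ] <- grid_phase(pop[[l]], field)

    # goal arrival ends homing; the goal-zone signal (the floor-marker
    # surrogate) gates the recalibration, keeping the reset zone narrow
    if (homing && sqrt(sum((cand - arena$goal)^2)) <= arena$goal_radius) {
      homing <- FALSE
      events[k] <- "goal"
      if (recal_active) {
        az <- wrap_angle(atan2(landmarks$y - cand[2], landmarks$x - cand[1]))
        act <- vpc_fast(stored_az, az, sigma)
        trig <- recalibration_trigger(act, params)
        if (trig$fire) {
          field <- set_pi(field, bank$profiles[[trig$winner]])
          events[k] <- "goal recal"
          last_recal_t <- t_now
          for (l in seq_along(pop))
            phases[[l]][k, ] <- grid_phase(pop[[l]], field)
        }
      }
    }
  }
  traj <- new_trajectory(data.frame(
    t = (0:n_steps) * config$dt, x = x, y = y, heading = hd,
    step_true = c(0, sqrt(diff(x)^2 + diff(y)^2)),
    step_meas = 0, heading_meas = hd,
    event = c("", events), stringsAsFactors = FALSE))
  list(trajectory = traj, phases = phases, pop = pop, field = field,
       bank = bank)
}

# Rate map + gridness for one phase cell of one layer of an arena run.
arena_cell_analysis <- function(sim, config, layer = 2, phase = NULL,
                                window = NULL, bin = 0.05,
                                smooth_sigma = 0.05) {
  ph <- sim$phases[[layer]]
  n <- nrow(ph)
  idx <- if (is.null(window)) seq_len(n) else
    which(seq_len(n) * config$dt >= window[1] &
          seq_len(n) * config$dt <= window[2])
  if (is.null(phase)) {
    tab <- table(paste(ph[idx, 1], ph[idx, 2]))
    phase <- as.integer(strsplit(names(tab)[which.max(tab)], " ")[[1]])
  }
  act <- phase_cell_trace(ph[idx, , drop = FALSE], phase, sim$pop[[layer]])
  map <- rate_map(sim$trajectory$x[idx + 1], sim$trajectory$y[idx + 1], act,
                  bin = bin, smooth_sigma = smooth_sigma)
  g <- gridness_from_ratemap(map)
  list(phase = phase, map = map, gridness = g)
}

# ---- line-world protocols (exp6 / exp7) -------------------------------------

# Spatial size (metres) of one discretization bin of the PI field.
grid_bin_size <- function(field, N_E)
  field$meters_per_unit / field$alpha * field$D_max / N_E

# WTA place-cell activity profile along a straight crossing of the learned
# point.  The place is learned half a discretization bin off the origin so
# it sits at a generic position, not on the degenerate corner where all
# layers flip simultaneously.
line_profile <- function(pop, field, extent, angle, step) {
  s <- seq(-extent, extent, by = step)
  u <- c(cos(angle), sin(angle))
  p0 <- 0.5 * grid_bin_size(field, pop[[1]]$N_E) * u
  learned <- grid_pattern_at(pop, field, p0)
  bank <- learn_place_wta(list(learned), pop)
  act <- vapply(s, function(d) {
    pat <- grid_pattern_at(pop, field, p0 + d * u)
    wta_place_activity(bank, pat)[1]
  }, numeric(1))
  data.frame(distance = s, activity = act)
}

# Grid pattern (all layers, possibly diffused) at a position, via the
# position-based oracle.
grid_pattern_at <- function(pop, field, p) {
  unlist(lapply(pop, function(sp) {
    ph <- grid_from_position(p, sp, field)
    act <- matrix(0, sp$MG, sp$MG)
    act[ph[1] + 1L, ph[2] + 1L] <- 1
    if (sp$diffusion_sigma > 0) act <- diffuse(act, sp$diffusion_sigma)
    as.numeric(act)
  }))
}

simulate_line_experiment <- function(config) {
  field <- pi_from_config(config, range_m = 4 * config$line_extent)
  pop <- grids_from_config(config)
  profile <- line_profile(pop, field, config$line_extent,
                          config$line_angle, config$line_step)
  list(profile = profile, pop = pop, field = field)
}

# Random grid layers (random 60-deg-free pairs and moduli) for the
# cell-count sweep.
random_layers <- function(n_layers, N_E, field, seed) {
  set.seed(seed)
  lapply(seq_len(n_layers), function(i) {
    pair <- sample.int(field$N, 2)
    # keep the implied direction difference away from 0 / 180 deg
    while (abs(sin(field$theta[pair[1]] - field$theta[pair[2]])) < 0.3)
      pair <- sample.int(field$N, 2)
    grid_layer_spec(sample(4:25, 1), pair, N_E)
  })
}

simulate_exp7 <- function(config) {
  widths <- lapply(config$discretizations, function(NE) {
    cfg <- config; cfg$grids$N_E <- NE
    field <- pi_from_config(cfg, range_m = 4 * config$line_extent)
    pop <- grids_from_config(cfg)
    prof <- line_profile(pop, field, config$line_extent,
                         config$line_angle, config$line_step)
    place_field_width(prof$distance, prof$activity)
  })
  noises <- lapply(config$cell_counts, function(L) {
    field <- pi_from_config(config, range_m = 4 * config$line_extent)
    layers <- random_layers(L, config$grids$N_E, field, config$seed)
    pop <- structure(layers, class = "grid_population")
    prof <- line_profile(pop, field, config$line_extent,
                         config$line_angle, config$line_step)
    # background noise: spurious partial matches far from the place field
    far <- abs(prof$distance) > config$line_extent / 4
    stats::sd(prof$activity[far])
  })
  list(discretizations = config$discretizations,
       bin_sizes = 4 * config$line_extent / config$discretizations,
       widths = unlist(widths),
       cell_counts = config$cell_counts,
       trace_noise = unlist(noises))
}

# ---- two-room protocols (exp8 - exp11) --------------------------------------

# Learned multi-room route: room 1, corridor, room 2, ending deep in room 2.
# Total arc length ~28.4 m, so 19 places at 1.5 m spacing fit on it.
tworoom_waypoints <- function(arena) {
  rbind(c(1, 6), c(5.5, 6), c(6.5, 3.8), c(7.5, 3.5),
        c(15.5, 3.5), c(16.5, 3.8), c(17.5, 6), c(22, 6), c(22, 1.5))
}

# Learn the multi-room path: recruit n_places regularly spaced VPCs with
# their PI profiles, then NLMS-train the grid -> VPC association over laps.
train_tworoom <- function(config) {
  arena <- config$arena
  wp <- tworoom_waypoints(arena)
  step_len <- config$speed * config$dt
  path <- path_positions(wp, step_len)
  total <- max(path$s)
  marks <- seq(0, by = config$place_spacing, length.out = config$n_places)
  field <- pi_from_config(config, range_m = arena_range_m(arena))
  pop <- grids_from_config(config)
  L <- sum(vapply(pop, function(sp) sp$MG^2, numeric(1)))
  bank <- place_cell_bank(L)
  origin <- c(path$x[1], path$y[1])
  # recruitment pass (PI follows the path, noise-free during learning)
  for (m in marks) {
    i <- which.min(abs(path$s - m))
    p <- c(path$x[i], path$y[i])
    fld <- set_pi(field, pi_profile_at(field, p - origin))
    obs <- landmark_azimuths(list(x = p[1], y = p[2]), arena,
                             visible_only = TRUE)
    bank <- recruit_vpc(bank, obs, fld)
  }
  # NLMS training laps along the path.  The neuromodulation gate (the
  # experimenter's supervision signal) opens only where the visual
  # recognition is confident (the recalibration-trigger condition), so the
  # association is never learned at perceptually ambiguous spots.
  for (lap in seq_len(config$training_laps)) {
    for (i in seq_along(path$s)) {
      p <- c(path$x[i], path$y[i])
      fld <- set_pi(field, pi_profile_at(field, p - origin))
      G <- grid_pattern(pop, fld)
      obs <- landmark_azimuths(list(x = p[1], y = p[2]), arena,
                               visible_only = TRUE)
      vpc <- vpc_activity(obs, bank, config$azimuth_sigma)
      pars <- config$learning
      pars$gamma <- as.numeric(recalibration_trigger(vpc, pars)$fire)
      bank <- nlms_update(bank, G, vpc, pars)
    }
  }
  list(bank = bank, pop = pop, field = field, path = path, origin = origin,
       marks = marks)
}

# Replay a (possibly kidnapped / offset) path with the trained bank:
# PI integrates the commanded displacements (blind to kidnaps), VPC sees the
# true position, recalibration overwrites PI on confident recognition.
replay_tworoom <- function(tr, config, offset = c(0, 0),
                           kidnap_from = NA, kidnap_to = NA) {
  arena <- config$arena
  path <- tr$path
  n <- length(path$s)
  # sample sequence of true path indices: up to the kidnap point, then a
  # teleport to the kidnap target and on to the end of the path
  if (is.na(kidnap_from)) {
    idx <- seq_len(n); kid_at <- NA_integer_
  } else {
    i_k <- which.min(abs(path$s - kidnap_from))
    j_k <- which.min(abs(path$s - kidnap_to))
    idx <- c(seq_len(i_k), seq(j_k, n))
    kid_at <- i_k + 1L
  }
  T <- length(idx)
  field <- set_pi(tr$field, pi_profile_at(tr$field, c(path$x[1], path$y[1]) +
                                            offset - tr$origin))
  pop <- tr$pop; bank <- tr$bank
  M <- n_cells(bank)
  out <- data.frame(s = path$s[idx],
                    x = path$x[idx] + offset[1], y = path$y[idx] + offset[2],
                    vpc_win = NA_integer_, pred_win = NA_integer_,
                    mpc_win = NA_integer_, recal = FALSE,
                    kidnapped = if (is.na(kid_at)) FALSE
                                else seq_len(T) >= kid_at)
  traces <- list(vpc = matrix(NA_real_, T, M), pred = matrix(NA_real_, T, M),
                 mpc = matrix(NA_real_, T, M))
  for (t in seq_len(T)) {
    i <- idx[t]
    p_true <- c(out$x[t], out$y[t])
    if (t > 1 && !identical(t, kid_at)) {
      # odometric signal for a normal step; the kidnap seam produces none
      dstep <- c(path$x[i] - path$x[idx[t - 1]],
                 path$y[i] - path$y[idx[t - 1]])
      field <- update_pi(field, atan2(dstep[2], dstep[1]),
                         sqrt(sum(dstep^2)))
    }
    G <- grid_pattern(pop, field)
    obs <- landmark_azimuths(list(x = p_true[1], y = p_true[2]), arena,
                             visible_only = TRUE)
    vpc <- vpc_activity(obs, bank, config$azimuth_sigma)
    pred <- predict_vpc(G, bank)
    mpc <- fuse_mpc(vpc, pred, config$learning$eta)
    trig <- recalibration_trigger(vpc, config$learning)
    if (trig$fire) {
      field <- set_pi(field, bank$profiles[[trig$winner]])
      out$recal[t] <- TRUE
    }
    out$vpc_win[t] <- wta_winner(vpc)$index
    out$pred_win[t] <- wta_winner(pred)$index
    out$mpc_win[t] <- wta_winner(mpc)$index
    traces$vpc[t, ] <- vpc; traces$pred[t, ] <- pred; traces$mpc[t, ] <- mpc
  }
  list(log = out, traces = traces)
}

# Index of the place mark nearest to each sample's true position.
nearest_place <- function(log, tr, offset = c(0, 0)) {
  mpos <- t(vapply(tr$marks, function(m) {
    i <- which.min(abs(tr$path$s - m))
    c(tr$path$x[i], tr$path$y[i])
  }, numeric(2)))
  vapply(seq_len(nrow(log)), function(i) {
    d <- (mpos[, 1] - log$x[i])^2 + (mpos[, 2] - log$y[i])^2
    which.min(d)
  }, integer(1))
}

#' Run an experiment
#'
#' Executes the protocol described by a configuration from [preset()] and
#' returns a run record with the trajectory, activity traces, analysis
#' products and event log.  Reruns with an identical config are identical.
#'
#' @param config an `experiment_config`.
#' @return a list of class `run_record`; contents depend on the protocol
#'   family (see [preset()]).
#' @export
run_experiment <- function(config) {
  rec <- switch(
    config$id,
    exp1 = , exp2 = , exp4 = {
      sim <- simulate_arena_experiment(config)
      window <- if (config$id == "exp4")
        c(config$recal_until_s, config$duration_s) else NULL
      cells <- lapply(seq_along(sim$pop), function(l)
        arena_cell_analysis(sim, config, layer = l, window = window))
      list(trajectory = sim$trajectory, cells = cells, bank = sim$bank,
           pop = sim$pop)
    },
    exp6 = simulate_line_experiment(config),
    exp7 = simulate_exp7(config),
    exp8 = {
      tr <- train_tworoom(config)
      rep <- replay_tworoom(tr, config)
      c(list(training = tr), rep)
    },
    exp9 = {
      tr <- train_tworoom(config)
      runs <- lapply(config$path_offsets, function(dy)
        replay_tworoom(tr, config, offset = c(0, dy)))
      list(training = tr, offsets = config$path_offsets, runs = runs)
    },
    exp10 = , exp11 = {
      tr <- train_tworoom(config)
      rep <- replay_tworoom(tr, config, kidnap_from = config$kidnap_from,
                            kidnap_to = config$kidnap_to)
      c(list(training = tr), rep)
    },
    stop("unknown experiment id: ", config$id))
  structure(c(list(config = config), rec), class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat("Run record for", x$config$id, "\n")
  if (!is.null(x$trajectory)) print(x$trajectory)
  if (!is.null(x$cells))
    for (l in seq_along(x$cells))
      cat(sprintf("  layer %d phase (%d,%d): gridness %.3f\n", l,
                  x$cells[[l]]$phase[1], x$cells[[l]]$phase[2],
                  x$cells[[l]]$gridness$score))
  invisible(x)
}

#' Write a run record to a directory
#'
#' CSV/JSON export of the main products: trajectory, per-layer rate maps and
#' rotational-correlation curves, activity traces, event log and the
#' resolved configuration snapshot.
#'
#' @param rec a `run_record`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_record <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- rec$config
  cfg$arena <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(rec$trajectory))
    write_trajectory_csv(rec$trajectory, file.path(dir, "trajectory.csv"))
  if (!is.null(rec$cells))
    for (l in seq_along(rec$cells)) {
      write_matrix_csv(rec$cells[[l]]$map,
                       file.path(dir, sprintf("ratemap_layer%d.csv", l)))
      write_curve_csv(rec$cells[[l]]$gridness$curve,
                      file.path(dir, sprintf("rotcurve_layer%d.csv", l)))
    }
  if (!is.null(rec$profile))
    utils::write.csv(rec$profile, file.path(dir, "profile.csv"),
                     row.names = FALSE)
  if (!is.null(rec$log))
    utils::write.csv(rec$log, file.path(dir, "log.csv"), row.names = FALSE)
  invisible(dir)
}
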
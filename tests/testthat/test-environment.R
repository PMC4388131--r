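test_that("random walk respects kinematics and containment", {
  arena <- hex_arena(4)
  # zero turn noise from the centre: straight line until the wall deflects
  traj <- generate_random_walk(arena, 100, turn_sd = 0, seed = 1)
  first_turn <- which(abs(diff(traj$heading)) > 1e-12)[1]
  expect_gt(first_turn, 10)
  expect_equal(traj$y[1:first_turn], rep(0, first_turn), tolerance = 1e-12)
  # total path length = n_steps * speed * dt when no step is blocked
  traj <- generate_random_walk(arena, 6000, speed = 0.2, dt = 0.1, seed = 2)
  expect_equal(sum(traj$step_true), 6000 * 0.2 * 0.1, tolerance = 1e-9)
  # containment: several seeds, every pose inside the boundary
  for (s in 1:3) {
    tr <- generate_random_walk(arena, 2000, seed = s,
                               noise = sensor_noise_model())
    expect_true(all(modulogrid:::point_in_polygon(tr$x, tr$y,
                                                  arena$boundary)))
  }
})

test_that("identical config and seed reproduce the trajectory bit for bit", {
  arena <- hex_arena(4)
  a <- generate_random_walk(arena, 500, seed = 11,
                            noise = sensor_noise_model())
  b <- generate_random_walk(arena, 500, seed = 11,
                            noise = sensor_noise_model())
  expect_identical(a, b)
})

test_that("sensor model: identity at zero noise, calibrated white noise, clamping", {
  nf <- noise_free()
  s <- sense(list(heading = 1.2), 0.02, nf)
  expect_equal(s$heading, 1.2)
  expect_equal(s$step, 0.02)
  # Monte-Carlo: sample SD of measured - true heading near 1 degree
  set.seed(4)
  nm <- sensor_noise_model(heading_sd = pi / 180, heading_sys_amp = 0,
                           step_sd_fraction = 0, step_bias_sd = 0)
  errs <- replicate(1e4, sense(list(heading = 0), 1, nm)$heading)
  errs <- modulogrid::angle_diff(errs, 0)
  expect_equal(stats::sd(errs), pi / 180, tolerance = 0.1)
  # negative measured steps are clamped to zero
  set.seed(5)
  big <- sensor_noise_model(heading_sd = 0, heading_sys_amp = 0,
                            step_sd_fraction = 5, step_bias_sd = 0)
  steps <- replicate(200, sense(list(heading = 0), 0.02, big)$step)
  expect_true(all(steps >= 0))
  expect_true(any(steps == 0))
})

test_that("path-length bookkeeping is exact without step noise", {
  arena <- hex_arena(4)
  tr <- generate_random_walk(arena, 1000, seed = 3, noise = noise_free())
  expect_equal(sum(tr$step_meas), sum(tr$step_true), tolerance = 1e-12)
})

test_that("landmark azimuths are allocentric and geometry-consistent", {
  arena <- arena_config(rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5)),
                        landmarks = data.frame(id = 1:3,
                                               x = c(2, 0, -1),
                                               y = c(0, 2, -1)))
  pose <- list(x = 0, y = 0)
  az <- landmark_azimuths(pose, arena)
  expect_equal(az$azimuth[1], 0)          # due east
  expect_equal(az$azimuth[2], pi / 2)     # due north
  # moving straight toward a landmark leaves its azimuth unchanged
  az2 <- landmark_azimuths(list(x = 1, y = 0), arena)
  expect_equal(az2$azimuth[1], az$azimuth[1])
  expect_false(isTRUE(all.equal(az2$azimuth[2], az$azimuth[2])))
  expect_false(isTRUE(all.equal(az2$azimuth[3], az$azimuth[3])))
})

test_that("kidnapping teleports the pose but not the odometry", {
  arena <- arena_config(rbind(c(0, 0), c(40, 0), c(40, 20), c(0, 20)))
  traj <- generate_random_walk(arena, 400, seed = 6, noise = noise_free(),
                               start = c(20, 10))
  # identity jump changes nothing downstream
  same <- apply_kidnap(traj, 200, list(x = traj$x[200], y = traj$y[200]),
                       arena)
  expect_equal(same$step_meas, traj$step_meas)
  expect_equal(same$x, traj$x)
  # a 10 m jump: odometric columns unchanged, true pose offset by 10 m
  kid <- apply_kidnap(traj, 200, list(x = traj$x[200] + 10, y = traj$y[200]),
                      arena)
  expect_identical(kid$step_meas, traj$step_meas)
  expect_identical(kid$heading_meas, traj$heading_meas)
  expect_equal(sqrt((kid$x[300] - traj$x[300])^2 +
                      (kid$y[300] - traj$y[300])^2), 10)
  expect_match(kid$event[200], "kidnap")
  expect_error(apply_kidnap(traj, 10, list(x = 100, y = 0), arena),
               "outside")
})

test_that("homing attraction basin covers the arena", {
  arena <- hex_arena(4)
  bank <- homing_bank(arena, default_field())
  # single learned place pointing at the goal: recall is the stored direction
  h <- homing_controller(bank, list(x = 1.2, y = 0), arena)
  expect_equal(h, bank$actions[2], tolerance = 1e-12)
  # already inside the goal zone: controller releases immediately
  at_goal <- run_homing(bank, arena, arena$goal + c(0.05, 0))
  expect_true(at_goal$reached)
  expect_equal(at_goal$steps, 0)
  # >= 95% of a 10 x 10 grid of starts terminate in the goal zone
  g <- expand.grid(x = seq(-1.9, 1.9, length.out = 10),
                   y = seq(-1.9, 1.9, length.out = 10))
  ok <- modulogrid:::point_in_polygon(g$x, g$y, arena$boundary)
  g <- g[ok, ]
  reached <- vapply(seq_len(nrow(g)), function(i)
    run_homing(bank, arena, c(g$x[i], g$y[i]))$reached, logical(1))
  expect_gte(mean(reached), 0.95)
})

test_that("trajectory CSV round trip preserves the record", {
  arena <- hex_arena(4)
  traj <- generate_random_walk(arena, 50, seed = 9,
                               noise = sensor_noise_model())
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$x, traj$x, tolerance = 1e-12)
  expect_equal(back$heading_meas, traj$heading_meas, tolerance = 1e-12)
  expect_identical(back$event, traj$event)
  unlink(path)
})

test_that("degenerate arenas are rejected", {
  expect_error(arena_config(rbind(c(0, 0), c(1, 0), c(2, 0))), "degenerate")
  expect_error(hex_arena(4, goal_radius = 0), "goal_radius")
})
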
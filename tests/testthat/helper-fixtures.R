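# Shared fixtures built in code at test time.

default_field <- function(mode = "signed_projection", range_m = 8)
  pi_field(mode = mode, range_m = range_m)

# Integrate a polyline path (matrix of vertices, starting at the origin of
# integration) into a PI field, one exact step per segment.
integrate_polyline <- function(field, pts) {
  for (i in 2:nrow(pts)) {
    d <- pts[i, ] - pts[i - 1, ]
    field <- update_pi(field, atan2(d[2], d[1]), sqrt(sum(d^2)))
  }
  field
}

# Random polyline from the origin to `p` staying within `lim`.
random_polyline_to <- function(p, n_mid = 4, lim = 1.8) {
  rbind(c(0, 0),
        matrix(stats::runif(2 * n_mid, -lim, lim), ncol = 2),
        p)
}

# Ideal hexagonal pattern: sum of three cosine gratings 60 degrees apart.
hex_grating_map <- function(n = 81, period_bins = 14, orient = 0) {
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  k <- 2 * pi / period_bins
  z <- 0
  for (a in orient + c(0, pi / 3, 2 * pi / 3))
    z <- z + cos(k * (xy$x * cos(a) + xy$y * sin(a)))
  rate <- matrix(z, n, n)
  structure(list(rate = rate, occupancy = matrix(1L, n, n),
                 mask = matrix(TRUE, n, n), bin = 0.05,
                 xlim = c(0, n * 0.05), ylim = c(0, n * 0.05)),
            class = "rate_map")
}

# Single-orientation stripe pattern.
stripe_map <- function(n = 81, period_bins = 14) {
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  rate <- matrix(cos(2 * pi * xy$x / period_bins), n, n)
  structure(list(rate = rate, occupancy = matrix(1L, n, n),
                 mask = matrix(TRUE, n, n), bin = 0.05,
                 xlim = c(0, n * 0.05), ylim = c(0, n * 0.05)),
            class = "rate_map")
}

# Fast phase-cell rate-map pipeline for a noise-free signed-mode walk.
walk_phase_ratemap <- function(n_steps = 50000, MG = 9, pair = c(1, 11),
                               seed = 7, bin = 0.05, sigma = 0.05) {
  arena <- hex_arena(4)
  traj <- generate_random_walk(arena, n_steps, noise = noise_free(),
                               seed = seed)
  field <- default_field()
  sp <- grid_layer_spec(MG, pair)
  Dt <- pi_trace(field, traj$heading_meas[-1], traj$step_meas[-1],
                 neurons = pair)
  ph <- grid_phase_trace(Dt, sp, field$D_max)
  act <- phase_cell_trace(ph, c(0, 0), sp)
  rate_map(traj$x[-1], traj$y[-1], act, bin = bin, smooth_sigma = sigma)
}
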
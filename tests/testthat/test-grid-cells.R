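test_that("discretization bins and modulo projection follow the written forms", {
  expect_equal(discretize(0, 60, 1), 0)
  expect_equal(discretize(0.5, 60, 1), 30)
  expect_equal(discretize(1, 60, 1), 59)       # closed top bin
  expect_error(discretize(1.2, 60, 1), "outside")
  expect_error(discretize(-0.1, 60, 1), "outside")
  expect_equal(modulo_project(7, 4), 3)
  expect_equal(modulo_project(0, 9), 0)
  b <- 0:59
  expect_equal(modulo_project(b + 9, 9), modulo_project(b, 9))  # periodicity
})

test_that("grid-layer conjunction is one-hot and anchored at the zero state", {
  f <- pi_field(mode = "as_printed")
  sp <- grid_layer_spec(9, c(1, 11))
  act <- grid_activity(sp, f)
  expect_equal(act[1, 1], 1)                   # zero state -> phase (0, 0)
  expect_equal(sum(act), 1)
  set.seed(21)
  for (k in 1:20) {
    f <- update_pi(f, stats::runif(1, 0, 2 * pi), stats::runif(1, 0, 0.05))
    expect_equal(sum(grid_activity(sp, f)), 1) # one-hot at any state
  }
})

test_that("a straight sweep of two spatial periods hits each phase exactly twice", {
  f <- default_field()
  sp <- grid_layer_spec(9, c(1, 11))
  binsize <- f$meters_per_unit / f$alpha * f$D_max / sp$N_E
  d <- (seq_len(2 * sp$MG) - 0.5) * binsize    # bin centres along +x (theta_1)
  k1 <- vapply(d, function(s) grid_from_position(c(s, 0), sp, f)[1],
               integer(1))
  expect_true(all(table(k1) == 2))
  expect_equal(length(unique(k1)), sp$MG)
})

test_that("torus diffusion preserves the winner and the Gaussian profile", {
  sp <- grid_layer_spec(9, c(1, 11))
  f <- default_field()
  act <- grid_activity(sp, f)
  expect_equal(diffuse(act, 0), act)           # sigma 0 is the identity
  d <- diffuse(act, 1)
  w <- which(act == 1, arr.ind = TRUE)
  expect_equal(which(d == max(d), arr.ind = TRUE)[1, ], w[1, ],
               ignore_attr = TRUE)             # peak preserved
  expect_equal(max(d), 1)
  expect_true(all(d >= 0 & d <= 1))
  # value at torus distance 1 is exp(-1/2) of the peak
  i <- w[1, 1]; j <- w[1, 2]
  expect_equal(d[(i %% 9) + 1, j], exp(-1 / 2), tolerance = 1e-9)
  # wrap-around: diffusion from a border cell reaches the opposite edge
  e <- matrix(0, 9, 9); e[1, 1] <- 1
  de <- diffuse(e, 1)
  expect_equal(de[9, 1], exp(-1 / 2), tolerance = 1e-9)
})

test_that("incremental grid activity equals the position-based oracle", {
  set.seed(22)
  sp <- grid_layer_spec(9, c(1, 11))
  for (r in 1:100) {
    p <- stats::runif(2, -1.5, 1.5)
    f <- integrate_polyline(default_field(),
                            random_polyline_to(p, n_mid = sample(2:6, 1)))
    expect_identical(grid_phase(sp, f), grid_from_position(p, sp, f))
  }
})

test_that("spacing law: spatial period equals modulo times bin size", {
  f <- default_field()
  for (MG in c(4, 9)) {
    sp <- grid_layer_spec(MG, c(1, 11))
    binsize <- f$meters_per_unit / f$alpha * f$D_max / sp$N_E
    d <- seq(-3, 3, by = 0.005)                # fine sweep along theta_1
    k1 <- vapply(d, function(s) grid_from_position(c(s, 0), sp, f)[1],
                 integer(1))
    hits <- d[k1 == 1]
    centres <- tapply(hits, cumsum(c(1, diff(hits) > 2 * 0.005)), mean)
    gaps <- diff(as.numeric(centres))
    expect_lt(abs(mean(gaps) - MG * binsize), binsize)
    expect_true(all(abs(gaps - MG * binsize) < binsize))
  }
})

# Lattice axis direction of a phase cell's autocorrelogram (degrees in
# [0, 60)), from the strongest off-centre peak at the lattice radius.
lattice_axis_deg <- function(pair, MG = 9) {
  f <- default_field()
  sp <- grid_layer_spec(MG, pair)
  g <- expand.grid(x = seq(-2, 2, by = 0.05), y = seq(-2, 2, by = 0.05))
  act <- vapply(seq_len(nrow(g)), function(i) {
    ph <- grid_from_position(c(g$x[i], g$y[i]), sp, f)
    as.numeric(ph[1] == 0 && ph[2] == 0)
  }, numeric(1))
  map <- rate_map(g$x, g$y, act, bin = 0.05, smooth_sigma = 0.05)
  ac <- spatial_autocorrelation(map)$ac
  n <- nrow(ac); c0 <- (n + 1) / 2
  period_bins <- MG * (8 / 60) / 0.05 * 2 / sqrt(3)  # lattice constant
  xy <- expand.grid(i = seq_len(n), j = seq_len(n))
  rr <- sqrt((xy$i - c0)^2 + (xy$j - c0)^2)
  ring <- which(abs(rr - period_bins) < 2 & !is.na(as.numeric(ac)))
  best <- ring[which.max(ac[ring])]
  ang <- atan2(xy$j[best] - c0, xy$i[best] - c0) * 180 / pi
  ang %% 60
}

test_that("rotating the direction pair rotates the firing lattice", {
  a0 <- lattice_axis_deg(c(1, 11))
  a30 <- lattice_axis_deg(c(6, 16))   # pair rotated by 30 degrees
  d <- abs(a0 - a30) %% 60
  expect_lt(abs(min(d, 60 - d) - 30), 6)
})

test_that("a 60-degree pair yields six-fold rotational symmetry", {
  f <- default_field()
  sp <- grid_layer_spec(9, c(1, 11))
  g <- expand.grid(x = seq(-2, 2, by = 0.05), y = seq(-2, 2, by = 0.05))
  act <- vapply(seq_len(nrow(g)), function(i) {
    ph <- grid_from_position(c(g$x[i], g$y[i]), sp, f)
    as.numeric(ph[1] == 0 && ph[2] == 0)
  }, numeric(1))
  map <- rate_map(g$x, g$y, act, bin = 0.05, smooth_sigma = 0.05)
  res <- gridness_from_ratemap(map)
  v <- res$values
  expect_gt(min(v["r60"], v["r120"]), max(v["r30"], v["r90"], v["r150"]))
  expect_gt(res$score, 0.5)
})

test_that("random modulo projections span grid-like and non-grid activity", {
  # hand-built single cell with a standard layer's scales reduces to the
  # one-hot conjunction
  f <- default_field()
  sp <- grid_layer_spec(9, c(1, 11))
  set.seed(23)
  hs <- stats::runif(300, 0, 2 * pi); ss <- stats::runif(300, 0, 0.05)
  Dt <- pi_trace(f, hs, ss)
  pop1 <- structure(list(cells = list(list(neurons = c(1L, 11L),
                                           scales = c(9L, 9L),
                                           residues = c(0L, 0L))),
                         N_E = 60L), class = "rp_population")
  a <- rp_activity_trace(pop1, Dt, f$D_max)[, 1]
  sp0 <- grid_layer_spec(9, c(1, 11))
  ph <- grid_phase_trace(Dt[, c(1, 11)], sp0, f$D_max)
  expect_equal(a, phase_cell_trace(ph, c(0, 0), sp0))
  # empty population
  pop0 <- random_projection_population(f, 0, seed = 1)
  expect_length(pop0$cells, 0)
  # screening: a fixed-seed population over a long walk shows both
  # positive- and negative-gridness cells
  arena <- hex_arena(4)
  traj <- generate_random_walk(arena, 20000, noise = noise_free(), seed = 17)
  Dt <- pi_trace(f, traj$heading_meas[-1], traj$step_meas[-1])
  pop <- random_projection_population(f, 60, seed = 17)
  A <- rp_activity_trace(pop, Dt, f$D_max)
  scores <- rep(NA_real_, ncol(A))
  for (i in seq_len(ncol(A))) {
    if (mean(A[, i]) < 0.002) next
    map <- rate_map(traj$x[-1], traj$y[-1], A[, i], bin = 0.1,
                    smooth_sigma = 0.1)
    g <- gridness_from_ratemap(map)
    if (!g$degenerate) scores[i] <- g$score
  }
  expect_gt(sum(!is.na(scores)), 10)
  expect_gt(max(scores, na.rm = TRUE), 0)
  expect_lt(min(scores, na.rm = TRUE), 0)
})

test_that("grid-layer specs validate their invariants", {
  expect_error(grid_layer_spec(1, c(1, 11)))       # modulo too small
  expect_error(grid_layer_spec(61, c(1, 11)))      # modulo above N_E
  expect_error(grid_layer_spec(9, c(4, 4)))        # identical pair
  expect_error(grid_layer_spec(9, c(1, 11), diffusion_sigma = -1))
})
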
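obs_df <- function(appearance, azimuth)
  data.frame(appearance = appearance, azimuth = azimuth)

test_that("visual place cells match landmark-azimuth constellations", {
  f <- default_field()
  bank <- place_cell_bank(0)
  stored <- obs_df(1:3, c(0, pi / 2, pi))
  bank <- recruit_vpc(bank, stored, f)
  # identical observation -> activity 1
  expect_equal(vpc_activity(stored, bank), 1)
  # all azimuths off by >> 3 sigma -> activity ~ 0
  off <- obs_df(1:3, c(0, pi / 2, pi) + 1.2)
  expect_lt(vpc_activity(off, bank, azimuth_sigma = 10 * pi / 180), 1e-6)
  # no appearance overlap -> 0
  expect_equal(vpc_activity(obs_df(7:9, c(0, 1, 2)), bank), 0)
  # mirror-identical constellations at two places excite the cell equally
  expect_equal(vpc_activity(stored, bank), vpc_activity(stored, bank))
  twin <- obs_df(c(2, 3, 1), c(pi / 2, pi, 0))  # same pairs, reordered
  expect_equal(vpc_activity(twin, bank), 1)
})

test_that("recruitment stores the constellation and the PI profile verbatim", {
  f <- reset_pi(default_field())
  bank <- place_cell_bank(0)
  obs <- obs_df(1:2, c(0.1, 2.2))
  # first recruitment after a reset stores the zero state
  bank <- recruit_vpc(bank, obs, f)
  expect_equal(bank$profiles[[1]], rep(f$D_max / 2, f$N))
  # no deduplication: recruiting twice gives two identical cells
  bank <- recruit_vpc(bank, obs, f)
  expect_identical(bank$profiles[[1]], bank$profiles[[2]])
  expect_identical(bank$constellations[[1]], bank$constellations[[2]])
  # 19 recruitments -> bank of 19
  b19 <- place_cell_bank(0)
  for (k in 1:19) b19 <- recruit_vpc(b19, obs, f)
  expect_length(b19$profiles, 19)
})

test_that("winner-take-all selects the argmax with low-index tie-breaking", {
  expect_equal(wta_winner(c(0.2, 0.9, 0.1))$index, 2)
  expect_equal(wta_winner(c(0.5, 0.5, 0.5))$index, 1)
  expect_equal(wta_winner(0.3)$index, 1)
  expect_equal(wta_winner(c(0.2, 0.9, 0.1))$beta, c(0, 1, 0))
})

test_that("NLMS prediction and gated update behave as written", {
  bank <- place_cell_bank(4)
  f <- default_field()
  bank <- recruit_vpc(bank, obs_df(1, 0), f)
  G <- c(1, 0, 1, 0)
  expect_equal(predict_vpc(G, bank), 0)          # zero weights
  expect_equal(predict_vpc(numeric(4), bank), 0) # zero input
  expect_error(predict_vpc(c(1, 0), bank), "length")
  # gamma = 0 freezes the weights
  frozen <- nlms_update(bank, G, 1, learning_params(gamma = 0))
  expect_identical(frozen$W, bank$W)
  # zero input energy performs no update
  skip0 <- nlms_update(bank, numeric(4), 1, learning_params(lambda = 1))
  expect_identical(skip0$W, bank$W)
  # lambda = 1: a single pair is learned in one step (normalised update)
  one <- nlms_update(bank, G, 1, learning_params(lambda = 1))
  expect_equal(predict_vpc(G, one), 1, tolerance = 1e-12)
  # stationary pair, lambda = 0.1: monotone decay below 1e-3 within 200 steps
  b <- bank; errs <- numeric(200)
  for (k in 1:200) {
    errs[k] <- abs(1 - predict_vpc(G, b))
    b <- nlms_update(b, G, 1, learning_params(lambda = 0.1))
  }
  expect_true(all(diff(errs) <= 1e-15))
  expect_lt(abs(1 - predict_vpc(G, b)), 1e-3)
})

test_that("NLMS contracts the per-sample error for lambda in (0, 1]", {
  set.seed(41)
  for (r in 1:30) {
    L <- 6
    bank <- place_cell_bank(L)
    f <- default_field()
    bank <- recruit_vpc(bank, obs_df(1, 0), f)
    bank$W[1, ] <- stats::rnorm(L, 0, 0.3)
    G <- stats::runif(L)
    target <- stats::runif(1)
    lam <- stats::runif(1, 0.05, 1)
    e_prior <- target - predict_vpc(G, bank)
    b2 <- nlms_update(bank, G, target, learning_params(lambda = lam))
    e_post <- target - predict_vpc(G, b2)
    expect_lte(abs(e_post), abs(e_prior) + 1e-12)
  }
})

test_that("multimodal fusion is a convex combination", {
  expect_equal(fuse_mpc(c(0.3, 0.8), c(0.6, 0.1), eta = 1), c(0.3, 0.8))
  expect_equal(fuse_mpc(c(0.4, 0.4), c(0.4, 0.4), eta = 0.27), c(0.4, 0.4))
  expect_equal(fuse_mpc(1, 0, eta = 0.5), 0.5)
  set.seed(42)
  v <- stats::runif(10); p <- stats::runif(10, -0.2, 1.2)
  m <- fuse_mpc(v, p, eta = 0.3)
  expect_true(all(m >= pmin(v, p) - 1e-12 & m <= pmax(v, p) + 1e-12))
})

test_that("the recalibration trigger needs confidence and a margin", {
  pars <- learning_params(thr_abs = 0.7, thr_rel = 0.2)
  expect_true(recalibration_trigger(c(0.9, 0.3), pars)$fire)
  expect_false(recalibration_trigger(c(0.9, 0.85), pars)$fire)
  expect_false(recalibration_trigger(c(0.5, 0.1), pars)$fire)
  # single cell: absolute test only
  expect_true(recalibration_trigger(0.8, pars)$fire)
  expect_equal(recalibration_trigger(c(0.2, 0.9, 0.1), pars)$winner, 2)
})

test_that("WTA place cells from binary grids produce the three-step stair", {
  rec <- run_experiment(preset("exp6"))
  act <- rec$profile$activity
  levels <- sort(unique(round(act[act > 1e-9], 9)))
  expect_equal(levels, c(1 / 3, 2 / 3, 1), tolerance = 1e-9)
  # self-match at the learned position
  expect_equal(max(act), 1)
  # with lateral diffusion the edges become graded and no distant false
  # maximum approaches the peak
  cfg <- preset("exp6")
  cfg$grids$diffusion_sigma <- 1
  recd <- run_experiment(cfg)
  actd <- recd$profile$activity
  d <- recd$profile$distance
  expect_gt(length(unique(round(actd[actd > 1e-9], 9))), 3) # graded
  expect_lt(max(actd[abs(d) > 1]), 0.9)
  # diffusion widens the half-height field
  w_bin <- place_field_width(rec$profile$distance, act)
  w_dif <- place_field_width(d, actd)
  expect_gt(w_dif, w_bin)
})

test_that("place-action association recalls the taught direction", {
  f <- default_field()
  bank <- place_cell_bank(0)
  bank <- recruit_vpc(bank, obs_df(1:2, c(0, pi / 2)), f)
  expect_error(homing_controller(bank, list(x = 0, y = 0), hex_arena(4)),
               "association")
  bank <- learn_place_action(bank, 1, 2.5)
  expect_equal(bank$actions[1], 2.5)
  # partial-rate update moves the stored direction toward the target
  b2 <- learn_place_action(bank, 1, 3.0, rate = 0.5)
  expect_gt(b2$actions[1], 2.5)
  expect_lt(b2$actions[1], 3.0)
})

test_that("bank serialization round-trips every store", {
  f <- update_pi(default_field(), 0.3, 0.5)
  bank <- place_cell_bank(5)
  bank <- recruit_vpc(bank, obs_df(1:2, c(0.3, 1.1)), f, action = 1.7)
  bank <- recruit_vpc(bank, obs_df(2:3, c(2.3, 0.4)), f)
  bank <- nlms_update(bank, c(1, 0, 0, 1, 0), c(0.9, 0.1),
                      learning_params(lambda = 0.5))
  path <- tempfile(fileext = ".json")
  write_bank(bank, path)
  back <- read_bank(path)
  expect_equal(back$W, bank$W, tolerance = 1e-12)
  expect_equal(back$profiles, bank$profiles, tolerance = 1e-12)
  expect_equal(back$actions, bank$actions)
  expect_equal(back$constellations[[2]]$azimuth,
               bank$constellations[[2]]$azimuth, tolerance = 1e-12)
  unlink(path)
})
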
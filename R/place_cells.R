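#' Learning parameters
#'
#' Parameters of the gated NLMS rule and of the recalibration trigger.  The
#' effective per-cell learning rate is `lambda * gamma * beta_m`, where
#' `gamma` is a binary neuromodulation gate and `beta_m` the winner-take-all
#' gate.  Recalibration fires when the winning visual place cell's activity
#' exceeds `thr_abs` AND leads the runner-up by at least `thr_rel`.
#'
#' @param lambda base learning rate in [0, 1].
#' @param gamma binary neuromodulation gate (0 or 1).
#' @param thr_abs absolute recognition threshold in [0, 1].
#' @param thr_rel relative margin threshold in [0, 1].
#' @param eta visual weight of the multimodal fusion in [0, 1].
#' @return object of class `learning_params`.
#' @export
learning_params <- function(lambda = 0.5, gamma = 1, thr_abs = 0.7,
                            thr_rel = 0.15, eta = 0.5) {
  stopifnot(lambda >= 0, lambda <= 1, gamma %in% c(0, 1),
            thr_abs >= 0, thr_abs <= 1, thr_rel >= 0, thr_rel <= 1,
            eta >= 0, eta <= 1)
  structure(list(lambda = lambda, gamma = gamma, thr_abs = thr_abs,
                 thr_rel = thr_rel, eta = eta), class = "learning_params")
}

#' Place-cell bank
#'
#' Bank of visual place cells and their associated stores.  Each recruited
#' cell holds: the landmark-azimuth constellation observed at recruitment,
#' a copy of the PI field profile at recruitment (its recalibration target),
#' an optional associated action direction (for homing), and a row of NLMS
#' weights predicting its activity from the grid-cell pattern.
#'
#' @param n_grid_inputs length L of the grid pattern vector the NLMS
#'   prediction reads from (0 if prediction is not used).
#' @return empty bank of class `place_cell_bank`.
#' @export
place_cell_bank <- function(n_grid_inputs = 0) {
  structure(list(constellations = list(), profiles = list(),
                 actions = numeric(0),
                 W = matrix(0, 0, n_grid_inputs),
                 L = as.integer(n_grid_inputs)),
            class = "place_cell_bank")
}

n_cells <- function(bank) length(bank$constellations)

#' @export
print.place_cell_bank <- function(x, ...) {
  cat("Place-cell bank:", n_cells(x), "cells,",
      x$L, "grid inputs per cell\n")
  invisible(x)
}

#' Recruit a new visual place cell
#'
#' Stores the current landmark observation as the cell's constellation and a
#' verbatim copy of the current PI field as its recalibration profile.  The
#' first cell recruited after a reset therefore stores the PI zero state.
#' No deduplication is performed.
#'
#' @param bank a `place_cell_bank`.
#' @param observation data.frame with columns `appearance`, `azimuth` (as
#'   returned by [landmark_azimuths()]).
#' @param field the current `pi_field`.
#' @param action optional associated action direction in radians.
#' @return the grown bank.
#' @export
recruit_vpc <- function(bank, observation, field, action = NA_real_) {
  m <- n_cells(bank) + 1L
  bank$constellations[[m]] <- observation[, c("appearance", "azimuth")]
  bank$profiles[[m]] <- field$D
  bank$actions[m] <- action
  bank$W <- rbind(bank$W, rep(0, bank$L))
  bank
}

#' Visual place-cell activities
#'
#' Constellation matching: for each cell, the mean over its stored landmarks
#' of `exp(-d^2 / (2 sigma^2))`, where `d` is the wrapped azimuth difference
#' to the observed landmark with the same appearance (best match if several
#' are in view; 0 contribution for landmarks not in view).  Gaussian azimuth
#' tuning produces the broad, graded place fields characteristic of
#' landmark-bearing recognition.
#'
#' @param observation data.frame with columns `appearance`, `azimuth`.
#' @param bank a `place_cell_bank` with at least one recruited cell.
#' @param azimuth_sigma tuning SD in radians (default 10 degrees).
#' @return numeric vector of M activities in [0, 1].
#' @export
vpc_activity <- function(observation, bank, azimuth_sigma = 10 * pi / 180) {
  if (n_cells(bank) < 1) stop("bank has no recruited cells")
  if (nrow(observation) < 1) stop("observation is empty")
  vapply(bank$constellations, function(st) {
    sim <- vapply(seq_len(nrow(st)), function(i) {
      j <- which(observation$appearance == st$appearance[i])
      if (!length(j)) return(0)
      d <- abs(angle_diff(observation$azimuth[j], st$azimuth[i]))
      max(exp(-min(d)^2 / (2 * azimuth_sigma^2)))
    }, numeric(1))
    mean(sim)
  }, numeric(1))
}

#' Winner-take-all competition
#'
#' @param activities numeric vector (M >= 1).
#' @return list with `index` (argmax, ties to the lowest index) and `beta`
#'   (one-hot gate vector).
#' @export
wta_winner <- function(activities) {
  stopifnot(length(activities) >= 1)
  i <- which.max(activities)
  beta <- numeric(length(activities)); beta[i] <- 1
  list(index = i, beta = beta)
}

#' Predicted place-cell activities from grids
#'
#' Linear readout `PredVPC_m = sum_l w_ml G_l`, unrectified and unclipped.
#'
#' @param G grid pattern vector of length L.
#' @param bank a `place_cell_bank`.
#' @return numeric vector of M predicted activities.
#' @export
predict_vpc <- function(G, bank) {
  if (length(G) != bank$L) stop("grid pattern length does not match bank")
  as.numeric(bank$W %*% G)
}

#' Gated NLMS weight update
#'
#' Normalised least-mean-squares step on the winning cell only:
#' `w <- w + lambda * gamma * (VPC_m - PredVPC_m) * G / sum(G^2)`, with the
#' winner chosen by WTA on the VPC activities.  A zero-energy input
#' (`sum(G^2) = 0`) performs no update.
#'
#' @param bank a `place_cell_bank`.
#' @param G grid pattern vector used for the prediction.
#' @param VPC visual activities (the teaching signal).
#' @param params a `learning_params`.
#' @return the updated bank.
#' @export
nlms_update <- function(bank, G, VPC, params = learning_params()) {
  if (params$gamma == 0) return(bank)
  den <- sum(G^2)
  if (den == 0) return(bank)
  m <- wta_winner(VPC)$index
  err <- VPC[m] - sum(bank$W[m, ] * G)
  bank$W[m, ] <- bank$W[m, ] + params$lambda * err * G / den
  bank
}

#' Multimodal fusion
#'
#' Convex combination `MPC = eta * VPC + (1 - eta) * PredVPC` per cell.
#'
#' @param VPC,PredVPC activity vectors of equal length.
#' @param eta visual weight in [0, 1] (default 0.5: both sources equal).
#' @return multimodal activities.
#' @export
fuse_mpc <- function(VPC, PredVPC, eta = 0.5) {
  stopifnot(eta >= 0, eta <= 1, length(VPC) == length(PredVPC))
  eta * VPC + (1 - eta) * PredVPC
}

#' Recalibration trigger
#'
#' Fires when the winning visual place cell is confidently recognized: its
#' activity is at or above the absolute threshold AND (with at least two
#' cells) leads the second-best by at least the relative threshold.  On fire
#' the caller overwrites the PI field with the winner's stored profile.
#'
#' @param activities VPC activity vector.
#' @param params a `learning_params`.
#' @return list with `fire` (logical) and `winner` (index).
#' @export
recalibration_trigger <- function(activities, params = learning_params()) {
  w <- wta_winner(activities)
  mx <- activities[w$index]
  margin <- if (length(activities) >= 2)
    mx - max(activities[-w$index]) else Inf
  list(fire = (mx >= params$thr_abs) && (margin >= params$thr_rel),
       winner = w$index)
}

#' Associate an action direction with a place cell
#'
#' Place-action association used for homing: the stored direction is moved
#' toward the taught direction by an NLMS step on its (cos, sin) components
#' (rate 1 stores it one-shot).
#'
#' @param bank a `place_cell_bank`.
#' @param cell cell index.
#' @param direction taught direction in radians.
#' @param rate learning rate in (0, 1].
#' @return the updated bank.
#' @export
learn_place_action <- function(bank, cell, direction, rate = 1) {
  old <- bank$actions[cell]
  if (is.na(old) || rate >= 1) {
    bank$actions[cell] <- wrap_angle(direction)
  } else {
    v <- (1 - rate) * c(cos(old), sin(old)) +
      rate * c(cos(direction), sin(direction))
    bank$actions[cell] <- wrap_angle(atan2(v[2], v[1]))
  }
  bank
}

#' Homing heading command
#'
#' Recalls the action direction associated with the winning visual place
#' cell for the current view.  Repeated application from anywhere in the
#' learned attraction field drives the agent into the goal zone.
#'
#' @param bank a `place_cell_bank` with learned place-action associations.
#' @param pose list/vector with `x`, `y`.
#' @param arena an `arena_config`.
#' @param azimuth_sigma VPC tuning SD in radians.
#' @return commanded heading in radians.
#' @export
homing_controller <- function(bank, pose, arena,
                              azimuth_sigma = 10 * pi / 180) {
  if (n_cells(bank) < 1 || all(is.na(bank$actions)))
    stop("bank holds no place-action associations")
  obs <- landmark_azimuths(pose, arena, visible_only = TRUE)
  act <- vpc_activity(obs, bank, azimuth_sigma)
  act[is.na(bank$actions)] <- -Inf       # only cells with actions compete
  bank$actions[wta_winner(act)$index]
}

#' WTA place cells learned from grid patterns
#'
#' One-shot competitive learning: each cell stores the grid-population
#' pattern observed at its recruitment position.  Recognition is the mean
#' over layers of the cosine similarity between the stored and current layer
#' patterns, followed by WTA.  With binary one-hot layers the activity is the
#' fraction of layers whose phase matches, which along a straight crossing of
#' the learned position yields the characteristic descending stair (1, 2/3,
#' 1/3 for three layers).
#'
#' @param patterns list of grid pattern vectors (from [grid_pattern()]), one
#'   per recruited cell.
#' @param pop the `grid_population` the patterns came from.
#' @return object of class `grid_wta_bank`.
#' @export
learn_place_wta <- function(patterns, pop) {
  sizes <- vapply(pop, function(sp) sp$MG^2, numeric(1))
  stopifnot(all(vapply(patterns, length, numeric(1)) == sum(sizes)))
  structure(list(patterns = patterns, sizes = sizes),
            class = "grid_wta_bank")
}

#' @rdname learn_place_wta
#' @param bank a `grid_wta_bank`.
#' @param pattern current grid pattern vector.
#' @return `wta_place_activity`: numeric vector of cell activities in [0, 1].
#' @export
wta_place_activity <- function(bank, pattern) {
  ends <- cumsum(bank$sizes); starts <- c(1, utils::head(ends, -1) + 1)
  vapply(bank$patterns, function(st) {
    sims <- vapply(seq_along(bank$sizes), function(l) {
      i <- starts[l]:ends[l]
      a <- st[i]; b <- pattern[i]
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
    }, numeric(1))
    mean(sims)
  }, numeric(1))
}

#' Serialize / restore a place-cell bank (JSON)
#'
#' Plain-text round trip of every store in the bank (constellations, PI
#' profiles, actions, NLMS weights), so learned banks can be reused across
#' runs.
#'
#' @param bank a `place_cell_bank`.
#' @param path file path.
#' @return `read_bank` returns the restored `place_cell_bank`.
#' @export
write_bank <- function(bank, path) {
  obj <- list(L = bank$L,
              constellations = bank$constellations,
              profiles = bank$profiles,
              actions = bank$actions,
              W = if (nrow(bank$W)) unclass(as.data.frame(t(bank$W))) else list())
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bank <- place_cell_bank(obj$L)
  # equal-length profile vectors may come back simplified into a matrix
  profiles <- if (is.matrix(obj$profiles))
    lapply(seq_len(nrow(obj$profiles)), function(i) obj$profiles[i, ])
  else lapply(obj$profiles, as.numeric)
  m <- length(profiles)
  if (m) {
    bank$constellations <- lapply(obj$constellations, function(d) {
      d <- as.data.frame(d)
      rownames(d) <- NULL
      d
    })
    bank$profiles <- profiles
    bank$actions <- as.numeric(obj$actions)
    W <- t(as.matrix(as.data.frame(obj$W)))   # stored column-per-cell
    dimnames(W) <- NULL
    bank$W <- W
  }
  bank
}
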
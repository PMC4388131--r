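#' Arena configuration
#'
#' Describes the environment the simulated agent moves in: a simple polygonal
#' boundary, a set of point landmarks used by the visual place-cell front end,
#' and a goal (recalibration) location with a detection radius.
#'
#' Landmarks have a unique `id` and an `appearance` label.  Two landmarks that
#' look alike (e.g. the same furniture in two visually similar rooms) share an
#' appearance while keeping distinct ids; observations report appearances,
#' which is what makes perceptually ambiguous environments reproducible.
#'
#' @param boundary n x 2 numeric matrix of polygon vertices (metres, world
#'   frame), in order, not closed (the last vertex connects back to the first).
#' @param landmarks data.frame with columns `id`, `x`, `y` and optionally
#'   `appearance` (defaults to `id`).
#' @param goal length-2 numeric, goal position (metres).
#' @param goal_radius goal-detection radius in metres.
#' @param avoid_dist wall-avoidance trigger distance in metres (the surrogate
#'   for the robot's proximity sensors).
#' @return an object of class `arena_config`.
#' @export
arena_config <- function(boundary, landmarks = NULL, goal = NULL,
                         goal_radius = 0.15, avoid_dist = 0.4) {
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2 || nrow(boundary) < 3)
    stop("boundary must be an n x 2 matrix with n >= 3")
  if (abs(polygon_area(boundary)) < 1e-12)
    stop("degenerate arena: boundary has zero area")
  if (polygon_area(boundary) < 0)           # enforce counter-clockwise order
    boundary <- boundary[nrow(boundary):1, , drop = FALSE]
  if (is.null(landmarks)) {
    landmarks <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                            appearance = integer(0))
  } else {
    landmarks <- as.data.frame(landmarks)
    if (!all(c("id", "x", "y") %in% names(landmarks)))
      stop("landmarks needs columns id, x, y")
    if (anyDuplicated(landmarks$id)) stop("landmark ids must be unique")
    if (is.null(landmarks$appearance)) landmarks$appearance <- landmarks$id
  }
  if (is.null(goal)) goal <- polygon_centroid(boundary)
  if (!point_in_polygon(goal[1], goal[2], boundary))
    stop("goal must lie inside the boundary")
  if (goal_radius <= 0) stop("goal_radius must be > 0")
  structure(list(boundary = boundary, landmarks = landmarks,
                 goal = as.numeric(goal), goal_radius = goal_radius,
                 avoid_dist = avoid_dist),
            class = "arena_config")
}

#' Hexagonal arena
#'
#' Regular hexagonal enclosure (flat diameter given in metres) with landmarks
#' at the six vertices, emulating the enclosure used for the grid-cell
#' experiments.
#'
#' @param diameter corner-to-corner diameter in metres (default 4).
#' @param goal_radius goal-detection radius in metres.
#' @inheritParams arena_config
#' @return an `arena_config`.
#' @export
hex_arena <- function(diameter = 4, goal_radius = 0.15, avoid_dist = 0.4) {
  r <- diameter / 2
  ang <- 2 * pi * (0:5) / 6
  boundary <- cbind(r * cos(ang), r * sin(ang))
  lm <- data.frame(id = 1:6,
                   x = 0.98 * r * cos(ang), y = 0.98 * r * sin(ang))
  arena_config(boundary, lm, goal = c(0, 0), goal_radius = goal_radius,
               avoid_dist = avoid_dist)
}

#' Two rooms connected by a corridor
#'
#' Multi-room environment for the place-cell experiments: two visually
#' similar rooms joined by a narrow corridor.  Landmarks in the second room
#' repeat the appearances of the first room's landmarks (mirror layout), so a
#' purely visual recognizer is exposed to perceptual aliasing; the corridor
#' has its own distinctive landmarks.
#'
#' @param room width/height of each square room in metres.
#' @param corridor_len,corridor_w corridor length and width in metres.
#' @return an `arena_config`.  The overall extent is
#'   `2 * room + corridor_len` by `room` metres.
#' @export
two_room_arena <- function(room = 7, corridor_len = 9, corridor_w = 2) {
  h <- room; L <- corridor_len; w <- corridor_w
  y0 <- (h - w) / 2; y1 <- (h + w) / 2
  # Outline: left room, corridor slot, right room (counter-clockwise).
  boundary <- rbind(
    c(0, 0), c(h, 0), c(h, y0), c(h + L, y0), c(h + L, 0),
    c(2 * h + L, 0), c(2 * h + L, h), c(h + L, h), c(h + L, y1),
    c(h, y1), c(h, h), c(0, h))
  m <- h / 2
  room1 <- data.frame(id = 1:5,
                      x = c(0.1 * h, 0.9 * h, 0.1 * h, 0.5 * h, 0.85 * h),
                      y = c(0.1 * h, 0.9 * h, 0.9 * h, 0.05 * h, 0.15 * h),
                      appearance = 1:5)
  # Repeated layout in room 2: four landmarks share the room-1 appearances
  # (shifted by a fixed few tens of centimetres, as similar rooms are never
  # pixel-identical) plus one room-specific landmark, so visual aliasing is
  # strong but each room keeps a distinctive cue.
  xoff <- h + L
  room2 <- data.frame(id = 6:10,
                      x = xoff + c(0.1 * h, 0.9 * h, 0.1 * h, 0.5 * h,
                                   0.85 * h) + c(0.3, -0.25, 0.2, -0.3, 0),
                      y = c(0.1 * h, 0.9 * h, 0.9 * h, 0.05 * h, 0.15 * h) +
                        c(-0.2, 0.3, 0.25, 0.2, 0),
                      appearance = c(1:4, 6))
  corr <- data.frame(id = 11:12,
                     x = c(h + 0.25 * L, h + 0.75 * L), y = c(m, m) + 0.4 * w,
                     appearance = 11:12)
  arena_config(boundary, rbind(room1, room2, corr),
               goal = c(m, m), goal_radius = 0.15)
}

#' @export
print.arena_config <- function(x, ...) {
  cat("Arena:", nrow(x$boundary), "boundary vertices, area",
      sprintf("%.2f m^2", abs(polygon_area(x$boundary))), "\n")
  cat("  landmarks:", nrow(x$landmarks),
      " goal: (", sprintf("%.2f, %.2f", x$goal[1], x$goal[2]),
      ") radius", x$goal_radius, "m\n")
  invisible(x)
}

#' Allocentric landmark azimuths
#'
#' World-referenced (compass) azimuth of every landmark as seen from a pose,
#' wrapped to `[0, 2*pi)`.  Azimuth 0 is due east (+x), `pi/2` due north.
#'
#' @param pose list or vector with elements/names `x`, `y`.
#' @param arena an `arena_config` with at least one landmark.
#' @param visible_only if `TRUE`, drop landmarks whose line of sight to the
#'   agent crosses a wall.
#' @return data.frame with columns `id`, `appearance`, `azimuth`.
#' @export
landmark_azimuths <- function(pose, arena, visible_only = FALSE) {
  lm <- arena$landmarks
  if (nrow(lm) < 1) stop("arena has no landmarks")
  px <- pose[["x"]]; py <- pose[["y"]]
  az <- wrap_angle(atan2(lm$y - py, lm$x - px))
  out <- data.frame(id = lm$id, appearance = lm$appearance, azimuth = az)
  if (visible_only) {
    vis <- !vapply(seq_len(nrow(lm)), function(i)
      segment_blocked(px, py, lm$x[i], lm$y[i], arena$boundary), logical(1))
    out <- out[vis, , drop = FALSE]
  }
  out
}
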
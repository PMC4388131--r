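#' Wrap angles to [0, 2*pi)
#'
#' @param a numeric vector of angles in radians.
#' @return angles wrapped to `[0, 2*pi)`.
#' @export
wrap_angle <- function(a) a %% (2 * pi)

#' Smallest signed angular difference
#'
#' Difference `a - b` mapped to `(-pi, pi]`.
#'
#' @param a,b angles in radians.
#' @return signed difference in radians.
#' @export
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Shoelace area of a polygon given as an n x 2 matrix (signed).
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Ray-casting point-in-polygon; px, py may be vectors.  Points on an edge
# count as inside for our purposes (containment checks on closed arenas).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  inside <- logical(length(px))
  for (k in seq_len(n)) {
    crosses <- ((y1[k] > py) != (y2[k] > py)) &
      (px < (x2[k] - x1[k]) * (py - y1[k]) / (y2[k] - y1[k]) + x1[k])
    inside <- xor(inside, crosses)
  }
  inside
}

# Minimum distance from point (px, py) to the polygon boundary.
boundary_distance <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  qx <- x1 + t * dx; qy <- y1 + t * dy
  min(sqrt((px - qx)^2 + (py - qy)^2))
}

# TRUE if open segment (ax,ay)-(bx,by) properly intersects any polygon edge.
# Used for line-of-sight tests; touching at an endpoint does not count.
segment_blocked <- function(ax, ay, bx, by, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  rx <- bx - ax; ry <- by - ay
  sx <- x2 - x1; sy <- y2 - y1
  denom <- rx * sy - ry * sx
  ok <- abs(denom) > 1e-12
  t <- ((x1 - ax) * sy - (y1 - ay) * sx) / denom
  u <- ((x1 - ax) * ry - (y1 - ay) * rx) / denom
  eps <- 1e-9
  any(ok & t > eps & t < 1 - eps & u > eps & u < 1 - eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
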
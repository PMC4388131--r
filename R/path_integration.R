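#' Direction-coded input field
#'
#' Ring of `N` neurons with preferred directions `theta_i = -2*pi*i/N`
#' (i = 0..N-1).  Given a movement direction `phi`, each neuron fires with a
#' cosine tuning curve; in the literal (`as_printed`) variant the activity is
#' `1 + cos(phi - theta_i)` (range [0, 2]); in the `signed_projection` variant
#' it is the raw cosine, i.e. the projection of the unit displacement onto the
#' neuron's preferred direction.
#'
#' @param N neuron count (default 60).
#' @return object of class `direction_field` with elements `N` and `theta`.
#' @export
direction_field <- function(N = 60) {
  stopifnot(N >= 2)
  structure(list(N = as.integer(N), theta = -2 * pi * (0:(N - 1)) / N),
            class = "direction_field")
}

#' Direction-field activities for a heading
#'
#' @param phi movement direction in radians.
#' @param field a `direction_field`.
#' @param mode `"as_printed"` (1 + cos) or `"signed_projection"` (cos).
#' @return numeric vector of N activities.
#' @export
direction_activity <- function(phi, field,
                               mode = c("as_printed", "signed_projection")) {
  mode <- match.arg(mode)
  v <- cos(phi - field$theta)
  if (mode == "as_printed") 1 + v else v
}

#' Path-integration neural field
#'
#' One-dimensional circular field of `N` neurons accumulating direction-tuned
#' displacement.  At every step each neuron adds `alpha * (step / meters_per_unit)`
#' times its direction-field activity.  Two accumulation modes are provided:
#'
#' * `as_printed`: the literal update `D <- [D + alpha*V]+` with
#'   `V = 1 + cos`, rectified at 0 and clamped at `D_max`.  The "1 +" term
#'   adds total path length to every neuron, so single-neuron values are
#'   path-dependent.
#' * `signed_projection` (default): `V = cos`, signed accumulation stored
#'   with a fixed offset `D_max/2` so values stay in `[0, D_max]`.  Each
#'   neuron then holds (a scaled version of) the net displacement projected
#'   onto its preferred direction — a pure function of position, the regime
#'   in which periodic grid patterns are attainable.
#'
#' The field is dimensionless; `range_m` sets the span of displacement it can
#' represent (default 8 m, twice a 4 m arena diameter), fixing
#' `meters_per_unit = alpha * range_m / D_max`.
#'
#' @param N neuron count (default 60).
#' @param alpha per-step gain, 0 < alpha < 1 (default 0.01).
#' @param D_max field ceiling (default 1).
#' @param mode `"signed_projection"` or `"as_printed"`.
#' @param range_m displacement span in metres the field must represent.
#' @return object of class `pi_field`.
#' @export
pi_field <- function(N = 60, alpha = 0.01, D_max = 1,
                     mode = c("signed_projection", "as_printed"),
                     range_m = 8) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, D_max > 0, range_m > 0)
  dirs <- direction_field(N)
  f <- structure(list(N = dirs$N, theta = dirs$theta, alpha = alpha,
                      D_max = D_max, mode = mode,
                      meters_per_unit = alpha * range_m / D_max,
                      D = numeric(dirs$N)),
                 class = "pi_field")
  reset_pi(f)
}

pi_zero_level <- function(field)
  if (field$mode == "signed_projection") field$D_max / 2 else 0

#' @export
print.pi_field <- function(x, ...) {
  cat("PI field:", x$N, "neurons, mode", x$mode,
      sprintf("(alpha %.3g, D_max %.3g, %.3g m per unit span)\n",
              x$alpha, x$D_max, x$meters_per_unit / x$alpha * x$D_max))
  invisible(x)
}

#' Integrate one displacement step into the PI field
#'
#' @param field a `pi_field`.
#' @param heading movement direction in radians.
#' @param step displacement length in metres (>= 0).
#' @return the updated `pi_field`.
#' @export
update_pi <- function(field, heading, step) {
  stopifnot(step >= 0)
  u <- field$alpha * (step / field$meters_per_unit)
  if (field$mode == "as_printed") {
    v <- 1 + cos(heading - field$theta)
    field$D <- pmin(field$D_max, pmax(0, field$D + u * v))
  } else {
    v <- cos(heading - field$theta)
    field$D <- pmin(field$D_max, pmax(0, field$D + u * v))
  }
  field
}

#' Reset the PI field to its zero state
#'
#' Zero state is all-zeros in `as_printed` mode and the mid-range offset
#' `D_max/2` in `signed_projection` mode.
#'
#' @param field a `pi_field`.
#' @return the reset field.
#' @export
reset_pi <- function(field) {
  field$D <- rep(pi_zero_level(field), field$N)
  field
}

#' Overwrite the PI field with a stored profile
#'
#' Recalibration primitive: forces the neuron activities to a previously
#' learned state (e.g. the profile stored when a visual place cell was
#' recruited).
#'
#' @param field a `pi_field`.
#' @param profile numeric vector of length N with values in `[0, D_max]`.
#' @return the updated field.
#' @export
set_pi <- function(field, profile) {
  if (length(profile) != field$N)
    stop("profile length must equal the field size N")
  if (any(profile < -1e-9 | profile > field$D_max + 1e-9))
    stop("profile values must lie in [0, D_max]")
  field$D <- pmin(field$D_max, pmax(0, as.numeric(profile)))
  field
}

#' Position-derived PI profile (signed mode)
#'
#' The signed-projection field state an error-free integrator would hold at
#' displacement `p` from the origin of integration: offset plus the scaled
#' projection of `p` onto each preferred direction.  Used to seed
#' recalibration profiles and as the position-purity oracle.
#'
#' @param field a signed-mode `pi_field`.
#' @param p length-2 numeric displacement in metres.
#' @return numeric profile of length N.
#' @export
pi_profile_at <- function(field, p) {
  if (field$mode != "signed_projection")
    stop("position-derived profiles are defined for signed_projection mode")
  proj <- p[1] * cos(field$theta) + p[2] * sin(field$theta)
  prof <- field$D_max / 2 + field$alpha * proj / field$meters_per_unit
  if (any(prof < 0 | prof > field$D_max))
    stop("position outside the displacement range of the field")
  prof
}

#' Home-vector readout
#'
#' The most active neuron points along the net movement direction and its
#' activity above the zero level is proportional to the distance travelled
#' from the last reset.
#'
#' @param field a `pi_field`.
#' @return list with `direction` (radians), `distance` (metres) and
#'   `degenerate` (TRUE for a flat field, where the direction is undefined).
#' @export
readout_home_vector <- function(field) {
  lvl <- field$D - pi_zero_level(field)
  i <- which.max(lvl)
  flat <- diff(range(lvl)) < 1e-12
  list(direction = if (flat) NA_real_ else wrap_angle(field$theta[i]),
       distance = max(0, lvl[i]) * field$meters_per_unit / field$alpha,
       degenerate = flat)
}

#' Vectorised PI trace along a path
#'
#' Integrates a whole sequence of (heading, step) samples at once and returns
#' the field state after every step.  In signed mode this is an exact cumsum
#' (valid as long as the path stays inside the representable range, where the
#' clamp never engages); in as_printed mode the rectified update is applied
#' sequentially.
#'
#' @param field a `pi_field`.
#' @param headings,steps numeric vectors (radians, metres) of equal length.
#' @param neurons optional integer vector restricting the output to a subset
#'   of neurons (1-based).
#' @return matrix of dim `length(steps) x length(neurons)` of field values.
#' @export
pi_trace <- function(field, headings, steps, neurons = seq_len(field$N)) {
  stopifnot(length(headings) == length(steps))
  u <- field$alpha * steps / field$meters_per_unit
  th <- field$theta[neurons]
  if (field$mode == "signed_projection") {
    inc <- outer(headings, th, function(h, t) cos(h - t)) * u
    D0 <- field$D[neurons]
    out <- sweep(apply(inc, 2, cumsum), 2, D0, "+")
    if (length(steps) == 1) out <- matrix(out, nrow = 1)
    if (any(out < -1e-9 | out > field$D_max + 1e-9))
      warning("path leaves the representable range; clamping engaged")
    out[] <- pmin(field$D_max, pmax(0, out))
    out
  } else {
    out <- matrix(0, length(steps), length(neurons))
    f <- field
    for (k in seq_along(steps)) {
      f <- update_pi(f, headings[k], steps[k])
      out[k, ] <- f$D[neurons]
    }
    out
  }
}

#' Export / import a PI state snapshot as CSV
#'
#' CSV of N rows with columns `index`, `theta`, `D` — the interchange format
#' for recalibration profiles and debugging.
#'
#' @param field a `pi_field`.
#' @param path file path.
#' @return `read_pi_csv` returns the profile as a numeric vector.
#' @export
write_pi_csv <- function(field, path) {
  utils::write.csv(data.frame(index = seq_len(field$N) - 1L,
                              theta = field$theta, D = field$D),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pi_csv
#' @export
read_pi_csv <- function(path) utils::read.csv(path)$D
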
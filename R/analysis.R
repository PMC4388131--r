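# Spatial analysis pipeline: occupancy-normalised rate maps, masked Pearson
# spatial autocorrelograms, rotational-correlation curves, gridness.

#' Occupancy-normalised rate map
#'
#' Bins per-sample activity over square spatial bins, divides by occupancy,
#' and (optionally) applies mask-aware Gaussian smoothing.  Bins never
#' visited are masked (`NA`), not zero.
#'
#' @param x,y sample positions in metres (or a `trajectory` as `x`).
#' @param activity per-sample activity values aligned with the positions.
#' @param bin bin size in metres (default 0.05).
#' @param smooth_sigma Gaussian smoothing SD in metres (default 0.05; 0
#'   disables smoothing).
#' @param xlim,ylim optional extents; default spans the data.
#' @return object of class `rate_map`: `rate` (matrix, rows = x bins),
#'   `occupancy`, `mask`, `bin`, `xlim`, `ylim`.
#' @export
rate_map <- function(x, y = NULL, activity, bin = 0.05, smooth_sigma = 0.05,
                     xlim = NULL, ylim = NULL) {
  if (inherits(x, "trajectory")) { y <- x$y; x <- x$x }
  stopifnot(length(x) == length(y), length(x) == length(activity))
  if (!length(x)) stop("empty trajectory")
  if (is.null(xlim)) xlim <- range(x)
  if (is.null(ylim)) ylim <- range(y)
  nx <- max(1L, ceiling(diff(xlim) / bin))
  ny <- max(1L, ceiling(diff(ylim) / bin))
  ix <- pmin(nx, pmax(1L, 1L + floor((x - xlim[1]) / bin)))
  iy <- pmin(ny, pmax(1L, 1L + floor((y - ylim[1]) / bin)))
  idx <- (iy - 1L) * nx + ix
  occ <- tabulate(idx, nbins = nx * ny)
  s <- numeric(nx * ny)
  agg <- rowsum(activity, idx)
  s[as.integer(rownames(agg))] <- agg[, 1]
  occ <- matrix(occ, nx, ny)
  rate <- matrix(ifelse(occ > 0, s / pmax(occ, 1), NA_real_), nx, ny)
  mask <- occ > 0
  if (smooth_sigma > 0) rate <- smooth_masked(rate, mask, smooth_sigma / bin)
  structure(list(rate = rate, occupancy = occ, mask = mask, bin = bin,
                 xlim = xlim, ylim = ylim),
            class = "rate_map")
}

# Mask-aware separable Gaussian smoothing (sigma in bins).
smooth_masked <- function(rate, mask, sigma_bins) {
  if (sigma_bins <= 0) return(rate)
  r <- max(1L, ceiling(3 * sigma_bins))
  k <- exp(-(-r:r)^2 / (2 * sigma_bins^2)); k <- k / sum(k)
  f <- rate; f[!mask] <- 0
  w <- matrix(as.numeric(mask), nrow(rate), ncol(rate))
  conv1 <- function(m, along) {
    out <- matrix(0, nrow(m), ncol(m))
    n <- if (along == 1) nrow(m) else ncol(m)
    for (o in -r:r) {
      src <- pmin(n, pmax(1L, seq_len(n) + o))     # clamped borders
      out <- out + (if (along == 1) m[src, , drop = FALSE]
                    else m[, src, drop = FALSE]) * k[o + r + 1]
    }
    out
  }
  num <- conv1(conv1(f, 1), 2)
  den <- conv1(conv1(w, 1), 2)
  sm <- num / pmax(den, 1e-12)
  sm[!mask] <- NA_real_
  sm
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("Rate map: %d x %d bins of %.3g m, %.0f%% visited, peak %.3g\n",
              nrow(x$rate), ncol(x$rate), x$bin, 100 * mean(x$mask),
              max(x$rate, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.rate_map <- function(x, ...) {
  graphics::image(seq(x$xlim[1], by = x$bin, length.out = nrow(x$rate)),
                  seq(x$ylim[1], by = x$bin, length.out = ncol(x$rate)),
                  x$rate, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

# Full cross-correlation sums C(d) = sum_x A(x) B(x+d) over all integer lags,
# via zero-padded FFTs.  Returns a (2*nr-1) x (2*nc-1) matrix with lag (0,0)
# at the centre.
xcorr_sums <- function(A, B) {
  nr <- nrow(A); nc <- ncol(A)
  P <- 2 * nr; Q <- 2 * nc
  pad <- function(M) { Z <- matrix(0, P, Q); Z[1:nr, 1:nc] <- M; Z }
  Z <- Re(stats::fft(Conj(stats::fft(pad(A))) * stats::fft(pad(B)),
                     inverse = TRUE)) / (P * Q)
  d1 <- -(nr - 1):(nr - 1); d2 <- -(nc - 1):(nc - 1)
  Z[(d1 %% P) + 1, (d2 %% Q) + 1, drop = FALSE]
}

#' Spatial autocorrelogram
#'
#' Pearson correlation of the rate map with itself at every 2D lag, computed
#' over the overlapping unmasked bins only; lags with fewer than
#' `min_overlap` overlapping bins (or with degenerate variance) are `NA`.
#' The result spans twice the map extent per axis, holds 1 at zero lag and
#' is symmetrised so its point-reflection symmetry is exact.
#'
#' @param map a `rate_map`.
#' @param min_overlap minimum number of overlapping bins per lag.
#' @return object of class `autocorrelogram`: `ac` matrix in `[-1, 1]`,
#'   `bin` (metres).
#' @export
spatial_autocorrelation <- function(map, min_overlap = 20) {
  f <- map$rate; m <- map$mask & is.finite(f)
  if (sum(m) < 2) stop("need at least 2 unmasked bins")
  f[!m] <- 0
  w <- matrix(as.numeric(m), nrow(f), ncol(f))
  n   <- round(xcorr_sums(w, w))
  Sx  <- xcorr_sums(f, w)
  Sy  <- xcorr_sums(w, f)
  Sxy <- xcorr_sums(f, f)
  Sxx <- xcorr_sums(f^2, w)
  Syy <- xcorr_sums(w, f^2)
  num <- n * Sxy - Sx * Sy
  v1 <- n * Sxx - Sx^2
  v2 <- n * Syy - Sy^2
  den <- sqrt(pmax(v1, 0) * pmax(v2, 0))
  ac <- ifelse(n >= min_overlap & den > 1e-9 * pmax(n, 1)^2, num / den, NA_real_)
  ac[] <- pmin(1, pmax(-1, ac))
  acr <- ac[nrow(ac):1, ncol(ac):1]               # point reflection
  both <- !is.na(ac) & !is.na(acr)
  sym <- ifelse(both, (ac + acr) / 2, NA_real_)   # exact even symmetry
  structure(list(ac = sym, bin = map$bin), class = "autocorrelogram")
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat(sprintf("Autocorrelogram: %d x %d lags, bin %.3g m\n",
              nrow(x$ac), ncol(x$ac), x$bin))
  invisible(x)
}

#' @export
plot.autocorrelogram <- function(x, ...) {
  n <- nrow(x$ac); m <- ncol(x$ac)
  graphics::image((-(n - 1) / 2):((n - 1) / 2) * x$bin,
                  (-(m - 1) / 2):((m - 1) / 2) * x$bin,
                  x$ac, asp = 1, xlab = "lag x (m)", ylab = "lag y (m)",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  zlim = c(-1, 1), ...)
  invisible(x)
}

# Radial mean profile of the autocorrelogram; radii in bins.
radial_profile <- function(ac) {
  n <- nrow(ac); m <- ncol(ac)
  cx <- (n + 1) / 2; cy <- (m + 1) / 2
  rr <- sqrt(outer((seq_len(n) - cx)^2, (seq_len(m) - cy)^2, "+"))
  r <- as.integer(round(rr))
  ok <- !is.na(ac)
  prof <- tapply(ac[ok], r[ok], mean)
  list(radius = as.integer(names(prof)), value = as.numeric(prof))
}

# First zero crossing of the radial profile (central-peak radius, bins).
central_peak_radius <- function(ac) {
  p <- radial_profile(ac)
  i <- which(p$value <= 0)
  if (!length(i)) return(max(2, min(dim(ac)) / 10))
  max(2, p$radius[min(i)])
}

# Bilinear sample of matrix M at fractional (row, col) coordinates.
bilinear <- function(M, ri, ci) {
  n <- nrow(M); m <- ncol(M)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  ok <- r0 >= 1 & r0 + 1 <= n & c0 >= 1 & c0 + 1 <= m
  val <- rep(NA_real_, length(ri))
  if (!any(ok)) return(val)
  i00 <- (c0[ok] - 1) * n + r0[ok]
  v00 <- M[i00]; v10 <- M[i00 + 1]
  v01 <- M[i00 + n]; v11 <- M[i00 + n + 1]
  v <- v00 * (1 - fr[ok]) * (1 - fc[ok]) + v10 * fr[ok] * (1 - fc[ok]) +
    v01 * (1 - fr[ok]) * fc[ok] + v11 * fr[ok] * fc[ok]
  val[ok] <- v
  val
}

#' Rotational-correlation curve
#'
#' Pearson correlation between the autocorrelogram and its rotation about
#' the centre, for angles 0 to 180 degrees in `step`-degree increments,
#' restricted to a circular annulus that excludes the central peak (inner
#' radius = first zero crossing of the radial profile, outer radius = the
#' largest circle fitting the matrix).  0 degrees correlates the map with
#' itself (exactly 1); 180 degrees is computed by exact point reflection, so
#' the mirror-symmetry identity holds to machine precision.  Other angles
#' use bilinear interpolation.
#'
#' @param acobj an `autocorrelogram`.
#' @param step angular step in degrees (default 1).
#' @return object of class `rotation_curve`: `angle_deg`, `r`, plus the
#'   annulus radii in bins.
#' @export
rotational_correlation <- function(acobj, step = 1) {
  ac <- acobj$ac
  n <- nrow(ac); m <- ncol(ac)
  cx <- (n + 1) / 2; cy <- (m + 1) / 2
  r_in <- central_peak_radius(ac)
  r_out <- (min(n, m) - 1) / 2
  rr <- sqrt(outer((seq_len(n) - cx)^2, (seq_len(m) - cy)^2, "+"))
  sel <- which(rr >= r_in & rr <= r_out & !is.na(ac))
  ri <- ((sel - 1) %% n) + 1
  ci <- ((sel - 1) %/% n) + 1
  base <- ac[sel]
  angles <- seq(0, 180, by = step)
  out <- numeric(length(angles))
  for (k in seq_along(angles)) {
    a <- angles[k]
    if (a == 0) { out[k] <- 1; next }
    if (a == 180) {
      rot <- ac[n:1, m:1]                # exact index flip
      v <- rot[sel]
      ok <- !is.na(v)
      # the symmetrised autocorrelogram is its own point reflection, so the
      # correlation is 1 by identity; computing it would only add round-off
      out[k] <- if (all(v[ok] == base[ok])) 1 else stats::cor(base[ok], v[ok])
      next
    }
    th <- a * pi / 180
    dx <- ri - cx; dy <- ci - cy
    rx <- cos(th) * dx - sin(th) * dy + cx
    ry <- sin(th) * dx + cos(th) * dy + cy
    v <- bilinear(ac, rx, ry)
    ok <- !is.na(v)
    out[k] <- if (sum(ok) > 10) stats::cor(base[ok], v[ok]) else NA_real_
  }
  structure(list(angle_deg = angles, r = out,
                 r_inner = r_in, r_outer = r_out),
            class = "rotation_curve")
}

#' @export
plot.rotation_curve <- function(x, ...) {
  graphics::plot(x$angle_deg, x$r, type = "l", xlab = "rotation (deg)",
                 ylab = "Pearson r", ylim = c(-1, 1), ...)
  graphics::abline(v = c(30, 60, 90, 120, 150), lty = 3, col = "grey")
  invisible(x)
}

#' Local maxima of a rotational-correlation curve
#'
#' Peak detection with a prominence filter: strict local maxima whose height
#' above the deeper of the two flanking valleys is at least
#' `min_prominence`, so the small interpolation ripples of a flat curve
#' segment are not counted as periodicity peaks.
#'
#' @param curve a `rotation_curve`.
#' @param min_prominence minimum peak prominence (correlation units).
#' @param range angular range (degrees) the peaks must fall in, endpoints
#'   excluded (default the open interval (30, 180)).
#' @return numeric vector of peak angles in degrees.
#' @export
curve_peaks <- function(curve, min_prominence = 0.1, range = c(30, 180)) {
  a <- curve$angle_deg; r <- curve$r
  n <- length(r)
  cand <- which(diff(sign(diff(r))) < 0) + 1
  keep <- vapply(cand, function(i) {
    # valley depth until a higher point (or the end) on each side
    left <- i; while (left > 1 && r[left] <= r[i]) left <- left - 1
    right <- i; while (right < n && r[right] <= r[i]) right <- right + 1
    lv <- min(r[left:i]); rv <- min(r[i:right])
    (r[i] - max(lv, rv)) >= min_prominence
  }, logical(1))
  pk <- a[cand[keep]]
  pk[pk > range[1] & pk < range[2]]
}

#' Gridness score
#'
#' Rotational-symmetry statistic of the autocorrelogram:
#' `min(r(60), r(120)) - max(r(30), r(90), r(150))`, in `[-2, 2]`.  Positive
#' scores indicate six-fold (hexagonal) symmetry; stripe patterns score
#' negative.  A degenerate (flat or undefined) curve reports 0 with a flag.
#'
#' @param curve a `rotation_curve` (must cover 30..150 degrees).
#' @return object of class `gridness_result`: `score`, `degenerate`, and the
#'   five correlation values used.
#' @export
gridness <- function(curve) {
  at <- function(a) {
    i <- which.min(abs(curve$angle_deg - a))
    curve$r[i]
  }
  vals <- c(r30 = at(30), r60 = at(60), r90 = at(90),
            r120 = at(120), r150 = at(150))
  degen <- any(!is.finite(vals)) ||
    stats::sd(curve$r[is.finite(curve$r)]) < 1e-12
  score <- if (degen) 0 else
    min(vals["r60"], vals["r120"]) - max(vals["r30"], vals["r90"], vals["r150"])
  structure(list(score = unname(score), degenerate = degen, values = vals),
            class = "gridness_result")
}

#' @export
print.gridness_result <- function(x, ...) {
  cat(sprintf("Gridness: %.3f%s\n", x$score,
              if (x$degenerate) " (degenerate autocorrelogram)" else ""))
  invisible(x)
}

#' Full gridness pipeline from a rate map
#'
#' Convenience wrapper: autocorrelogram, rotational-correlation curve (1-deg
#' steps) and gridness score in one call.
#'
#' @param map a `rate_map`.
#' @param min_overlap passed to [spatial_autocorrelation()].
#' @return a `gridness_result` with the `autocorr` and `curve` attached.
#' @export
gridness_from_ratemap <- function(map, min_overlap = 20) {
  ac <- spatial_autocorrelation(map, min_overlap)
  curve <- rotational_correlation(ac)
  g <- gridness(curve)
  g$autocorr <- ac
  g$curve <- curve
  g
}

#' Place-field width along a 1D crossing
#'
#' Width of the contiguous region around the activity peak where activity
#' stays at or above `threshold * peak`.
#'
#' @param distance positions along the path (monotone, metres or abstract
#'   units).
#' @param activity activity samples aligned with `distance`.
#' @param threshold fraction of the peak (default 0.5).
#' @return width in the units of `distance` (0 if nothing crosses the
#'   threshold).
#' @export
place_field_width <- function(distance, activity, threshold = 0.5) {
  stopifnot(length(distance) == length(activity))
  pk <- max(activity)
  if (pk <= 0) return(0)
  above <- activity >= threshold * pk
  if (!any(above)) return(0)
  i <- which.max(activity)
  lo <- i; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i; while (hi < length(above) && above[hi + 1]) hi <- hi + 1
  abs(distance[hi] - distance[lo])
}

#' Export analysis products as CSV
#'
#' `write_matrix_csv` writes a rate map or autocorrelogram matrix as CSV with
#' a small JSON sidecar (`<path>.json`) holding bin size and extent;
#' `write_curve_csv` writes a rotational-correlation curve with columns
#' `angle_deg`, `pearson_r`.
#'
#' @param x a `rate_map`, `autocorrelogram` or `rotation_curve`.
#' @param path output CSV path.
#' @export
write_matrix_csv <- function(x, path) {
  M <- if (inherits(x, "rate_map")) x$rate else x$ac
  utils::write.table(M, path, sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(bin = x$bin, class = class(x)[1],
               xlim = x$xlim %||% NULL, ylim = x$ylim %||% NULL,
               na_encoding = "NA")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
write_curve_csv <- function(x, path) {
  utils::write.csv(data.frame(angle_deg = x$angle_deg, pearson_r = x$r),
                   path, row.names = FALSE)
  invisible(path)
}
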
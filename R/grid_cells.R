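#' Grid-layer specification
#'
#' One layer of grid cells is built from a pair of PI neurons: each neuron's
#' analogue value is discretized over `N_E` bins, the bin index is compressed
#' by `mod MG`, and the conjunction of the two residues yields an `MG x MG`
#' torus of phase cells.  The angular separation of the paired preferred
#' directions sets the lattice geometry (60 degrees gives a hexagonal
#' lattice), the modulo sets the spacing, and the residue pair is the phase.
#'
#' @param MG modulo (integer, `1 < MG <= N_E`).
#' @param pair length-2 integer, 1-based indices of the paired PI neurons.
#' @param N_E discretization bin count (default 60).
#' @param diffusion_sigma lateral-diffusion SD in phase bins (0 = binary).
#' @return object of class `grid_layer_spec`.
#' @export
grid_layer_spec <- function(MG, pair, N_E = 60, diffusion_sigma = 0) {
  MG <- as.integer(MG); pair <- as.integer(pair)
  stopifnot(MG > 1, MG <= N_E, length(pair) == 2, pair[1] != pair[2],
            diffusion_sigma >= 0)
  structure(list(MG = MG, pair = pair, N_E = as.integer(N_E),
                 diffusion_sigma = diffusion_sigma),
            class = "grid_layer_spec")
}

#' Default grid-cell population
#'
#' Three layers with moduli 4, 9 and 25 (pairwise coprime, maximizing the
#' residue-code period) over `N_E = 60` bins.  Each layer uses a different
#' 60-degree-separated pair of PI directions (rotated offsets), so that
#' place-cell plateau steps fall at staggered boundaries.
#'
#' @param moduli integer vector of layer moduli.
#' @param N_E discretization bin count.
#' @param pairs list of length-2 index vectors (1-based, into a
#'   `direction_field` of 60 neurons); default pairs are separated by
#'   60 degrees and rotated by 12 degrees between layers.
#' @param diffusion_sigma shared lateral-diffusion SD in phase bins.
#' @return list of `grid_layer_spec` of class `grid_population`.
#' @export
grid_population <- function(moduli = c(4, 9, 25), N_E = 60,
                            pairs = list(c(1, 11), c(3, 13), c(5, 15)),
                            diffusion_sigma = 0) {
  stopifnot(length(moduli) == length(pairs))
  layers <- mapply(function(m, p) grid_layer_spec(m, p, N_E, diffusion_sigma),
                   moduli, pairs, SIMPLIFY = FALSE)
  structure(layers, class = "grid_population")
}

#' @export
print.grid_population <- function(x, ...) {
  cat("Grid population:", length(x), "layers\n")
  for (l in x)
    cat(sprintf("  modulo %d, pair (%d,%d), N_E %d, sigma %.2g\n",
                l$MG, l$pair[1], l$pair[2], l$N_E, l$diffusion_sigma))
  invisible(x)
}

#' Discretize a PI value onto a bin field
#'
#' `floor(D * N_E / D_max)`; the top bin is closed, i.e. `D = D_max` maps to
#' `N_E - 1` rather than out of range.
#'
#' @param D PI neuron value(s) in `[0, D_max]`.
#' @param N_E bin count.
#' @param D_max field ceiling.
#' @return integer bin index (0-based), vectorised.
#' @export
discretize <- function(D, N_E, D_max) {
  if (any(D < 0 | D > D_max)) stop("D outside [0, D_max]")
  pmin(N_E - 1L, as.integer(floor(D * N_E / D_max)))
}

#' Modulo projection of a bin index
#'
#' @param bin 0-based bin index (vectorised).
#' @param MG modulo.
#' @return phase index `bin %% MG`.
#' @export
modulo_project <- function(bin, MG) as.integer(bin) %% as.integer(MG)

#' Phase pair of a grid layer for the current PI state
#'
#' @param spec a `grid_layer_spec`.
#' @param field a `pi_field`.
#' @return integer vector `c(k1, k2)` of 0-based phase indices.
#' @export
grid_phase <- function(spec, field) {
  D <- field$D[spec$pair]
  modulo_project(discretize(D, spec$N_E, field$D_max), spec$MG)
}

#' Grid-layer activity
#'
#' The conjunction of the two modulo projections: an `MG x MG` matrix with a
#' single 1 at the current phase pair (binary), optionally spread by torus
#' Gaussian diffusion (`diffusion_sigma > 0`), in which case activities are
#' analogue in [0, 1] with the maximum still at the winner.
#'
#' @param spec a `grid_layer_spec`.
#' @param field a `pi_field`.
#' @return `MG x MG` activity matrix (rows = first residue `k1`).
#' @export
grid_activity <- function(spec, field) {
  ph <- grid_phase(spec, field)
  act <- matrix(0, spec$MG, spec$MG)
  act[ph[1] + 1L, ph[2] + 1L] <- 1
  if (spec$diffusion_sigma > 0) act <- diffuse(act, spec$diffusion_sigma)
  act
}

#' Torus Gaussian diffusion of a phase layer
#'
#' Circular convolution of the `MG x MG` phase lattice with a Gaussian kernel
#' truncated at 3 sigma (wrapping on both axes: the phase space is a torus),
#' renormalised so the maximum is 1.  `sigma = 0` is the identity.
#'
#' @param act `MG x MG` activity matrix.
#' @param sigma Gaussian SD in phase bins.
#' @return diffused activity matrix in [0, 1].
#' @export
diffuse <- function(act, sigma) {
  if (sigma <= 0) return(act)
  m <- nrow(act)
  r <- min(floor(3 * sigma), (m - 1) %/% 2)   # avoid wrap-around aliasing
  off <- -r:r
  kern <- exp(-off^2 / (2 * sigma^2))
  out <- matrix(0, m, m)
  for (i in seq_along(off)) {
    rows <- ((seq_len(m) - 1 + off[i]) %% m) + 1
    for (j in seq_along(off)) {
      cols <- ((seq_len(m) - 1 + off[j]) %% m) + 1
      out <- out + act[rows, cols, drop = FALSE] * (kern[i] * kern[j])
    }
  }
  out / max(out)
}

#' Grid phase directly from a position (oracle)
#'
#' Computes a layer's phase pair straight from the projections of a position
#' onto the two paired preferred directions, bypassing temporal integration.
#' For a noise-free signed-mode integrator the incremental and position-based
#' computations agree; this is the position-purity oracle.
#'
#' @param p length-2 position in metres (displacement from the PI origin).
#' @param spec a `grid_layer_spec`.
#' @param field a signed-mode `pi_field` (supplies directions and scaling).
#' @return integer vector `c(k1, k2)`.
#' @export
grid_from_position <- function(p, spec, field) {
  prof <- pi_profile_at(field, p)
  D <- prof[spec$pair]
  modulo_project(discretize(D, spec$N_E, field$D_max), spec$MG)
}

#' Phase trace of a grid layer along a PI trace
#'
#' Vectorised: given the two paired neurons' PI values over time, returns the
#' 0-based phase pair per sample.
#'
#' @param Dpair matrix with two columns (values of the paired neurons).
#' @param spec a `grid_layer_spec`.
#' @param D_max field ceiling of the originating `pi_field`.
#' @return integer matrix with columns `k1`, `k2`.
#' @export
grid_phase_trace <- function(Dpair, spec, D_max) {
  k1 <- modulo_project(discretize(Dpair[, 1], spec$N_E, D_max), spec$MG)
  k2 <- modulo_project(discretize(Dpair[, 2], spec$N_E, D_max), spec$MG)
  cbind(k1 = k1, k2 = k2)
}

#' Activity trace of one phase cell
#'
#' Activity over time of the phase cell `(k1, k2)` of a layer, given the
#' layer's phase trace: binary match, or the torus-Gaussian diffused value if
#' the layer has `diffusion_sigma > 0`.
#'
#' @param phases integer matrix from [grid_phase_trace()].
#' @param phase length-2 integer, the tracked cell's 0-based phase pair.
#' @param spec the `grid_layer_spec`.
#' @return numeric activity vector in [0, 1].
#' @export
phase_cell_trace <- function(phases, phase, spec) {
  m <- spec$MG
  d1 <- pmin((phases[, 1] - phase[1]) %% m, (phase[1] - phases[, 1]) %% m)
  d2 <- pmin((phases[, 2] - phase[2]) %% m, (phase[2] - phases[, 2]) %% m)
  if (spec$diffusion_sigma <= 0) return(as.numeric(d1 == 0 & d2 == 0))
  s <- spec$diffusion_sigma
  r <- min(floor(3 * s), (m - 1) %/% 2)
  a <- exp(-(d1^2 + d2^2) / (2 * s^2))
  a[d1 > r | d2 > r] <- 0
  a
}

#' Flattened grid-population pattern
#'
#' Concatenates the (possibly diffused) activities of all layers into one
#' vector — the input pattern for WTA place-cell learning and for the NLMS
#' association with visual place cells.
#'
#' @param pop a `grid_population`.
#' @param field a `pi_field`.
#' @return numeric vector of length `sum(MG^2)`.
#' @export
grid_pattern <- function(pop, field)
  unlist(lapply(pop, function(sp) as.numeric(grid_activity(sp, field))))

#' Random modulo-projection cell population
#'
#' Generalized entorhinal coding: each cell picks `fan_in` PI neurons at
#' random, a random scale (modulo) per input and a random target residue, and
#' fires when every discretized input matches its residue under its scale
#' (a product of modulo match indicators).  Rate maps of such cells span the
#' whole spectrum from grid-like to irregular.
#'
#' @param field a `pi_field` (supplies N and scaling).
#' @param n_cells number of cells.
#' @param fan_in inputs per cell, or an integer vector to sample from
#'   (default `c(2, 3)`).
#' @param scales integer vector the moduli are drawn from (default `3:12`).
#' @param N_E discretization bin count (default 60).
#' @param seed RNG seed.
#' @return object of class `rp_population`: list of cells with `neurons`,
#'   `scales`, `residues`.
#' @export
random_projection_population <- function(field, n_cells, fan_in = c(2, 3),
                                         scales = 3:12, N_E = 60, seed = 1L) {
  stopifnot(all(fan_in >= 2))
  set.seed(seed)
  cells <- lapply(seq_len(n_cells), function(i) {
    k <- if (length(fan_in) > 1) sample(fan_in, 1) else fan_in
    sc <- sample(scales, k, replace = TRUE)
    list(neurons = sample.int(field$N, k),
         scales = sc,
         residues = vapply(sc, function(s) sample.int(s, 1) - 1L, integer(1)))
  })
  structure(list(cells = cells, N_E = as.integer(N_E)),
            class = "rp_population")
}

#' Activity traces of a random-projection population
#'
#' @param pop an `rp_population`.
#' @param Dtrace matrix of PI values over time (samples x N neurons), e.g.
#'   from [pi_trace()].
#' @param D_max field ceiling.
#' @return samples x n_cells binary activity matrix.
#' @export
rp_activity_trace <- function(pop, Dtrace, D_max) {
  bins <- matrix(discretize(Dtrace, pop$N_E, D_max), nrow = nrow(Dtrace))
  out <- matrix(0, nrow(Dtrace), length(pop$cells))
  for (i in seq_along(pop$cells)) {
    cl <- pop$cells[[i]]
    m <- rep(TRUE, nrow(bins))
    for (j in seq_along(cl$neurons))
      m <- m & (bins[, cl$neurons[j]] %% cl$scales[j] == cl$residues[j])
    out[, i] <- as.numeric(m)
  }
  out
}
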
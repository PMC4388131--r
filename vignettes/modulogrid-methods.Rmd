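---
title: "Grid cells from modulo-compressed path integration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid cells from modulo-compressed path integration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 4)
library(modulogrid)
```

## The model

`modulogrid` simulates a neural architecture in which the hexagonal firing
pattern of entorhinal grid cells is not computed by a dedicated spatial
system but falls out of *compressing* a path-integration code.

**Path integration.** A ring of $N$ neurons (default 60) with preferred
directions $\theta_i = -2\pi i/N$ receives the agent's movement direction
$\phi$ through a cosine tuning curve and accumulates the travelled
displacement:

$$ V_i(\phi) = 1 + \cos(\phi - \theta_i), \qquad
   D_i(t) = \big[D_i(t-1) + \alpha\,V_i(\phi(t))\big]^+ $$

with gain $\alpha$ (default 0.01), rectification $[\cdot]^+$ and a hard
ceiling $D_{max}$ (default 1).  The most active neuron points along the net
movement and its activity is proportional to the distance from the last
reset, giving direct access to a homing vector.

The package implements this update twice, selected by the `mode` argument of
`pi_field()`:

* `as_printed` is the literal rule above.  Its "$1+$" term adds total path
  length into every neuron, which makes any single neuron's value depend on
  the path taken, not only on where the agent is.
* `signed_projection` (the default) drops the offset, accumulating
  $\cos(\phi-\theta_i)$ with sign and storing the result around a fixed
  mid-range level $D_{max}/2$.  Each neuron then holds the projection of the
  net displacement onto its preferred direction — a pure function of
  position.  This is the regime in which periodic spatial firing is
  attainable at all, and both modes share every downstream mechanism, so the
  signed mode is used for all grid-pattern experiments.  The cosine ring and
  the literal rule remain available and tested.

Step lengths are expressed in metres and scaled by `meters_per_unit`, chosen
so the field spans twice the arena diameter; at constant speed the per-step
formulation above is recovered exactly.

**Modulo compression.** Each selected PI neuron's value is discretized over
$N_E$ bins (default 60, with a closed top bin so $D = D_{max}$ stays in
range), and the bin index is reduced modulo $M_G$:

$$ j = \lfloor D_i N_E / D_{max} \rfloor, \qquad k = j \bmod M_G . $$

The conjunction of the residues of **two** PI neurons yields an
$M_G \times M_G$ torus of phase cells, exactly one of which is active at any
time.  Along each paired direction the active residue recurs every
$M_G \cdot (D_{max}/N_E)$ field units, so the conjunction tiles space with a
lattice: the modulo sets the spacing, the residue pair the phase, and the
angular separation of the paired directions the geometry.  A separation of
60° produces a triangular (hexagonal) lattice; the source architecture
leaves the pair choice open ("randomly chosen pairs"), and 60° is the only
separation consistent with the hexagonal patterns it reports, so 60° is the
default here, with each of the three default layers (moduli 4, 9, 25 —
pairwise coprime, maximizing the residue-code period) using a pair rotated
by 12° from the previous layer so that place-cell plateau boundaries are
staggered.

Optional lateral diffusion (`diffusion_sigma`, in phase bins) convolves each
layer with a Gaussian on the phase torus (truncated at $3\sigma$,
renormalised to a maximum of 1, keeping activities in $[0,1]$), turning the
one-hot code into a graded one.  `random_projection_population()` generalises
the construction: cells multiply modulo match indicators of randomly chosen
PI neurons under randomly chosen scales, producing the whole spectrum from
grid-like to irregular spatial activity.

**Visual place cells and recalibration.** The camera front end of the
original robot is replaced by a synthetic landmark-bearing model that
preserves what that pipeline ultimately delivers: a constellation of
landmark identities and allocentric azimuths.  A visual place cell stores
the constellation seen at recruitment and responds with the mean Gaussian
azimuth similarity over its stored landmarks (`azimuth_sigma` default 10°,
which yields place fields 2–3 m wide in a 4 m arena, matching the broad
generalisation of the original recogniser).  Each recruited cell also stores
a verbatim copy of the PI field; when a cell later wins the competition with
activity above an absolute threshold (default 0.7) *and* a margin over the
runner-up above a relative threshold (default 0.15), the PI field is
overwritten with the stored profile.  The two thresholds implement a
confidence test that refuses to recalibrate in perceptually ambiguous
places.  The original parameter appendix is not available; both defaults are
exposed in `learning_params()`.

**Prediction and fusion.** A normalised least-mean-squares (NLMS) rule
associates grid patterns with visual recognition:

$$ \mathrm{PredVPC}_m = \sum_l w_{ml} G_l, \qquad
   \Delta w_{ml} = \lambda\,\gamma\,\beta_m\,
   \frac{(\mathrm{VPC}_m - \mathrm{PredVPC}_m)\,G_l}{\sum_l G_l^2} $$

with $\beta$ a winner-take-all gate on the visual activities (ties to the
lowest index) and $\gamma$ a binary neuromodulation gate.  Prediction uses
the pre-update weights (predict-then-update order); a zero-energy input
performs no update.  The prediction is left unrectified and unclipped as
written, so fused activities can transiently exceed 1.  The multimodal place
cell is the convex combination
$\mathrm{MPC}_m = \eta\,\mathrm{VPC}_m + (1-\eta)\,\mathrm{PredVPC}_m$ with
$\eta = 0.5$ by default (both sources weighted equally; the weighting is
configurable but not learned).

**Homing.** A handful of place cells around the goal each store an action
direction (learned by the same NLMS machinery applied to the direction's
cosine/sine components); the controller recalls the winning cell's direction
and the resulting sensory-motor attraction basin drives the agent into the
goal zone without any metric map.

## The synthetic environment

`hex_arena(4)` reproduces the 4 m hexagonal enclosure of the grid-cell
experiments (landmarks at the six vertices); `two_room_arena()` builds the
multi-room layout of the place-cell experiments: two 7 m rooms joined by a
9 m corridor, with the second room repeating the first room's landmark
appearances (shifted by a fixed few tens of centimetres — similar rooms are
never pixel-identical) plus one distinctive landmark per room.  Line of
sight is polygon-blocked, so each room presents a room-local constellation
and the corridor its own distinctive one.  This makes perceptual aliasing a
property of the fixture: a cell learned in room 1 fires strongly at the
matching spot of room 2.

Trajectories are bounded random walks (constant speed 0.2 m/s, time step
0.1 s, per-step heading SD 0.15 rad, reflective deflection toward the
interior within 0.4 m of a wall — the proximity-sensor surrogate) or
scripted waypoint paths.  Goal detection is a radius test (0.15 m), standing
in for the floor-marker sensor of the original setup.

**Sensor noise.** The compass gets white noise (SD 1°) plus a *systematic*
deviation curve: a two-harmonic Fourier series in heading, drawn once per
run with RMS amplitude 1° — the classic hard/soft-iron deviation of a
magnetic compass, which also stands in for the angular discretization error
of the heading code.  This term matters: white noise alone integrates as
$\sqrt{t}$ and stays at centimetres over half an hour, and slowly drifting
bias terms cancel in a confined arena (their error is bounded by the current
distance from the origin).  A heading-dependent systematic error, by
contrast, adds coherently every time a heading recurs, so the
path-integration estimate drifts roughly linearly with distance run while
the compass error itself stays bounded.  At the default amplitude the
estimate is off by about half of the mid-scale grid period (1.2 m) after
4–5 minutes of continuous walking — the horizon at which uncalibrated grid
patterns are expected to wash out — and by several metres after 30 minutes.
Odometry adds 2% white multiplicative noise and a slow scale-bias random
walk (3e-4 per step).  The original study does not quantify its odometric
noise, so these are free parameters chosen once to reproduce that
qualitative degradation horizon; they are fields of `sensor_noise_model()`.

Negative noisy step lengths are clamped to zero (a wheel cannot run backward
during a forward command).  Azimuths are allocentric (compass-referenced);
no egocentric mode is provided.  There is no inertia or wheel-slip dynamics
— the noise model replaces them — and no camera imagery or ultrasound
emulation.

## The analysis pipeline

`rate_map()` bins activity over square spatial bins (default 5 cm for the
4 m arena), divides by occupancy, masks never-visited bins (masked, not
zero) and applies mask-aware Gaussian smoothing (default SD 5 cm).
`spatial_autocorrelation()` computes the Pearson correlation of the map with
itself at every 2D lag over the overlapping unmasked bins (FFT-based sums;
lags with fewer than 20 overlapping bins are masked), clamps to $[-1,1]$ and
averages the result with its point reflection: the autocorrelogram of any
map is exactly even, so this step only removes floating-point round-off and
makes the mirror-symmetry identity hold to machine precision.
`rotational_correlation()` correlates the autocorrelogram with its rotation
from 0° to 180° in 1° steps over an annulus that excludes the central peak
(inner radius: first zero crossing of the radial profile; outer radius: the
largest inscribed circle); 180° is computed as an exact index flip, other
angles by bilinear interpolation.  The gridness score is

$$ \min(r_{60}, r_{120}) - \max(r_{30}, r_{90}, r_{150}) \in [-2, 2], $$

the standard rotational-symmetry statistic (the source work cites the
literature that introduced it without printing a formula; this definition is
adopted).  A flat or undefined curve reports score 0 with a degeneracy
flag.  `curve_peaks()` detects local maxima with a prominence filter
(default 0.1) so that interpolation ripples on flat curve segments are not
mistaken for periodicity peaks.

## Experiment presets

`preset()` returns config objects for the simulated protocols;
`run_experiment()` executes them.  The presets map simulated seconds 1:1 to
the original wall-clock protocols (30 simulated minutes of exploration at
0.2 m/s, homing every 30 s to 4 min).

* **exp1 / exp2 / exp4** — closed-loop exploration of the hexagonal arena
  with noisy sensors, without recalibration, with periodic homing
  recalibration, and with recalibration disabled halfway.  In the arena
  protocols the reset fires only on arrival in the goal zone (the
  floor-marker conjunction of the original setup), keeping the reset zone
  narrow; per-layer rate maps and gridness are computed from a sampled
  phase cell.
* **exp6 / exp7** — winner-take-all place cells from grid patterns along a
  straight crossing.  The place is learned half a discretization bin off
  the origin, a generic position rather than the degenerate bin corner
  where every layer flips simultaneously.  exp7 sweeps the discretization
  factor (120, 60, 30 bins: field width grows with bin size) and the
  grid-cell count (12, 48, 192 random layers: background trace noise falls
  with count; counts start at 12 because a 1D transect almost never
  intersects the sparse lattice matches of only 3 random layers).
* **exp8–exp11** — the two-room protocols: 19 places recruited every 1.5 m
  along a ~28 m multi-room route (the route is long enough to hold all 19),
  NLMS association trained over 3 laps, then replays recording
  VPC/PredVPC/MPC winners.  These presets use diffused (analog) grid layers
  ($\sigma = 1$ bin), as the original place-cell experiments did.  The
  neuromodulation gate during training is opened by the same confidence
  test as the recalibration trigger, so associations are never learned at
  perceptually ambiguous spots — the supervision the original experimenters
  exercised by hand.  exp9 replays the trained bank on parallel paths
  (±0.4, ±0.8 m).  exp10/exp11 kidnap the agent (teleport with no odometric
  signal) onto a previously learned distant place, as in the original
  protocol; the kidnap targets sit where recognition is confident, so
  recalibration follows quickly, while the logged pre-trigger samples show
  the grid prediction still pointing at the pre-kidnap location.

## Numerical choices and degenerate inputs

Ties in every winner-take-all break to the lowest index.  The NLMS update
skips zero-energy inputs.  The top discretization bin is closed.  Diffusion
kernels are truncated at $3\sigma$ and never wrap onto themselves
(truncation at half the torus size).  A flat PI field reads out distance 0
with an undefined-direction flag.  Rate-map bins never visited are masked
through the whole pipeline rather than treated as zeros.  Autocorrelogram
lags with insufficient overlap are masked; the annulus of the rotational
correlation requires at least 10 valid pixel pairs per angle.

## Problem sizes

The bundled tests and the acceptance script run at desk scale, sizes chosen
as representative rather than exhaustive: 50,000-step walks (83 simulated
minutes) for rate-map pipelines, 30-simulated-minute closed-loop runs with
5 seed repeats for the drift comparison, 100 random paths for the
position-purity oracle, and 60-cell populations for the random-projection
screening.

## What passing tests do and do not show

The generator emulates the *statistical* structure of the original
experiments — noisy odometry and compass, bounded exploration, perceptual
aliasing between similar rooms — not their physical detail: there is no
imagery, no ultrasound, no wheel dynamics, and the aliasing is constructed
rather than emergent from vision.  Tests passing on these fixtures show
that the architecture behaves as described under the stated noise model
(grids appear and persist exactly when drift is bounded by recalibration;
fusion resolves constructed ambiguities; kidnapping is recovered through
the visual channel).  They do not show that a physical robot with a real
camera would reproduce the quantitative gridness values, nor that the noise
defaults match any particular vehicle: those defaults are calibrated to the
qualitative drift horizon reported for the original platform and are
exposed for adjustment.

## Known limitations

The PI saturation is a hard clamp; field dynamics near the ceiling are not
modelled.  Heading arrives as a scalar with noise — there is no dynamic
neural-field head-direction model.  Recruitment of place cells is
experiment-scripted, not novelty-driven.  The `as_printed` PI mode cannot
produce stable grid patterns on long paths by construction (its readout is
path-dependent), which is why the signed mode is the default for spatial
experiments.  Conjunctive grid-by-heading cells and hippocampal transition
models are out of scope.
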
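---
title: "Maximum-likelihood PET detector alignment: model, simulator, and validation"
author: "petalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-likelihood PET detector alignment: model, simulator, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

PET image quality depends on placing every line of response (LOR) correctly
in space, which in turn depends on knowing where each detector block
actually sits. Manufacturing tolerances, mechanical stress and assembly
errors displace and tilt blocks by fractions of a millimeter to a few
millimeters — enough to visibly blur sub-millimeter reconstructions.
`petalign` estimates the per-block rigid deviations (a translation `T_d` in
mm and rotation angles `R_d` in degrees for every block `d`) directly from a
static coincidence measurement of a *known* tracer distribution, with no
motion stages or manual steps.

## The model

The scanner blueprint supplies designed block positions `P` and orthonormal
local axes `X, Y, Z` per block (local x = planar transaxial, y =
depth-of-interaction pointing radially outward, z = axial). The predicted
geometry is `P_d + T_d` with axes rotated by the composition of single-axis
rotations about the block's blueprint axes, intrinsically in the order
x, then y, then z. The composition order is not physically identified for
the sub-degree deviations of interest (order effects are second order in
the angles); fixing one makes results exactly reproducible, and the order
is configurable in `local_rotation_matrix()`.

Interactions are discretized to crystal voxels by a lookup table
`L: cr -> R^3` of block-local centers and half-extents
(`crystal_lut()`). A crystal voxel center maps to global coordinates as
`p = P_d + T_d + L(cr)_x X_d + L(cr)_y Y_d + L(cr)_z Z_d` (with the rotated
axes).

The expected count of a coincidence bin `(lambda1, lambda2, t)` is

```
L(l1, l2, t) = scale * E_l1 * E_l2 * exp(-int A) * int K_TOF(s - c_t) F ds
```

the TOF-kernel-weighted line integral of the activity image `F` between
points sampled uniformly inside the two crystal voxels (five pairs by
default, averaged), attenuated by the Beer–Lambert factor of the mu-map `A`
and weighted by per-crystal efficiencies `E`. The TOF kernel is Gaussian
with FWHM `c * CTR / 2` (74.95 mm at a 500 ps coincidence time resolution);
its sign convention places positive offsets toward the first-listed
detector, mirrored when a bin is canonicalized. Scatter and randoms are not
modeled.

Line integrals use Joseph's method: the segment is stepped along the
principal grid axis and the field is interpolated bilinearly in the two
transverse directions at each plane crossing (where trilinear interpolation
reduces to bilinear), with trapezoid end handling. The same routine returns
the analytic gradient of the integral with respect to both endpoints, which
the calibration chains through the crystal-to-global transform to all
`6 * Ndet` alignment parameters. Gradients match central finite differences
to better than `1e-3` relative error (see `test-forward.R` and
`test-calibration.R`).

Two bin-mass conventions are implemented: the midpoint rule (kernel at the
bin center times bin width, the default) and the exact integrated Gaussian
(`tof_model(..., exact = TRUE)`). The study presets use the exact form so
that the simulator's hard binning of blurred offsets and the model's bin
masses agree identically; at the default bin width (a third of the kernel
FWHM) the two differ only at the `O(bin_width^2)` level.

The overall rate `scale` is not a model parameter: it absorbs acquisition
duration, the arbitrary normalization of the activity image, and the
arbitrary normalization of fan-sum raw-count efficiencies. It is profiled
analytically at every objective evaluation
(`scale* = weighted counts / weighted model mass`), which also removes the
efficiency/activity normalization degeneracy from the optimization.

## The estimator

Calibration maximizes the Poisson likelihood of the measured histogram
`C(l1, l2, t)`. `calibrate_alignment()` runs Adam with separate learning
rates for translations (1 mm) and rotations (0.1 degrees), 200 iterations,
and a fresh batch per iteration — the reference protocol. Two objective
modes are provided:

* **Full-sum** (`zero_bin_fraction > 0`): `sum_bins [L - C log L]` over
  all acceptance-compatible bins, occupied or not. A batch mixes occupied
  bins drawn uniformly from the histogram support (the data term) with
  sampled crystal pairs carrying count zero for the expectation term,
  importance-weighted so the batch objective is an unbiased estimate of
  the full sum. The zero part is evaluated TOF-marginally (summing the
  per-bin kernel masses inside one grid traversal is exactly the sum of
  that pair's rates over the TOF axis), and can mix uniform proposals with
  proposals from the measured pair distribution (`mass_mix`), whose
  density is exactly computable, for variance reduction.
* **Support-only** (`zero_bin_fraction = 0`): the likelihood terms are
  evaluated on the measured-support bins alone — the literal form of the
  printed estimator, whose expectation runs over bins drawn from the
  measured histogram. For sparse phantoms at fine crystal binning this is
  the only well-conditioned choice: the model mass then lives on billions
  of never-observed crystal pairs of which any affordable sample catches a
  handful, so the full-sum expectation term has order-one relative noise
  that destabilizes the profiled scale.

### Capture and refinement stages

With sub-millimeter sources, 1 mm crystal voxels and millimeter-scale
initial misalignment, the sampled model lines of the blueprint geometry
miss the activity entirely: the data term is blind and no gradient points
home. `run_recovery_experiment()` therefore calibrates in two stages:

1. **Capture**: coarse crystal binning (3 x 10 x 3 mm^3 by default) and an
   activity image whose source support is inflated by 1.4 mm, rasterized
   on its own coarse grid — classic multi-resolution continuation that
   widens the basin to several millimeters; full-sum objective.
2. **Refinement**: the target binning on the true activity image,
   initialized from the capture result; support-only objective, reduced
   learning rates, cosine decay and tail averaging.

This is an optimization schedule, not a change of model or estimand: the
final estimate is a stationary point of the fine-binning likelihood on the
true activity image.

Numerical safeguards, and why they exist:

* **Rate floor** (`rate_floor`, default 0.02 expected counts): the data
  term contains `log L` with `L` estimated by a finite crystal-sample
  average. For small sources a sampled line can miss the activity
  entirely, making the Monte-Carlo rate zero or tiny and the per-bin
  gradient coefficient `C / L` arbitrarily large. The additive floor keeps
  the objective finite and smooth and bounds those coefficients, turning a
  heavy-tailed gradient distribution into a well-behaved one. The floor is
  two orders of magnitude below a typical occupied-bin rate, so the
  stationary point moves negligibly.
* **Antithetic crystal sampling**: in-voxel sample offsets come in
  antithetic pairs, reducing the variance of the per-bin rate estimate at
  no cost.
* **Learning-rate decay and tail averaging** (`lr_decay = "cosine"`,
  `average_last`): with batches orders of magnitude below the reference
  protocol's five million bins, constant-rate Adam reaches a stationary
  jitter proportional to the learning rate rather than converging.
  Decaying the rate to zero and averaging the final iterates
  (Polyak–Ruppert) recovers most of the lost precision. The defaults in
  `align_control()` reproduce the reference protocol exactly; the
  desk-scale preset `desk_control()` enables both refinements.

The likelihood constrains only the *relative* geometry: moving all blocks
and the phantom by one common rigid motion is unobservable in practice
(the phantom may itself be misplaced). All evaluation therefore registers
the estimated geometry onto the reference with a closed-form Kabsch
Procrustes fit (positions only, rotation applied to axes, no scaling or
reflection) before computing per-axis errors: `dT_i` is the mean absolute
per-axis position residual, `dR_i` the mean angle between corresponding
local axis vectors. `dR_y` cannot see a spin of a block about its own
y axis; the definition is kept as is, deliberately, to stay comparable
with the field's convention.

## The simulator

`simulate_events()` replaces a full Monte-Carlo chain at desk scale:

* emission points are drawn activity-proportionally from the analytic
  phantom (uniform in each source ball, uniform in tube arclength with a
  uniform disc offset, uniform in shell or rod volumes) — not from the
  voxelized image, avoiding double discretization;
* a uniformly random direction defines the back-to-back photon pair; each
  photon is assigned to the first block its ray enters;
* the interaction depth follows a **uniform free-path model**: the photon
  interacts at a uniform random distance in `[0, free_path_max]` along its
  chord through the block or escapes. Detection probability is then
  proportional to the path length in the crystal volume — exactly the
  response the line-integral model assumes — and the interaction point is
  uniform along the chord, matching the model's uniform-in-voxel endpoint
  sampling to first order. (Assigning every interaction to the entry face
  instead would pile all events into the front DOI layer, a systematic
  half-depth radial offset that no rigid registration can remove; an
  exponential depth law would be more physical but would fold a
  depth-efficiency profile into the data that the oracle-efficiency model
  does not carry.)
* optional thinning by per-crystal efficiencies (`E1 * E2`) and by the
  attenuation survival probability;
* the TOF coordinate is the true signed midpoint offset plus Gaussian
  noise of the kernel FWHM, hard-binned later by `bin_events()`.

Events store block-local interaction coordinates, so one simulation can be
re-binned under any crystal-voxel layout (the binning sweep and the no-TOF
ablation reuse identical events).

What the simulator deliberately does *not* reproduce: positron range,
annihilation-photon non-collinearity, scatter, randoms, energy resolution
and dead time. Passing recovery tests therefore demonstrate the estimator
under the model's own physics (plus the solid-angle and finite-acceptance
effects the line-integral model ignores); they do not bound the additional
degradation a full physics chain or a real scanner would add.

The simulator and the forward model agree in distribution up to the known
endpoint-measure vs. solid-angle difference of line-integral response
models, which is at the few-percent level for near-opposed detector pairs
at realistic ring radii. The self-consistency chi-squared test in
`test-simulator.R` is sized (moderate per-bin counts) so that genuine
disagreement would fail it while this intrinsic model-class difference
stays within Poisson noise.

## Reconstruction

`lm_osem()` implements standard list-mode OSEM with multiplicative updates,
subsets interleaved by transaxial LOR azimuth (events dealt round-robin in
azimuth order, so subsets are balanced to one event), `lors_per_event`
sample lines inside the crystal voxels per event, the same projector as
the calibration (single source of truth), and a sensitivity map
(`sensitivity_map()`) summing backprojected `E1 * E2 * attenuation`
weights over accepted crystal pairs, TOF-marginalized. Convergence is
fixed-iteration (10 x 10 by default), voxels with zero sensitivity stay
zero, and nonnegativity is preserved by construction.

## Study conditions and problem sizes

The simulation-study presets mirror the reference conditions: a 24-block
scanner (3 rings of 8) with 48 x 48 x 10 mm^3 blocks at 75 mm inner
radius; ground-truth misalignment drawn per block from zero-mean Gaussians
with `sigma_T = 2 mm`, `sigma_R = 2 deg` (realized mean per-axis
deviations of roughly 1.4–2.0 mm and 1.2–2.2 deg); a 250 ps CTR; ten point
sources of 0.125 mm radius drawn uniformly in a cylinder of radius 30 mm
and half-length 40 mm, or a 250 micrometer tube along a clamped cubic
B-spline through ten control points drawn the same way. The B-spline is
cubic with uniform clamped knots; the control polygon is not interpolated
(the usual B-spline convention), and activity is uniform along the tube.

Desk-scale choices (all stated here as the package's own problem sizes):
2 x 10^6 simulated coincidences for the point sources and 5 x 10^6 for the
tube (the corresponding full-scale studies used 4.3 x 10^7 and 1.1 x 10^8);
activity images at 0.25 mm voxels for point sources and 0.125 mm for the
one-voxel-wide tube, cropped to the phantom support with a zero margin;
capture stage at 3 x 10 x 3 mm^3 binning, 100 Adam iterations at batch
4 x 10^4 with learning rates 1 mm / 0.1 deg; refinement at the target
binning, 250 iterations at batch 3 x 10^4 with rates 0.3 mm / 0.05 deg,
cosine decay, averaging of the last 100 iterates, and 6 antithetic
crystal-sample pairs per bin (10 for the tube, whose thin support makes
the per-bin rate estimate noisier). Sub-voxel tubes are rasterized by
arclength-weighted trilinear splatting of dense axis samples, which
conserves mass and preserves the local first moment (the axis position);
wider structures use 3^3 partial-volume supersampling. The acceptance
script (`scripts/acceptance.R`) runs exactly these presets.

Projector efficiency notes: line integration visits only the disjoint
axis-aligned support boxes of the activity image (merged per line so
interval ends always fall in zero field), endpoint trapezoid samples are
skipped at box faces, and the TOF kernel window is clipped at four sigma
(omitting under 1e-4 of a bin's mass). These are evaluation-cost choices
with sub-1e-3 relative effect on rates; the gradient tests bound their
effect directly.

## Degenerate inputs and tie-breaks

Empty phantoms, empty histograms, all-zero efficiency tables and all-zero
sensitivity maps raise errors rather than propagating NaNs. Events whose
blurred TOF offset falls outside the tiled bin range are dropped
symmetrically by simulator and model. Bin canonicalization orders each
pair by detector index and mirrors the TOF sign. Crystal assignment at
voxel boundaries floors toward the lower index after clamping to the
block interior. Procrustes registration refuses collinear configurations
and guards against reflections via the determinant correction.

## Known limitations

* The forward model (deliberately, following the field's convention for
  this estimator) omits solid-angle weighting; at small ring radii this
  leaves a few-percent rate modulation across oblique crystal pairs that
  acts as a mild unmodeled efficiency field.
* `dR_y` is blind to spin about the DOI axis (definition inherited from
  the evaluation convention).
* Stochastic optimization at desk-scale batch sizes leaves a jitter floor
  that tail averaging reduces but does not eliminate; the reported errors
  include it. One visible consequence: once both runs sit at that floor
  (tens of micrometers, well below the errors of the corresponding
  full-scale studies), disabling the TOF kernel no longer degrades every
  error component — the expected TOF-better-than-no-TOF ordering holds in
  magnitude but can flip on individual axes within the jitter.
* The simulator's free-path depth model truncates chords longer than
  `free_path_max` (default three times the DOI depth), which slightly
  under-weights very oblique side-entry paths.
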
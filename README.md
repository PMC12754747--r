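# petalign

Maximum-likelihood estimation of PET detector-block alignment from
time-of-flight coincidence data.

## The problem

Assembled PET scanners never match their mechanical drawings exactly:
detector blocks end up translated and tilted by anything from tens of
micrometers to millimeters. Every misplaced block misplaces all of its
lines of response (LORs), which blurs reconstructions — fatally so for
sub-millimeter, high-resolution systems. `petalign` is for instrument
builders and calibration physicists who want to *measure* the true block
geometry from coincidence data alone: one static acquisition of a known
tracer distribution, no motion stages, no manual point-source bookkeeping.

## The method

Each block `d` gets a rigid deviation from the blueprint: a translation
`T_d` (mm) and rotation angles `R_d` (degrees) about its local axes.
A coincidence bin `(λ₁, λ₂, t)` — two crystal voxels plus a TOF bin — has
the expected count

```
L(λ₁, λ₂, t) = scale · E_λ₁ E_λ₂ · exp(−∫ A dl) · ∫ K_TOF(s − c_t) F(γ(l)) dl
```

where `F` is the known activity image, `A` the attenuation map, `E` the
per-crystal efficiencies (estimated in-system by the fan-sum method), and
`K_TOF` a Gaussian whose FWHM is set by the coincidence timing resolution
(`c·CTR/2`). The line integral runs between points sampled inside the two
crystal voxels and is evaluated by Joseph's method with analytic endpoint
gradients. The estimate

```
(T, R) = argmin Σ_bins [ L(λ₁, λ₂, t) − C(λ₁, λ₂, t) · log L(λ₁, λ₂, t) ]
```

minimizes the Poisson negative log-likelihood of the measured histogram
`C` by Adam on importance-weighted bin batches, with the global `scale`
profiled analytically. Because a common rigid motion of scanner plus
phantom is unobservable, estimated geometries are registered to the
reference by a closed-form Procrustes fit before errors are reported:
`ΔT_i` is the mean per-axis position residual, `ΔR_i` the mean angle
between corresponding local axes.

The package also contains everything needed to validate the estimator
end-to-end without scanner data: a back-to-back coincidence simulator for
analytic phantoms (point sources, thin B-spline tubes, shells, hot-rod
patterns), fan-sum efficiency estimation, TOF list-mode OSEM
reconstruction with sensitivity maps, and the image metrics
(PSNR / SSIM / COV / peak-to-valley) used to judge alignment quality.

## A worked example

Simulate a misaligned 12-block scanner, calibrate it back, and score the
result (a few minutes on one CPU):

```r
library(petalign)

bp  <- cylindrical_blueprint(6, 2, 40, c(24, 10, 24))  # 12 blocks, 2 rings
cfg <- experiment_config(
  scanner = bp, sigma_t = 1, sigma_r = 1,       # 1 mm / 1 deg ground truth
  ctr_ps = 250, tof_range_mm = 60,
  n_events = 5e5, lut_voxel = c(1, 1, 1),       # finest crystal binning
  grid_spacing = 0.4,
  control = desk_control(seed = 101), seed = 7)
set.seed(7)                                      # eight point sources
r <- 18 * sqrt(runif(8)); th <- runif(8, 0, 2 * pi); z <- runif(8, -15, 15)
cfg$phantom <- phantom_points(cbind(r * cos(th), r * sin(th), z),
                              radii = 0.25)

rep <- run_recovery_experiment(cfg)
print(rep$errors_before)
print(rep$errors_after)
```

which prints:

```
alignment errors (mean over blocks)
  dT (mm):  x 1.0474  y 0.8954  z 0.4256
  dR (deg): x 0.990  y 1.298  z 1.411
alignment errors (mean over blocks)
  dT (mm):  x 0.0530  y 0.0414  z 0.0106
  dR (deg): x 0.085  y 0.108  z 0.086
```

The six numbers per geometry are the Procrustes-registered mean per-axis
translation and rotation errors against the simulated ground truth: the
millimeter-scale misalignment is recovered to a few tens of micrometers
and about a tenth of a degree from half a million coincidences. Inside the
report, `rep$fit` is the fitted model object: `plot(rep$fit)` shows the
NLL trace, `coef(rep$fit)` returns the Ndet x 6 parameter matrix,
`summary(rep$fit, reference = ...)` prints the same error report, and
`simulate(rep$fit, nsim, phantom = ...)` draws events from the fitted
geometry. `calibrate_alignment()` is the underlying fitting function when
you already have a histogram, a blueprint and an activity image.

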
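# Reproducible experiment recipes: simulate -> (efficiencies) -> calibrate ->
# evaluate, plus the crystal-binning sweep. One master seed drives every
# stage; identical configurations give identical reports.
#
# Calibration runs in two stages. The capture stage uses a coarse crystal
# binning and an activity image with inflated source support, which widens
# the likelihood's capture basin well beyond the millimeter-scale initial
# misalignment (with sub-millimeter sources and fine crystals, the sampled
# model lines of a multi-millimeter-misaligned blueprint miss the activity
# entirely and the data term is blind). The refinement stage then runs at
# the target binning on the true activity image, initialized from the
# capture result, with the likelihood restricted to the measured-support
# bins -- the form of the printed estimator, whose expectation runs over
# bins drawn from the measured histogram.

#' Reference simulation-study scanner
#'
#' 24 blocks (3 rings of 8) at 75 mm inner radius, 48 x 48 mm faces with
#' 10 mm DOI depth.
#' @export
study_scanner <- function() {
  cylindrical_blueprint(8L, 3L, 75, c(48, 10, 48))
}

#' Desk-scale optimizer preset (refinement stage)
#'
#' Support-only objective, reduced batch, cosine learning-rate decay and
#' tail averaging: appropriate when batches are orders of magnitude smaller
#' than the reference protocol's five million bins.
#'
#' @param iterations,batch_size,... overrides passed to [align_control()].
#' @export
desk_control <- function(iterations = 250L, batch_size = 3e4,
                         n_crystal_samples = 6L, lr_translation = 0.3,
                         lr_rotation = 0.05, average_last = 100L, ...) {
  align_control(iterations = iterations, batch_size = batch_size,
                n_crystal_samples = n_crystal_samples,
                lr_translation = lr_translation, lr_rotation = lr_rotation,
                zero_bin_fraction = 0, lr_decay = "cosine",
                average_last = average_last, ...)
}

# capture-stage preset: coarse binning, wide basin, full objective. The
# inflated activity is rasterized on its own coarser grid: its features are
# millimeters wide, so sub-millimeter voxels buy nothing.
capture_stage <- function(lut_voxel = c(3, 10, 3), inflate = 1.4,
                          grid_spacing = 1, control = NULL) {
  if (is.null(control))
    control <- align_control(iterations = 100L, batch_size = 4e4,
                             n_crystal_samples = 10L, lr_translation = 1,
                             lr_rotation = 0.1, zero_bin_fraction = 0.5,
                             lr_decay = "cosine", average_last = 35L)
  list(lut_voxel = lut_voxel, inflate = inflate,
       grid_spacing = grid_spacing, control = control)
}

# widen a phantom's support (used by the capture stage only)
inflate_phantom <- function(spec, amount) {
  switch(spec$kind,
    point_sources = { spec$radii <- spec$radii + amount; spec },
    bspline_tube = { spec$diameter <- spec$diameter + 2 * amount; spec },
    cylindrical_shell = { spec$thickness <- spec$thickness + 2 * amount; spec },
    hotrod = stop("capture-stage inflation is not defined for hotrod phantoms"))
}

#' Assemble a recovery-experiment configuration
#'
#' @param scanner a `pet_blueprint` (default [study_scanner()]).
#' @param phantom a `pet_phantom`; default: 10 equal point sources drawn
#'   uniformly in a cylinder of radius 30 mm and half-length 40 mm (drawn
#'   from the master seed).
#' @param sigma_t,sigma_r ground-truth misalignment scales (mm, degrees).
#' @param ctr_ps coincidence timing resolution for simulation and model.
#' @param tof_range_mm half-range tiled by TOF bins.
#' @param use_tof calibrate with the TOF kernel (the simulated offsets are
#'   always TOF-blurred; disabling folds all bins into one).
#' @param n_events accepted coincidences to simulate.
#' @param lut_voxel crystal-voxel size (mm, local x/y/z) of the refinement
#'   stage.
#' @param grid_spacing activity-image voxel size (mm).
#' @param efficiencies `"oracle"` (uniform truth, known to the model) or
#'   `"fan_sum"` (estimated from the data).
#' @param control an [align_control()] for the refinement stage.
#' @param coarse capture-stage settings (list with `lut_voxel`, `inflate`,
#'   `control`) or `NULL` to calibrate in a single stage.
#' @param seed master seed.
#' @export
experiment_config <- function(scanner = study_scanner(), phantom = NULL,
                              sigma_t = 2, sigma_r = 2, ctr_ps = 250,
                              tof_range_mm = 90, use_tof = TRUE,
                              n_events = 2e6, lut_voxel = c(1, 1, 1),
                              grid_spacing = 0.25,
                              efficiencies = c("oracle", "fan_sum"),
                              control = desk_control(),
                              coarse = capture_stage(), seed = 1L) {
  structure(list(scanner = scanner, phantom = phantom, sigma_t = sigma_t,
                 sigma_r = sigma_r, ctr_ps = ctr_ps,
                 tof_range_mm = tof_range_mm, use_tof = isTRUE(use_tof),
                 n_events = n_events, lut_voxel = lut_voxel,
                 grid_spacing = grid_spacing,
                 efficiencies = match.arg(efficiencies),
                 control = control, coarse = coarse,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

default_point_phantom <- function(n = 10L, radius = 30, half_z = 40,
                                  source_radius = 0.125) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  z <- runif(n, -half_z, half_z)
  phantom_points(cbind(r * cos(th), r * sin(th), z), radii = source_radius)
}

#' Tube phantom through random control points
#'
#' A 250 micrometer tube along a clamped cubic B-spline whose control points
#' are drawn like the default point sources (the same kind of FOV-spanning
#' support).
#' @param n_control number of control points.
#' @param diameter tube diameter (mm).
#' @param radius,half_z control-point envelope (mm).
#' @export
random_tube_phantom <- function(n_control = 10L, diameter = 0.25,
                                radius = 30, half_z = 40) {
  r <- radius * sqrt(runif(n_control))
  th <- runif(n_control, 0, 2 * pi)
  z <- runif(n_control, -half_z, half_z)
  phantom_tube(cbind(r * cos(th), r * sin(th), z), diameter = diameter)
}

# shared calibration driver: optional capture stage, then refinement
staged_calibration <- function(events, bp, config, activity, phantom,
                               acc, tof, efficiencies = NULL) {
  cal_tof <- if (config$use_tof) tof else NULL
  init <- NULL
  fit_coarse <- NULL
  if (!is.null(config$coarse)) {
    cs <- config$coarse
    lutA <- crystal_lut(bp$block_dims, cs$lut_voxel)
    spA <- if (is.null(cs$grid_spacing)) config$grid_spacing
           else cs$grid_spacing
    FA <- voxelize_phantom(inflate_phantom(phantom, cs$inflate),
                           spacing = spA)
    hA <- histogram_events(bin_events(events, lutA, cal_tof),
                           ndet = bp$ndet, ncr = lutA$ncr)
    hA <- hA[accepts(acc, hA$d1, hA$d2)]
    fit_coarse <- calibrate_alignment(hA, bp, lutA, FA, tof = cal_tof,
                                      acceptance = acc,
                                      control = cs$control)
    init <- fit_coarse$params
    rm(hA, FA, lutA)
    gc(FALSE)
  }
  lut <- crystal_lut(bp$block_dims, config$lut_voxel)
  h <- histogram_events(bin_events(events, lut, cal_tof), ndet = bp$ndet,
                        ncr = lut$ncr)
  h <- h[accepts(acc, h$d1, h$d2)]
  eff <- NULL
  if (identical(config$efficiencies, "fan_sum")) {
    fan <- fan_acceptance(bp, n_opposing = 3L,
                          include_axial_neighbors = TRUE)
    eff <- fan_sum_efficiencies(h, fan, ndet = bp$ndet, ncr = lut$ncr)
    eff[eff == 0] <- min(eff[eff > 0])  # unseen crystals: floor, not zero
  }
  if (!is.null(efficiencies)) eff <- efficiencies
  fit <- calibrate_alignment(h, bp, lut, activity, efficiencies = eff,
                             tof = cal_tof, acceptance = acc,
                             control = config$control, init = init)
  list(fit = fit, fit_coarse = fit_coarse, histogram = h, lut = lut)
}

#' Run a full alignment recovery experiment
#'
#' Builds the blueprint, draws a Gaussian ground-truth misalignment,
#' simulates TOF coincidences from the phantom under the perturbed geometry,
#' optionally estimates efficiencies by fan-sum, calibrates starting from
#' the unperturbed blueprint (capture stage plus refinement stage), and
#' scores the result with Procrustes-registered per-axis errors before and
#' after calibration.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory for JSON report and loss-trace CSV.
#' @return list with the fitted `pet_alignment`, the ground-truth geometry,
#'   `errors_before`, `errors_after`, and the simulated events.
#' @export
run_recovery_experiment <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  bp <- config$scanner
  gt_params <- perturb_alignment(bp$ndet, config$sigma_t, config$sigma_r)
  gt_geom <- apply_alignment(bp, gt_params)
  phantom <- config$phantom
  if (is.null(phantom)) phantom <- default_point_phantom()
  tof <- tof_model(config$ctr_ps, range_mm = config$tof_range_mm,
                   exact = TRUE)
  activity <- voxelize_phantom(phantom, spacing = config$grid_spacing)
  events <- simulate_events(gt_geom, phantom, config$n_events, tof = tof)
  acc <- fan_acceptance(bp, n_opposing = 3L, max_ring_diff = Inf)
  cal <- staged_calibration(events, bp, config, activity, phantom, acc, tof)
  errs_before <- alignment_errors(bp, gt_geom, procrustes = TRUE)
  errs_after <- alignment_errors(cal$fit$geometry, gt_geom,
                                 procrustes = TRUE)
  report <- list(fit = cal$fit, fit_coarse = cal$fit_coarse,
                 ground_truth = gt_geom, gt_params = gt_params,
                 errors_before = errs_before, errors_after = errs_after,
                 events = events, histogram = cal$histogram, lut = cal$lut,
                 activity = activity, phantom = phantom, tof = tof,
                 acceptance = acc, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(delta_T_before = errs_before$delta_T,
           delta_R_before = errs_before$delta_R,
           delta_T_after = errs_after$delta_T,
           delta_R_after = errs_after$delta_R,
           scale = cal$fit$scale, n_events = nrow(events),
           seed = config$seed),
      file.path(out_dir, "report.json"), digits = NA, auto_unbox = TRUE)
    utils::write.csv(data.frame(iteration = seq_along(cal$fit$loss_trace),
                                nll = cal$fit$loss_trace,
                                grad_norm = cal$fit$grad_norms),
                     file.path(out_dir, "loss_trace.csv"),
                     row.names = FALSE)
  }
  report
}

#' Re-calibrate an existing experiment under new binning / TOF settings
#'
#' Rebins the stored events under a different crystal-voxel size and/or with
#' the TOF kernel disabled, and repeats only the calibration stages. Used
#' for the binning sweep and the no-TOF ablation on identical data.
#'
#' @param report output of [run_recovery_experiment()].
#' @param lut_voxel crystal-voxel size (mm).
#' @param use_tof calibrate with the TOF kernel.
#' @param control optional [align_control()] override (refinement stage).
#' @param seed optional seed for the recalibration RNG stream.
#' @export
recalibrate <- function(report, lut_voxel = NULL, use_tof = NULL,
                        control = NULL, seed = NULL) {
  config <- report$config
  if (!is.null(lut_voxel)) config$lut_voxel <- lut_voxel
  if (!is.null(use_tof)) config$use_tof <- use_tof
  if (!is.null(control)) config$control <- control
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  bp <- config$scanner
  cal <- staged_calibration(report$events, bp, config, report$activity,
                            report$phantom, report$acceptance, report$tof)
  list(fit = cal$fit,
       errors_after = alignment_errors(cal$fit$geometry,
                                       report$ground_truth,
                                       procrustes = TRUE),
       lut_voxel = config$lut_voxel, use_tof = config$use_tof)
}

#' Crystal-binning x TOF sweep
#'
#' Runs one simulation and calibrates the same events under several crystal
#' binnings, with and without the TOF kernel, reporting the six
#' Procrustes-registered error components per setting.
#'
#' @param config an [experiment_config()].
#' @param binnings list of crystal-voxel sizes (mm).
#' @param tof_modes logical vector of TOF settings to evaluate.
#' @return data.frame with one row per (binning, tof) combination.
#' @export
run_binning_sweep <- function(config,
                              binnings = list(c(3, 10, 3), c(2, 10, 2),
                                              c(2, 2, 2), c(1, 1, 1)),
                              tof_modes = c(TRUE, FALSE)) {
  base <- run_recovery_experiment(config)
  rows <- list()
  for (usetof in tof_modes) {
    for (bv in binnings) {
      res <- if (identical(as.numeric(bv), as.numeric(config$lut_voxel)) &&
                 identical(usetof, config$use_tof)) {
        list(errors_after = base$errors_after)
      } else {
        recalibrate(base, lut_voxel = bv, use_tof = usetof)
      }
      e <- res$errors_after
      rows[[length(rows) + 1L]] <-
        data.frame(binning = paste(bv, collapse = "x"), tof = usetof,
                   dTx = e$delta_T[1], dTy = e$delta_T[2],
                   dTz = e$delta_T[3], dRx = e$delta_R[1],
                   dRy = e$delta_R[2], dRz = e$delta_R[3])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "errors_before") <- base$errors_before
  out
}
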
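# Expected-count forward model for coincidence bins: Joseph-method line
# integrals through voxel grids, Beer-Lambert attenuation, Gaussian
# TOF-kernel weighting, and per-crystal efficiencies.

as_point_matrix <- function(p) {
  if (is.null(dim(p))) matrix(p, 1, 3) else as.matrix(p)
}

#' Line integral through a voxel grid (Joseph's method)
#'
#' Integrates the trilinearly interpolated field along the segment
#' `p0 -> p1`, sampling at principal-axis plane crossings where trilinear
#' interpolation reduces to bilinear. Zero outside the grid support.
#'
#' @param grid a [voxel_grid()].
#' @param p0,p1 endpoints (mm): length-3 vectors or n x 3 matrices.
#' @return Numeric vector of integrals (grid units x mm).
#' @export
line_integral <- function(grid, p0, p1) {
  P0 <- as_point_matrix(p0)
  P1 <- as_point_matrix(p1)
  if (any(rowSums((P1 - P0)^2) < 1e-20))
    stop("degenerate segment: p0 == p1")
  ga <- grid_cpp_args(grid)
  cpp_line_integrals(ga$values, ga$origin, ga$spacing, ga$dims, ga$brick,
                     ga$bdims, ga$bsz, ga$boxes, P0, P1,
                     tof_cpp_spec(NULL), FALSE, NULL)
}

#' Attenuation factor along a line of response
#'
#' `exp(-integral of mu)` along the full segment (Beer-Lambert).
#'
#' @param attenuation attenuation map (`voxel_grid`, mm^-1).
#' @inheritParams line_integral
#' @export
attenuation_factor <- function(attenuation, p0, p1) {
  exp(-line_integral(attenuation, p0, p1))
}

#' TOF-kernel-weighted activity line integral
#'
#' Integrates `K(s(l) - c_t) * F(l)` along the segment, where `s` is the
#' signed distance from the LOR midpoint (positive toward `p0`) and `c_t` is
#' the center of TOF bin `t`.
#'
#' @param activity tracer grid (`voxel_grid`).
#' @inheritParams line_integral
#' @param t 1-based TOF bin index (vector recycled over rows).
#' @param tof a [tof_model()].
#' @export
tof_weighted_integral <- function(activity, p0, p1, t, tof) {
  P0 <- as_point_matrix(p0)
  P1 <- as_point_matrix(p1)
  t <- as.integer(t)
  if (any(t < 1L | t > tof$n_bins)) stop("TOF bin index out of range")
  ga <- grid_cpp_args(activity)
  spec <- tof_cpp_spec(tof)
  spec$tbin <- t - 1L
  cpp_line_integrals(ga$values, ga$origin, ga$spacing, ga$dims, ga$brick,
                     ga$bdims, ga$bsz, ga$boxes, P0, P1, spec, FALSE, NULL)
}

#' Per-crystal efficiency table
#'
#' @param ndet,ncr table dimensions.
#' @param values scalar or Ndet x Ncr matrix of nonnegative efficiencies.
#' @export
efficiency_table <- function(ndet, ncr, values = 1) {
  E <- if (length(values) == 1L) matrix(values, ndet, ncr) else as.matrix(values)
  stopifnot(nrow(E) == ndet, ncol(E) == ncr)
  if (any(E < 0)) stop("efficiencies must be nonnegative")
  if (all(E == 0)) stop("efficiency table is identically zero")
  E
}

#' Expected count of a coincidence bin
#'
#' The Poisson rate of bin `(lambda1, lambda2, t)`:
#' `scale * E1 * E2 * mean_s [ exp(-int A) * int K_TOF F ]`, the mean taken
#' over `n_samples` point pairs drawn uniformly inside the two crystal
#' voxels. Smooth in the alignment parameters through the crystal endpoints.
#'
#' @param d1,cr1,d2,cr2 0-based detector / crystal indices (vectors).
#' @param t 1-based TOF bin (ignored when `tof` is `NULL`).
#' @param geometry aligned `pet_blueprint`.
#' @param lut `pet_crystal_lut`.
#' @param activity,attenuation voxel grids (`attenuation` may be `NULL`).
#' @param efficiencies Ndet x Ncr matrix (default: uniform 1).
#' @param tof [tof_model()] or `NULL` for a non-TOF model.
#' @param n_samples crystal point pairs per bin (default 5).
#' @param seed integer seed for the in-crystal sampling.
#' @param scale global rate calibration factor.
#' @export
expected_count <- function(d1, cr1, d2, cr2, t = 1L, geometry, lut,
                           activity, attenuation = NULL, efficiencies = NULL,
                           tof = NULL, n_samples = 5L, seed = 1L, scale = 1) {
  n <- max(length(d1), length(cr1), length(d2), length(cr2), length(t))
  d1 <- rep_len(as.integer(d1), n); cr1 <- rep_len(as.integer(cr1), n)
  d2 <- rep_len(as.integer(d2), n); cr2 <- rep_len(as.integer(cr2), n)
  t <- rep_len(as.integer(t), n)
  if (any(d1 == d2)) stop("a coincidence requires two distinct detectors")
  if (any(d1 < 0 | d1 >= geometry$ndet | d2 < 0 | d2 >= geometry$ndet))
    stop("detector index out of range")
  if (any(cr1 < 0 | cr1 >= lut$ncr | cr2 < 0 | cr2 >= lut$ncr))
    stop("crystal index out of range")
  if (!is.null(tof) && any(t < 1L | t > tof$n_bins))
    stop("TOF bin index out of range")
  if (is.null(efficiencies))
    efficiencies <- efficiency_table(geometry$ndet, lut$ncr)
  arr <- geometry_cpp_arrays(geometry)
  res <- forward_raw(arr, lut, d1, cr1, d2, cr2,
                     tbin = if (is.null(tof)) rep(0L, n) else t - 1L,
                     activity = activity, attenuation = attenuation,
                     tof = tof, n_samples = n_samples, seed = seed,
                     want_grad = FALSE)
  scale * efficiencies[cbind(d1 + 1L, cr1 + 1L)] *
    efficiencies[cbind(d2 + 1L, cr2 + 1L)] * res$mu
}

# thin wrapper assembling the cpp_batch_forward call
forward_raw <- function(arr, lut, d1, cr1, d2, cr2, tbin, activity,
                        attenuation, tof, n_samples, seed, want_grad) {
  ga <- grid_cpp_args(activity)
  if (!is.null(attenuation)) {
    aa <- grid_cpp_args(attenuation, use_bricks = FALSE)
    Av <- aa$values; Ao <- aa$origin; Asp <- aa$spacing; Ad <- aa$dims
  } else {
    Av <- NULL; Ao <- c(0, 0, 0); Asp <- c(1, 1, 1); Ad <- c(1L, 1L, 1L)
  }
  cpp_batch_forward(arr$pos, arr$axes, arr$rot, arr$drot,
                    lut$centers, lut$half_extents,
                    as.integer(d1), as.integer(cr1),
                    as.integer(d2), as.integer(cr2), as.integer(tbin),
                    ga$values, ga$origin, ga$spacing, ga$dims,
                    ga$brick, ga$bdims, ga$bsz, ga$boxes,
                    Av, Ao, Asp, Ad,
                    tof_cpp_spec(tof), as.integer(n_samples),
                    as.integer(seed), want_grad)
}
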
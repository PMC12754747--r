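# Axis-aligned voxel grids (tracer activity F, attenuation A) and the TOF
# localization model.

#' Axis-aligned 3D voxel grid
#'
#' `origin` is the outer corner of voxel (0,0,0); voxel centers sit at
#' `origin + (i + 0.5) * spacing`. Values are a nonnegative scalar field:
#' activity per mm^3 for tracer images, mm^-1 for attenuation maps.
#'
#' @param values 3D numeric array.
#' @param origin,spacing length-3 numeric (mm).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, origin, spacing) {
  values <- as.array(values)
  if (storage.mode(values) != "double") storage.mode(values) <- "double"
  stopifnot(length(dim(values)) == 3L, length(origin) == 3L,
            length(spacing) == 3L, all(spacing > 0))
  if (any(values < 0)) stop("grid values must be nonnegative")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), dims = dim(values)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$dims, collapse = " x "), "voxels,",
      paste(signif(x$spacing, 4), collapse = " x "), "mm spacing\n")
  cat("  origin (mm):", paste(signif(x$origin, 6), collapse = ", "), "\n")
  cat("  total mass:", signif(sum(x$values) * prod(x$spacing), 6),
      " max:", signif(max(x$values), 6), "\n")
  invisible(x)
}

# coarse occupancy used to skip empty regions during line integration;
# dilated by one brick so trilinear support never leaks past an empty flag
grid_bricks <- function(grid, brick_size = 4L) {
  dm <- grid$dims
  bd <- as.integer(ceiling(dm / brick_size))
  occ <- array(FALSE, bd)
  nz <- which(grid$values != 0, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    bi <- (nz - 1L) %/% brick_size        # 0-based brick indices
    occ[unique(bi[, 1] + bd[1] * (bi[, 2] + bd[2] * bi[, 3])) + 1L] <- TRUE
  }
  # dilate by one brick in each direction
  dil <- occ
  for (s in c(-1L, 1L)) {
    dil[pmin(pmax(seq_len(bd[1]) + s, 1L), bd[1]), , ] <-
      dil[pmin(pmax(seq_len(bd[1]) + s, 1L), bd[1]), , ] | occ
  }
  occ2 <- dil
  for (s in c(-1L, 1L)) {
    occ2[, pmin(pmax(seq_len(bd[2]) + s, 1L), bd[2]), ] <-
      occ2[, pmin(pmax(seq_len(bd[2]) + s, 1L), bd[2]), ] | dil
  }
  occ3 <- occ2
  for (s in c(-1L, 1L)) {
    occ3[, , pmin(pmax(seq_len(bd[3]) + s, 1L), bd[3])] <-
      occ3[, , pmin(pmax(seq_len(bd[3]) + s, 1L), bd[3])] | occ2
  }
  list(brick = as.integer(occ3), bdims = bd, bsz = as.integer(brick_size))
}

# disjoint axis-aligned support boxes: the grid is sliced into slabs along
# its longest axis and each slab contributes the bounding box of the
# occupied bricks in itself and its neighbors (so trilinear bleed across a
# cut face is always covered), padded by one voxel transversally and
# extended one voxel into empty neighbor slabs. Line integration visits
# only these boxes, which makes sparse fields (point sources, thin tubes)
# cheap to project through.
grid_boxes <- function(grid, brick_size = 4L, slab_bricks = 2L) {
  dm <- grid$dims
  bd <- as.integer(ceiling(dm / brick_size))
  occ <- array(FALSE, bd)
  nz <- which(grid$values != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(matrix(0, 0, 6))
  bi <- (nz - 1L) %/% brick_size
  occ[unique(bi[, 1] + bd[1] * (bi[, 2] + bd[2] * bi[, 3])) + 1L] <- TRUE
  ax <- which.max(dm)
  tr <- setdiff(1:3, ax)
  nslab <- ceiling(bd[ax] / slab_bricks)
  slab_of <- (seq_len(bd[ax]) - 1L) %/% slab_bricks + 1L
  # occupied brick coordinates
  w <- which(occ, arr.ind = TRUE)
  sl <- slab_of[w[, ax]]
  boxes <- NULL
  occ_slab <- tabulate(sl, nslab) > 0
  for (s in which(occ_slab)) {
    nb <- w[sl %in% c(s - 1L, s, s + 1L), , drop = FALSE]
    # transverse voxel extent (0-based lo, exclusive hi), padded 1 voxel
    lo <- hi <- numeric(3)
    for (a in tr) {
      lo[a] <- max((min(nb[, a]) - 1L) * brick_size - 1L, 0L)
      hi[a] <- min(max(nb[, a]) * brick_size + 1L, dm[a])
    }
    lo[ax] <- (s - 1L) * slab_bricks * brick_size
    hi[ax] <- min(s * slab_bricks * brick_size, dm[ax])
    if (s == 1L || !occ_slab[s - 1L]) lo[ax] <- max(lo[ax] - 1L, 0L)
    if (s == nslab || !occ_slab[s + 1L]) hi[ax] <- min(hi[ax] + 1L, dm[ax])
    boxes <- rbind(boxes, c(grid$origin + lo * grid$spacing,
                            grid$origin + hi * grid$spacing))
  }
  boxes
}

# cache bricks and support boxes on the grid object
with_bricks <- function(grid, brick_size = 4L) {
  if (is.null(attr(grid, "bricks")))
    attr(grid, "bricks") <- grid_bricks(grid, brick_size)
  if (is.null(attr(grid, "boxes")))
    attr(grid, "boxes") <- grid_boxes(grid, brick_size)
  grid
}

grid_cpp_args <- function(grid, use_bricks = TRUE) {
  br <- attr(grid, "bricks")
  if (!use_bricks || is.null(br))
    br <- list(brick = integer(0), bdims = integer(0), bsz = 1L)
  bx <- attr(grid, "boxes")
  if (!use_bricks || is.null(bx)) bx <- matrix(0, 0, 6)
  # grid$values is passed as-is (a double array is a numeric vector with a
  # dim attribute); avoiding as.numeric() avoids copying the whole field on
  # every projector call
  list(values = grid$values, origin = grid$origin,
       spacing = grid$spacing, dims = as.integer(grid$dims),
       brick = br$brick, bdims = br$bdims, bsz = br$bsz, boxes = bx)
}

#' Read/write voxel grids as NIfTI
#'
#' Spacing and origin are carried in the NIfTI affine (mm units).
#'
#' @param grid a `voxel_grid`.
#' @param path file path (`.nii` / `.nii.gz`).
#' @export
write_voxel_grid <- function(grid, path) {
  img <- RNifti::asNifti(grid$values)
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing
  aff[1:3, 4] <- grid$origin + grid$spacing / 2   # center of voxel (0,0,0)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_voxel_grid
#' @export
read_voxel_grid <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  sp <- abs(diag(aff)[1:3])
  orig <- aff[1:3, 4] - sp / 2
  voxel_grid(array(as.numeric(img), dim = dim(img)[1:3]), orig, sp)
}

SPEED_OF_LIGHT_MM_PS <- 0.299792458

#' Gaussian time-of-flight localization model
#'
#' The coincidence timing resolution (CTR, FWHM in ps) localizes the
#' annihilation along the LOR with a Gaussian of FWHM `c * ctr / 2` mm.
#' TOF bins tile `[-range_mm, range_mm]` symmetrically about the LOR midpoint
#' (an odd number of bins, the central bin centered on 0).
#'
#' @param ctr_ps coincidence timing resolution, FWHM in ps (e.g. 250 ps gives
#'   a 37.5 mm kernel, 500 ps gives 75 mm).
#' @param bin_width TOF bin width in mm; default `kernel_fwhm / 3`.
#' @param range_mm half-range covered by the bins (mm); should cover the
#'   radial extent of the field of view plus a few kernel sigmas.
#' @param exact if `TRUE`, bin masses use the integrated (erf) Gaussian over
#'   the bin; otherwise the midpoint rule (kernel at bin center times width).
#' @return An object of class `tof_model` with `kernel_fwhm`, `sigma`,
#'   `bin_width`, `n_bins`, `bin_centers`.
#' @examples
#' tof_model(500)$kernel_fwhm  # 74.95 mm
#' @export
tof_model <- function(ctr_ps, bin_width = NULL, range_mm = 120,
                      exact = FALSE) {
  stopifnot(ctr_ps > 0, range_mm > 0)
  fwhm <- SPEED_OF_LIGHT_MM_PS * ctr_ps / 2
  if (is.null(bin_width)) bin_width <- fwhm / 3
  n_half <- ceiling(range_mm / bin_width)
  n_bins <- as.integer(2 * n_half + 1)
  centers <- (seq_len(n_bins) - (n_bins + 1) / 2) * bin_width
  structure(list(ctr_ps = ctr_ps, kernel_fwhm = fwhm,
                 sigma = fwhm / (2 * sqrt(2 * log(2))),
                 bin_width = bin_width, n_bins = n_bins,
                 bin_centers = centers, exact = isTRUE(exact)),
            class = "tof_model")
}

# C++ spec for a tof model; tbin 0-based per row, -1 = marginal over bins,
# NULL tof = no kernel
tof_cpp_spec <- function(tof, tbin = 0L) {
  if (is.null(tof))
    return(list(mode = 0L, sigma = 1.0, binw = 1.0, nbins = 1L,
                exact = FALSE, tbin = as.integer(tbin)))
  list(mode = 1L, sigma = tof$sigma, binw = tof$bin_width,
       nbins = tof$n_bins, exact = tof$exact, tbin = as.integer(tbin))
}

# signed midpoint offset -> 1-based bin index (NA outside the tiled range)
tof_bin_of <- function(tof, s) {
  i <- round(s / tof$bin_width) + (tof$n_bins + 1) / 2
  i[i < 1 | i > tof$n_bins] <- NA_integer_
  as.integer(i)
}
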
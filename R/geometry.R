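# Scanner geometry: blueprint construction, per-block rigid perturbations,
# crystal-voxel lookup tables, and local-to-global coordinate transforms.
#
# Conventions (documented, fixed):
#  * global frame: right-handed, z = scanner axis, origin at the geometric
#    center of the block arrangement; all coordinates in mm
#  * block-local frame: x = planar transaxial, y = depth-of-interaction (DOI)
#    pointing radially outward, z = axial
#  * rotation angles are stored in degrees everywhere; the per-block rotation
#    is composed intrinsically X -> Y -> Z about the block's blueprint axes.

ROT_ORDER <- c("x", "y", "z")

#' Construct a blueprint scanner geometry
#'
#' A blueprint holds designed block-center positions and orthonormal local
#' axes for `Ndet` detector blocks, together with the common block dimensions.
#'
#' @param positions Ndet x 3 matrix of block centers (mm).
#' @param axes_x,axes_y,axes_z Ndet x 3 matrices of unit local axes
#'   (planar transaxial, DOI/radial, axial).
#' @param block_dims length-3 block extents along the local x, y, z axes (mm).
#' @param meta optional list of layout metadata (blocks per ring, rings, ...).
#' @return An object of class `pet_blueprint`.
#' @export
blueprint_geometry <- function(positions, axes_x, axes_y, axes_z, block_dims,
                               meta = list()) {
  positions <- as.matrix(positions)
  ndet <- nrow(positions)
  stopifnot(ncol(positions) == 3L, nrow(axes_x) == ndet, nrow(axes_y) == ndet,
            nrow(axes_z) == ndet, length(block_dims) == 3L)
  bp <- structure(list(positions = positions, axes_x = as.matrix(axes_x),
                       axes_y = as.matrix(axes_y), axes_z = as.matrix(axes_z),
                       block_dims = as.numeric(block_dims), ndet = ndet,
                       meta = meta),
                  class = "pet_blueprint")
  check_blueprint(bp)
  bp
}

check_blueprint <- function(bp, tol = 1e-9) {
  for (nm in c("axes_x", "axes_y", "axes_z")) {
    nrm <- sqrt(rowSums(bp[[nm]]^2))
    if (any(abs(nrm - 1) > tol))
      stop("axis vectors in ", nm, " are not unit length")
  }
  for (d in seq_len(bp$ndet)) {
    A <- rbind(bp$axes_x[d, ], bp$axes_y[d, ], bp$axes_z[d, ])
    if (max(abs(A %*% t(A) - diag(3))) > 1e-8)
      stop("local axes of block ", d, " are not orthonormal")
    if (abs(det(A) - 1) > 1e-8)
      stop("local axes of block ", d, " are not right-handed")
  }
  invisible(bp)
}

#' Cylindrical multi-ring blueprint
#'
#' Blocks are equally spaced in azimuth within each ring; the local DOI axis
#' points radially outward so the crystal front face looks at the scanner
#' center, and block centers sit at `inner_radius + block_dims[2] / 2`.
#'
#' @param blocks_per_ring,rings layout counts.
#' @param inner_radius radial distance of the block front face (mm).
#' @param block_dims block extents (local x = planar, y = DOI, z = axial), mm.
#' @param ring_pitch axial ring spacing (mm); defaults to the axial extent.
#' @return A `pet_blueprint`.
#' @examples
#' bp <- cylindrical_blueprint(8, 3, 75, c(48, 10, 48))
#' bp$ndet  # 24
#' @export
cylindrical_blueprint <- function(blocks_per_ring, rings = 1L,
                                  inner_radius, block_dims = c(48, 10, 48),
                                  ring_pitch = NULL) {
  stopifnot(blocks_per_ring >= 1, rings >= 1, inner_radius > 0,
            all(block_dims > 0))
  if (is.null(ring_pitch)) ring_pitch <- block_dims[3]
  ndet <- blocks_per_ring * rings
  phi <- rep(2 * pi * (seq_len(blocks_per_ring) - 1L) / blocks_per_ring, rings)
  ring <- rep(seq_len(rings), each = blocks_per_ring)
  zc <- (ring - (rings + 1) / 2) * ring_pitch
  rad <- inner_radius + block_dims[2] / 2
  positions <- cbind(rad * cos(phi), rad * sin(phi), zc)
  axes_y <- cbind(cos(phi), sin(phi), 0)          # DOI, radially outward
  axes_z <- cbind(0, 0, rep(1, ndet))             # axial
  axes_x <- cbind(sin(phi), -cos(phi), 0)         # planar, = Y x Z
  blueprint_geometry(positions, axes_x, axes_y, axes_z, block_dims,
                     meta = list(blocks_per_ring = as.integer(blocks_per_ring),
                                 rings = as.integer(rings),
                                 inner_radius = inner_radius,
                                 ring_pitch = ring_pitch,
                                 ring = as.integer(ring),
                                 in_ring = rep(seq_len(blocks_per_ring),
                                               rings) - 1L))
}

#' Per-block alignment parameters
#'
#' Translations in mm and rotations in degrees about the block's blueprint
#' axes (intrinsic X -> Y -> Z composition). An optional `share_map` ties
#' several detectors to one learnable parameter group.
#'
#' @param translations,rotations Ndet x 3 matrices (or group x 3 when
#'   `share_map` is given).
#' @param share_map optional integer vector (length Ndet) of 1-based group
#'   indices; must cover every detector.
#' @export
alignment_params <- function(translations, rotations, share_map = NULL) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  stopifnot(ncol(translations) == 3L, ncol(rotations) == 3L,
            nrow(translations) == nrow(rotations),
            all(is.finite(translations)), all(is.finite(rotations)))
  if (!is.null(share_map)) {
    share_map <- as.integer(share_map)
    if (anyNA(share_map) || min(share_map) < 1L ||
        max(share_map) > nrow(translations))
      stop("share_map must map every detector to a valid parameter group")
  }
  structure(list(translations = translations, rotations = rotations,
                 share_map = share_map),
            class = "pet_alignment_params")
}

#' @rdname alignment_params
#' @param ndet number of detector blocks.
#' @export
zero_alignment <- function(ndet) {
  alignment_params(matrix(0, ndet, 3), matrix(0, ndet, 3))
}

#' Gaussian random per-block misalignment
#'
#' Draws i.i.d. zero-mean Gaussian translations (sd `sigma_t` mm) and
#' rotations (sd `sigma_r` degrees), reproducible under a fixed seed.
#'
#' @param ndet number of blocks.
#' @param sigma_t,sigma_r standard deviations (mm, degrees).
#' @export
perturb_alignment <- function(ndet, sigma_t, sigma_r) {
  stopifnot(sigma_t >= 0, sigma_r >= 0)
  alignment_params(matrix(rnorm(3 * ndet, 0, sigma_t), ndet, 3),
                   matrix(rnorm(3 * ndet, 0, sigma_r), ndet, 3))
}

# expand group-level parameters to per-detector matrices
expand_params <- function(params, ndet) {
  if (is.null(params$share_map)) {
    stopifnot(nrow(params$translations) == ndet)
    return(params)
  }
  stopifnot(length(params$share_map) == ndet)
  alignment_params(params$translations[params$share_map, , drop = FALSE],
                   params$rotations[params$share_map, , drop = FALSE])
}

rodrigues <- function(axis, theta_rad) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta_rad) * K + (1 - cos(theta_rad)) * (K %*% K)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

skew3 <- function(a) {
  matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
}

#' Rotation matrix about a block's local axes
#'
#' Composes the three single-axis rotations intrinsically in the order
#' X -> Y -> Z about the supplied (blueprint) axes:
#' `M = R(X, ax) R(Y, ay) R(Z, az)`, acting on column vectors. The order is a
#' documented convention; for the small angles this model targets (a few
#' degrees at most) order effects are second order.
#'
#' @param angles_deg length-3 rotation angles in degrees.
#' @param axes 3 x 3 matrix with rows X, Y, Z (orthonormal).
#' @param order permutation of c("x","y","z") giving the composition order.
#' @return A proper 3 x 3 rotation matrix.
#' @export
local_rotation_matrix <- function(angles_deg, axes, order = ROT_ORDER) {
  axes <- as.matrix(axes)
  if (max(abs(axes %*% t(axes) - diag(3))) > 1e-8)
    stop("axes must be orthonormal")
  idx <- match(order, c("x", "y", "z"))
  th <- angles_deg * pi / 180
  M <- diag(3)
  for (i in idx) M <- M %*% rodrigues(axes[i, ], th[i])
  M
}

# rotation matrix and its three angle derivatives (per degree) for one block
rotation_with_derivs <- function(angles_deg, axes, order = ROT_ORDER) {
  idx <- match(order, c("x", "y", "z"))
  th <- angles_deg * pi / 180
  Rs <- lapply(idx, function(i) rodrigues(axes[i, ], th[i]))
  M <- Rs[[1]] %*% Rs[[2]] %*% Rs[[3]]
  dM <- vector("list", 3)
  for (k in 1:3) {
    pos <- which(idx == k)   # position of axis k in the composition
    K <- skew3(axes[k, ])
    parts <- Rs
    parts[[pos]] <- K %*% Rs[[pos]]
    dM[[k]] <- (parts[[1]] %*% parts[[2]] %*% parts[[3]]) * (pi / 180)
  }
  list(M = M, dM = dM)
}

#' Apply alignment parameters to a blueprint
#'
#' Positions become `P + T`; each local axis is rotated by
#' [local_rotation_matrix()] evaluated at the block's angles. Share groups are
#' expanded first. The result is again a valid blueprint (orthonormal,
#' right-handed axes).
#'
#' @param blueprint a `pet_blueprint`.
#' @param params a `pet_alignment_params`.
#' @export
apply_alignment <- function(blueprint, params) {
  params <- expand_params(params, blueprint$ndet)
  if (nrow(params$translations) != blueprint$ndet)
    stop("parameter count does not match the number of detector blocks")
  pos <- blueprint$positions + params$translations
  bx <- blueprint$axes_x
  ay <- blueprint$axes_y
  az <- blueprint$axes_z
  nx <- ny <- nz <- matrix(0, blueprint$ndet, 3)
  for (d in seq_len(blueprint$ndet)) {
    A <- rbind(bx[d, ], ay[d, ], az[d, ])
    M <- local_rotation_matrix(params$rotations[d, ], A)
    nx[d, ] <- drop(M %*% bx[d, ])
    ny[d, ] <- drop(M %*% ay[d, ])
    nz[d, ] <- drop(M %*% az[d, ])
  }
  # renormalize against numerical drift, then validate
  nx <- nx / sqrt(rowSums(nx^2))
  ny <- ny / sqrt(rowSums(ny^2))
  nz <- nz / sqrt(rowSums(nz^2))
  blueprint_geometry(pos, nx, ny, nz, blueprint$block_dims, blueprint$meta)
}

#' Crystal-voxel lookup table
#'
#' Regular binning of the block volume into crystal voxels; `L(cr)` gives the
#' voxel center in the block-local frame, `half_extents` the in-voxel bounds
#' used for endpoint sampling. Crystal indices are 0-based and run fastest
#' along local x, then y (DOI), then z.
#'
#' @param block_dims block extents (local x, y, z), mm.
#' @param voxel_size length-3 crystal-voxel size (mm); must divide the block.
#' @return An object of class `pet_crystal_lut`.
#' @examples
#' lut <- crystal_lut(c(48, 10, 48), c(2, 2, 2))  # 24 x 5 x 24 voxels
#' lut$ncr
#' @export
crystal_lut <- function(block_dims, voxel_size) {
  stopifnot(length(block_dims) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  nvox <- round(block_dims / voxel_size)
  if (max(abs(nvox * voxel_size - block_dims)) > 1e-9)
    stop("voxel_size must tile block_dims exactly")
  ix <- seq_len(nvox[1]) - 1L
  iy <- seq_len(nvox[2]) - 1L
  iz <- seq_len(nvox[3]) - 1L
  g <- expand.grid(x = ix, y = iy, z = iz)   # x fastest: matches cr indexing
  centers <- cbind(-block_dims[1] / 2 + (g$x + 0.5) * voxel_size[1],
                   -block_dims[2] / 2 + (g$y + 0.5) * voxel_size[2],
                   -block_dims[3] / 2 + (g$z + 0.5) * voxel_size[3])
  half <- matrix(voxel_size / 2, nrow(centers), 3, byrow = TRUE)
  structure(list(centers = centers, half_extents = half,
                 nvox = as.integer(nvox), voxel_size = as.numeric(voxel_size),
                 block_dims = as.numeric(block_dims),
                 ncr = as.integer(prod(nvox))),
            class = "pet_crystal_lut")
}

# 0-based crystal index from block-local coordinates (vectorized)
crystal_index_from_local <- function(lut, local) {
  local <- as.matrix(local)
  i <- matrix(0L, nrow(local), 3)
  for (a in 1:3) {
    idx <- floor((local[, a] + lut$block_dims[a] / 2) / lut$voxel_size[a])
    i[, a] <- as.integer(pmin(pmax(idx, 0), lut$nvox[a] - 1L))
  }
  i[, 1] + lut$nvox[1] * (i[, 2] + lut$nvox[2] * i[, 3])
}

#' Global coordinates of crystal-voxel centers
#'
#' `p = P_d + L(cr)_x X_d + L(cr)_y Y_d + L(cr)_z Z_d` for crystal
#' `lambda = (d, cr)` under geometry `geometry` (vectorized over crystals).
#'
#' @param geometry a `pet_blueprint` (typically after [apply_alignment()]).
#' @param d,cr 0-based detector and crystal-voxel indices (recycled).
#' @param lut a `pet_crystal_lut`.
#' @export
crystal_center_global <- function(geometry, d, cr, lut) {
  n <- max(length(d), length(cr))
  d <- rep_len(as.integer(d), n)
  cr <- rep_len(as.integer(cr), n)
  if (any(d < 0L | d >= geometry$ndet)) stop("detector index out of range")
  if (any(cr < 0L | cr >= lut$ncr)) stop("crystal index out of range")
  L <- lut$centers[cr + 1L, , drop = FALSE]
  geometry$positions[d + 1L, , drop = FALSE] +
    L[, 1] * geometry$axes_x[d + 1L, , drop = FALSE] +
    L[, 2] * geometry$axes_y[d + 1L, , drop = FALSE] +
    L[, 3] * geometry$axes_z[d + 1L, , drop = FALSE]
}

#' Sample points inside a crystal voxel (global frame)
#'
#' Uniform draws within `center +/- half_extent` in the local frame,
#' transformed to global coordinates. Deterministic under `set.seed()`.
#'
#' @inheritParams crystal_center_global
#' @param n number of points.
#' @export
sample_crystal_points <- function(geometry, d, cr, lut, n) {
  stopifnot(n >= 1)
  d <- as.integer(d)[1]
  cr <- as.integer(cr)[1]
  if (d < 0L || d >= geometry$ndet) stop("detector index out of range")
  if (cr < 0L || cr >= lut$ncr) stop("crystal index out of range")
  off <- matrix(runif(3 * n, -1, 1), n, 3) *
    matrix(lut$half_extents[cr + 1L, ], n, 3, byrow = TRUE)
  L <- matrix(lut$centers[cr + 1L, ], n, 3, byrow = TRUE) + off
  geometry$positions[rep(d + 1L, n), , drop = FALSE] +
    L[, 1] %o% geometry$axes_x[d + 1L, ] +
    L[, 2] %o% geometry$axes_y[d + 1L, ] +
    L[, 3] %o% geometry$axes_z[d + 1L, ]
}

# block-local coordinates of global points for one block (rows = points)
global_to_local <- function(geometry, d, points) {
  points <- as.matrix(points)
  rel <- sweep(points, 2, geometry$positions[d + 1L, ])
  cbind(rel %*% geometry$axes_x[d + 1L, ],
        rel %*% geometry$axes_y[d + 1L, ],
        rel %*% geometry$axes_z[d + 1L, ])
}

#' Read or write a blueprint as JSON
#'
#' Positions, the nine axis numbers per block, block dimensions and ring
#' metadata; coordinates in mm.
#'
#' @param blueprint a `pet_blueprint`.
#' @param path file path.
#' @export
write_blueprint <- function(blueprint, path) {
  jsonlite::write_json(list(positions = blueprint$positions,
                            axes_x = blueprint$axes_x,
                            axes_y = blueprint$axes_y,
                            axes_z = blueprint$axes_z,
                            block_dims = blueprint$block_dims,
                            meta = blueprint$meta[c("blocks_per_ring", "rings",
                                                    "inner_radius",
                                                    "ring_pitch")]),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_blueprint
#' @export
read_blueprint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bp <- blueprint_geometry(x$positions, x$axes_x, x$axes_y, x$axes_z,
                           x$block_dims, meta = as.list(x$meta))
  if (!is.null(bp$meta$blocks_per_ring)) {
    npr <- bp$meta$blocks_per_ring
    bp$meta$ring <- rep(seq_len(bp$meta$rings), each = npr)
    bp$meta$in_ring <- rep(seq_len(npr), bp$meta$rings) - 1L
  }
  bp
}

# flattened per-block arrays for the C++ kernels
geometry_cpp_arrays <- function(blueprint, params = NULL) {
  nd <- blueprint$ndet
  axes <- cbind(blueprint$axes_x, blueprint$axes_y, blueprint$axes_z)
  if (is.null(params)) {
    pos <- blueprint$positions
    rot <- matrix(rep(as.vector(t(diag(3))), each = nd), nd, 9)
    drot <- matrix(0, nd, 27)
  } else {
    params <- expand_params(params, nd)
    pos <- blueprint$positions + params$translations
    rot <- matrix(0, nd, 9)
    drot <- matrix(0, nd, 27)
    for (d in seq_len(nd)) {
      A <- rbind(blueprint$axes_x[d, ], blueprint$axes_y[d, ],
                 blueprint$axes_z[d, ])
      rd <- rotation_with_derivs(params$rotations[d, ], A)
      rot[d, ] <- as.vector(t(rd$M))
      drot[d, ] <- c(as.vector(t(rd$dM[[1]])), as.vector(t(rd$dM[[2]])),
                     as.vector(t(rd$dM[[3]])))
    }
  }
  list(pos = pos, axes = axes, rot = rot, drot = drot)
}
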
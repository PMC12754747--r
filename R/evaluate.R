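# Evaluation: Procrustes registration of geometries, per-axis alignment
# errors, and image metrics (PSNR, SSIM, COV, peak-to-valley ratio).

#' Least-squares rigid registration of two point sets (Kabsch/Procrustes)
#'
#' Finds the rotation and translation minimizing
#' `sum_i || R p_i + t - q_i ||^2` (no scaling, no reflection).
#'
#' @param estimated,reference N x 3 matrices (N >= 3, non-collinear).
#' @return list(rotation = 3 x 3, translation = length 3) of class
#'   `rigid_transform`.
#' @export
procrustes_align <- function(estimated, reference) {
  P <- as.matrix(estimated)
  Q <- as.matrix(reference)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  if (nrow(P) < 3) stop("need at least 3 points")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  X <- sweep(P, 2, cp)
  Y <- sweep(Q, 2, cq)
  H <- t(X) %*% Y
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate (collinear) point configuration")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  structure(list(rotation = R, translation = drop(cq - R %*% cp)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or to a geometry
#'
#' @param transform a `rigid_transform`.
#' @param x N x 3 point matrix or a `pet_blueprint` (positions and axes are
#'   both transformed).
#' @export
apply_rigid <- function(transform, x) {
  R <- transform$rotation
  tv <- transform$translation
  if (inherits(x, "pet_blueprint")) {
    return(blueprint_geometry(
      sweep(x$positions %*% t(R), 2, tv, "+"),
      x$axes_x %*% t(R), x$axes_y %*% t(R), x$axes_z %*% t(R),
      x$block_dims, x$meta))
  }
  sweep(as.matrix(x) %*% t(R), 2, tv, "+")
}

#' Per-axis alignment errors between two geometries
#'
#' Translation error per global axis i: mean over blocks of
#' `|P*_{d,i} - P^_{d,i}|`. Rotation error per local axis: mean over blocks
#' of the angle (degrees) between the corresponding local axis vectors.
#' With `procrustes = TRUE` the estimated geometry is first registered onto
#' the reference by a global rigid motion fitted on block positions (the
#' calibration cannot observe a common motion of scanner and phantom, so
#' only the relative alignment is meaningful).
#'
#' @param estimated,reference `pet_blueprint`s with equal block count.
#' @param procrustes register before scoring.
#' @return list of class `alignment_errors`: `delta_T` (mm, per global
#'   axis), `delta_R` (degrees, per local axis), per-detector residual
#'   matrices, and the fitted transform (if any).
#' @export
alignment_errors <- function(estimated, reference, procrustes = TRUE) {
  if (estimated$ndet != reference$ndet)
    stop("geometries have different block counts")
  tr <- NULL
  if (procrustes) {
    tr <- procrustes_align(estimated$positions, reference$positions)
    estimated <- apply_rigid(tr, estimated)
  }
  dP <- abs(reference$positions - estimated$positions)
  ang <- function(A, B) {
    d <- rowSums(A * B) / (sqrt(rowSums(A^2)) * sqrt(rowSums(B^2)))
    acos(pmin(pmax(d, -1), 1)) * 180 / pi
  }
  dR <- cbind(x = ang(reference$axes_x, estimated$axes_x),
              y = ang(reference$axes_y, estimated$axes_y),
              z = ang(reference$axes_z, estimated$axes_z))
  structure(list(delta_T = setNames(colMeans(dP), c("x", "y", "z")),
                 delta_R = setNames(colMeans(dR), c("x", "y", "z")),
                 per_detector_T = dP, per_detector_R = dR,
                 transform = tr),
            class = "alignment_errors")
}

#' @export
print.alignment_errors <- function(x, ...) {
  cat("alignment errors (mean over blocks)\n")
  cat(sprintf("  dT (mm):  x %.4f  y %.4f  z %.4f\n", x$delta_T[1],
              x$delta_T[2], x$delta_T[3]))
  cat(sprintf("  dR (deg): x %.3f  y %.3f  z %.3f\n", x$delta_R[1],
              x$delta_R[2], x$delta_R[3]))
  invisible(x)
}

sum_normalize <- function(v) {
  s <- sum(v)
  if (s <= 0) stop("cannot sum-normalize a non-positive image")
  v / s
}

#' Peak signal-to-noise ratio between two images
#'
#' Images are sum-normalized first; `PSNR = 10 log10(max(I)^2 / MSE)`.
#' Identical images yield `Inf`.
#'
#' @param reference,test equally shaped arrays or `voxel_grid`s.
#' @export
psnr <- function(reference, test) {
  I <- if (inherits(reference, "voxel_grid")) reference$values else reference
  J <- if (inherits(test, "voxel_grid")) test$values else test
  stopifnot(all(dim(I) == dim(J)))
  I <- sum_normalize(as.numeric(I))
  J <- sum_normalize(as.numeric(J))
  mse <- mean((I - J)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(I)^2 / mse)
}

#' Global structural similarity index
#'
#' Whole-image SSIM with the standard constants `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2`, `L` the reference dynamic range; images are
#' sum-normalized first.
#'
#' @inheritParams psnr
#' @export
ssim <- function(reference, test) {
  I <- if (inherits(reference, "voxel_grid")) reference$values else reference
  J <- if (inherits(test, "voxel_grid")) test$values else test
  stopifnot(all(dim(I) == dim(J)))
  I <- sum_normalize(as.numeric(I))
  J <- sum_normalize(as.numeric(J))
  L <- diff(range(I))
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  mI <- mean(I)
  mJ <- mean(J)
  vI <- mean((I - mI)^2)
  vJ <- mean((J - mJ)^2)
  cIJ <- mean((I - mI) * (J - mJ))
  ((2 * mI * mJ + C1) * (2 * cIJ + C2)) /
    ((mI^2 + mJ^2 + C1) * (vI + vJ + C2))
}

#' Coefficient of variation inside a uniform region
#'
#' `100 * sd / mean` (population sd) of the image inside the mask.
#'
#' @param image array or `voxel_grid`.
#' @param mask logical array of the same shape, nonempty.
#' @export
cov_uniform_region <- function(image, mask) {
  I <- if (inherits(image, "voxel_grid")) image$values else image
  stopifnot(all(dim(I) == dim(mask)))
  v <- as.numeric(I)[as.logical(mask)]
  if (length(v) == 0) stop("empty mask")
  m <- mean(v)
  if (m <= 0) stop("zero or negative mean in the uniform region")
  100 * sqrt(mean((v - m)^2)) / m
}

# trilinear sampling of a voxel grid at arbitrary points (R-side utility)
interp3 <- function(grid, points) {
  p <- as_point_matrix(points)
  ga <- grid_cpp_args(grid, use_bricks = FALSE)
  # evaluate via a degenerate short segment through each point
  eps <- min(grid$spacing) * 1e-3
  p0 <- p
  p0[, 1] <- p0[, 1] - eps / 2
  p1 <- p
  p1[, 1] <- p1[, 1] + eps / 2
  cpp_line_integrals(ga$values, ga$origin, ga$spacing, ga$dims, ga$brick,
                     ga$bdims, ga$bsz, ga$boxes, p0, p1, tof_cpp_spec(NULL),
                     FALSE, NULL) / eps
}

#' Peak-to-valley ratios for a hot-rod reconstruction
#'
#' For each rod diameter: mean image intensity at the rod centers divided by
#' the mean intensity at the inter-rod midpoints, averaged over several
#' axial sampling planes. The sampling locations come from the synthetic rod
#' layout, making the profile placement reproducible.
#'
#' @param image reconstructed `voxel_grid`.
#' @param phantom the `pet_phantom` of kind `"hotrod"` that generated the
#'   data.
#' @param n_axial number of axial sampling planes.
#' @return Named numeric vector of PVRs (one per rod diameter); `Inf` when a
#'   valley mean is zero.
#' @export
peak_to_valley <- function(image, phantom, n_axial = 5) {
  stopifnot(inherits(phantom, "pet_phantom"), phantom$kind == "hotrod")
  zs <- seq(-0.3, 0.3, length.out = n_axial) * phantom$axial_length
  out <- numeric(length(phantom$layout))
  names(out) <- names(phantom$layout)
  for (k in seq_along(phantom$layout)) {
    l <- phantom$layout[[k]]
    pk <- do.call(rbind, lapply(zs, function(z) cbind(l$centers, z)))
    vl <- if (is.null(l$valleys)) NULL
          else do.call(rbind, lapply(zs, function(z) cbind(l$valleys, z)))
    peak <- mean(interp3(image, pk))
    valley <- if (is.null(vl)) NA_real_ else mean(interp3(image, vl))
    out[k] <- if (is.na(valley)) NA_real_
              else if (valley == 0) Inf else peak / valley
  }
  out
}
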
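test_that("procrustes registration recovers rigid motions exactly", {
  set.seed(60)
  P <- matrix(rnorm(30), 10, 3)
  # identical sets: identity transform
  tr <- procrustes_align(P, P)
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tr$translation)), 1e-9)
  # known rigid motion recovered to machine precision
  ax <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(ax) < 0) ax[, 1] <- -ax[, 1]
  tv <- c(3, -2, 5)
  Q <- sweep(P %*% t(ax), 2, tv, "+")
  tr <- procrustes_align(P, Q)
  expect_lt(max(abs(tr$rotation - ax)), 1e-9)
  expect_lt(max(abs(tr$translation - tv)), 1e-9)
  # residual after alignment never exceeds residual before
  for (i in 1:10) {
    Q2 <- Q + matrix(rnorm(30, 0, 0.3), 10, 3)
    tr2 <- procrustes_align(P, Q2)
    before <- sum((P - Q2)^2)
    after <- sum((apply_rigid(tr2, P) - Q2)^2)
    expect_lte(after, before + 1e-12)
  }
  expect_error(procrustes_align(matrix(rep(1:3, 5), 5, 3, byrow = TRUE),
                                matrix(rnorm(15), 5, 3)), "degenerate")
})

test_that("alignment errors behave under identity, global motion, and single-block rotation", {
  bp <- cylindrical_blueprint(8, 2, 60, c(24, 10, 24))
  e0 <- alignment_errors(bp, bp)
  expect_equal(unname(e0$delta_T), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(e0$delta_R), c(0, 0, 0), tolerance = 1e-6)
  # a uniform shift of all blocks is removed by Procrustes
  sh <- bp
  sh$positions <- sweep(sh$positions, 2, c(0.3, 0, 0), "+")
  e1 <- alignment_errors(sh, bp, procrustes = TRUE)
  expect_lt(max(e1$delta_T), 1e-9)
  # without registration it is visible
  e2 <- alignment_errors(sh, bp, procrustes = FALSE)
  expect_equal(unname(e2$delta_T), c(0.3, 0, 0), tolerance = 1e-12)
  # a common rigid motion applied to both geometries: rotation errors and
  # the total translation residual are invariant (the per-axis translation
  # decomposition follows the rotated frame); a common pure translation
  # leaves every component unchanged
  set.seed(61)
  g <- apply_alignment(bp, perturb_alignment(bp$ndet, 1, 1))
  tr <- list(rotation = local_rotation_matrix(c(5, -3, 8), diag(3)),
             translation = c(4, 1, -2))
  class(tr) <- "rigid_transform"
  ea <- alignment_errors(g, bp)
  eb <- alignment_errors(apply_rigid(tr, g), apply_rigid(tr, bp))
  expect_equal(ea$delta_R, eb$delta_R, tolerance = 1e-7)
  expect_equal(sum(rowSums(ea$per_detector_T^2)),
               sum(rowSums(eb$per_detector_T^2)), tolerance = 1e-7)
  trt <- list(rotation = diag(3), translation = c(4, 1, -2))
  class(trt) <- "rigid_transform"
  ec <- alignment_errors(apply_rigid(trt, g), apply_rigid(trt, bp))
  expect_equal(ea$delta_T, ec$delta_T, tolerance = 1e-8)
  expect_equal(ea$delta_R, ec$delta_R, tolerance = 1e-8)
  # one block rotated about its own z axis: x and y axes tilt by that angle,
  # z axis unchanged; independent oracle via direct angle computation
  p <- zero_alignment(bp$ndet)
  p$rotations[3, 3] <- 1
  g2 <- apply_alignment(bp, p)
  e3 <- alignment_errors(g2, bp, procrustes = FALSE)
  expect_equal(unname(e3$delta_R["x"]), 1 / bp$ndet, tolerance = 1e-6)
  expect_equal(unname(e3$delta_R["y"]), 1 / bp$ndet, tolerance = 1e-6)
  expect_equal(unname(e3$delta_R["z"]), 0, tolerance = 1e-9)
  oracle <- acos(sum(g2$axes_x[3, ] * bp$axes_x[3, ])) * 180 / pi
  expect_equal(unname(e3$per_detector_R[3, "x"]), oracle, tolerance = 1e-9)
})

test_that("image metrics match their closed forms", {
  set.seed(62)
  I <- array(runif(8 * 7 * 6), c(8, 7, 6))
  # PSNR
  expect_identical(psnr(I, I), Inf)
  J <- I + 1e-3
  In <- I / sum(I); Jn <- J / sum(J)
  direct <- 10 * log10(max(In)^2 / mean((In - Jn)^2))
  expect_equal(psnr(I, J), direct, tolerance = 1e-9)
  # SSIM: identical images give 1; anti-correlated images go negative
  expect_equal(ssim(I, I), 1, tolerance = 1e-12)
  K <- max(I) - I + 0.1
  expect_lt(ssim(I, K), 0)
  # direct formula evaluation
  In <- I / sum(I); Kn <- K / sum(K)
  L <- diff(range(In)); C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mI <- mean(In); mK <- mean(Kn)
  vI <- mean((In - mI)^2); vK <- mean((Kn - mK)^2)
  cIK <- mean((In - mI) * (Kn - mK))
  expect_equal(ssim(I, K),
               (2 * mI * mK + C1) * (2 * cIK + C2) /
                 ((mI^2 + mK^2 + C1) * (vI + vK + C2)),
               tolerance = 1e-9)
  # COV: constant region 0; {1,3} in equal proportion gives 50%
  img <- array(1, c(4, 4, 2))
  msk <- array(TRUE, c(4, 4, 2))
  expect_equal(cov_uniform_region(img, msk), 0)
  img[1:2, , ] <- 1; img[3:4, , ] <- 3
  expect_equal(cov_uniform_region(img, msk), 50)
  expect_error(cov_uniform_region(img, array(FALSE, dim(img))), "empty")
})

test_that("peak-to-valley ratios hit closed forms and are scale invariant", {
  ph <- phantom_hotrod(diameters = c(2, 1.5), sector_radius = 10,
                       axial_length = 6, shell_width = 0)
  # flat image: PVR 1 for all diameters
  flat <- voxel_grid(array(1, c(60, 60, 20)), c(-15, -15, -5),
                     c(0.5, 0.5, 0.5))
  pv <- peak_to_valley(flat, ph)
  expect_equal(unname(pv), rep(1, 2), tolerance = 1e-9)
  # synthetic image with peaks 4 at rod centers, 1 elsewhere
  img <- array(1, c(120, 120, 20))
  grid <- voxel_grid(img, c(-15, -15, -5), c(0.25, 0.25, 0.5))
  for (l in ph$layout) {
    for (i in seq_len(nrow(l$centers))) {
      ix <- round((l$centers[i, 1] + 15) / 0.25 + 0.5)
      iy <- round((l$centers[i, 2] + 15) / 0.25 + 0.5)
      grid$values[ix + (-2:2), iy + (-2:2), ] <- 4
    }
  }
  pv <- peak_to_valley(grid, ph)
  expect_equal(unname(pv), rep(4, 2), tolerance = 0.05)
  # invariant under global intensity scaling
  g2 <- grid
  g2$values <- g2$values * 37.5
  expect_equal(peak_to_valley(g2, ph), pv, tolerance = 1e-9)
})
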
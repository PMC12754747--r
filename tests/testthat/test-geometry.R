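test_that("local rotation matrices are proper rotations with the documented convention", {
  # zero angles give the identity
  expect_equal(local_rotation_matrix(c(0, 0, 0), diag(3)), diag(3))
  # quarter turn about global z maps x to y
  M <- local_rotation_matrix(c(0, 0, 90), diag(3))
  expect_equal(drop(M %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  # random angles: orthogonal with unit determinant
  set.seed(1)
  for (i in 1:20) {
    ax <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(ax) < 0) ax[, 1] <- -ax[, 1]
    M <- local_rotation_matrix(runif(3, -180, 180), t(ax))
    expect_lt(max(abs(t(M) %*% M - diag(3))), 1e-9)
    expect_equal(det(M), 1, tolerance = 1e-9)
  }
  expect_error(local_rotation_matrix(c(1, 2, 3), matrix(1, 3, 3)),
               "orthonormal")
})

test_that("small-angle single-axis rotations commute to first order", {
  set.seed(2)
  ax <- diag(3)
  th <- runif(3, -0.1, 0.1)
  M1 <- local_rotation_matrix(th, ax, order = c("x", "y", "z"))
  M2 <- local_rotation_matrix(th, ax, order = c("z", "y", "x"))
  expect_lt(max(abs(M1 - M2)) / max(abs(M1)), 1e-5)
})

test_that("apply_alignment translates, rotates, and round-trips", {
  bp <- toy_scanner()
  # zero parameters reproduce the blueprint exactly
  out <- apply_alignment(bp, zero_alignment(bp$ndet))
  expect_equal(out$positions, bp$positions)
  expect_equal(out$axes_x, bp$axes_x)
  # pure translation moves one block, axes untouched
  p <- zero_alignment(bp$ndet)
  p$translations[1, ] <- c(1, 2, 3)
  out <- apply_alignment(bp, p)
  expect_equal(out$positions[1, ], bp$positions[1, ] + c(1, 2, 3))
  expect_equal(out$axes_y, bp$axes_y)
  # applying parameters then their exact inverse recovers the blueprint
  set.seed(3)
  pars <- perturb_alignment(bp$ndet, 1, 2)
  fwd <- apply_alignment(bp, pars)
  # inverse: rotate back about the already-rotated axes, undo translation
  back <- fwd
  for (d in seq_len(bp$ndet)) {
    A <- rbind(bp$axes_x[d, ], bp$axes_y[d, ], bp$axes_z[d, ])
    M <- local_rotation_matrix(pars$rotations[d, ], A)
    back$positions[d, ] <- fwd$positions[d, ] - pars$translations[d, ]
    back$axes_x[d, ] <- drop(t(M) %*% fwd$axes_x[d, ])
    back$axes_y[d, ] <- drop(t(M) %*% fwd$axes_y[d, ])
    back$axes_z[d, ] <- drop(t(M) %*% fwd$axes_z[d, ])
  }
  expect_lt(max(abs(back$positions - bp$positions)), 1e-9)
  expect_lt(max(abs(back$axes_x - bp$axes_x)), 1e-9)
  # alignment always preserves orthonormality (validated on construction)
  expect_s3_class(apply_alignment(bp, perturb_alignment(bp$ndet, 3, 10)),
                  "pet_blueprint")
  expect_error(apply_alignment(bp, zero_alignment(7)))
})

test_that("crystal centers transform linearly into the global frame", {
  bp <- toy_scanner()
  lut <- crystal_lut(bp$block_dims, c(4, 5, 4))
  # the center crystal of the lut is offset from the block position only by
  # its local center
  p <- crystal_center_global(bp, 0L, 0L, lut)
  manual <- bp$positions[1, ] + lut$centers[1, 1] * bp$axes_x[1, ] +
    lut$centers[1, 2] * bp$axes_y[1, ] + lut$centers[1, 3] * bp$axes_z[1, ]
  expect_equal(drop(p), manual, tolerance = 1e-12)
  # identity axes: center + local offset
  bp2 <- blueprint_geometry(matrix(c(5, 6, 7), 1, 3), matrix(c(1, 0, 0), 1),
                            matrix(c(0, 1, 0), 1), matrix(c(0, 0, 1), 1),
                            c(20, 10, 20))
  p2 <- crystal_center_global(bp2, 0L, 5L, lut)
  expect_equal(drop(p2), c(5, 6, 7) + lut$centers[6, ], tolerance = 1e-12)
  # arbitrary rotated frame equals an explicit dense matrix-vector transform
  set.seed(4)
  pars <- perturb_alignment(bp$ndet, 2, 15)
  g <- apply_alignment(bp, pars)
  for (k in 1:10) {
    d <- sample(0:(bp$ndet - 1), 1)
    cr <- sample(0:(lut$ncr - 1), 1)
    A <- cbind(g$axes_x[d + 1, ], g$axes_y[d + 1, ], g$axes_z[d + 1, ])
    expct <- g$positions[d + 1, ] + drop(A %*% lut$centers[cr + 1, ])
    expect_equal(drop(crystal_center_global(g, d, cr, lut)), expct,
                 tolerance = 1e-9)
  }
  expect_error(crystal_center_global(bp, 99L, 0L, lut), "range")
  expect_error(crystal_center_global(bp, 0L, 9999L, lut), "range")
})

test_that("crystal point sampling stays inside the voxel and is unbiased", {
  bp <- toy_scanner()
  lut <- crystal_lut(bp$block_dims, c(4, 5, 4))
  set.seed(5)
  pts <- sample_crystal_points(bp, 1L, 7L, lut, 2000)
  loc <- petalign:::global_to_local(bp, 1L, pts)
  ctr <- lut$centers[8, ]
  he <- lut$half_extents[8, ]
  for (a in 1:3) {
    expect_true(all(loc[, a] >= ctr[a] - he[a] - 1e-9))
    expect_true(all(loc[, a] <= ctr[a] + he[a] + 1e-9))
    # mean within 4 standard errors of the uniform distribution
    se <- he[a] / sqrt(3) / sqrt(nrow(loc))
    expect_lt(abs(mean(loc[, a]) - ctr[a]), 4 * se)
  }
  # determinism under a fixed seed
  set.seed(9); a <- sample_crystal_points(bp, 0L, 0L, lut, 5)
  set.seed(9); b <- sample_crystal_points(bp, 0L, 0L, lut, 5)
  expect_identical(a, b)
})

test_that("cylindrical blueprints have the documented layout", {
  bp <- cylindrical_blueprint(8, 3, 75, c(48, 10, 48))
  expect_equal(bp$ndet, 24L)
  phi <- atan2(bp$positions[1:8, 2], bp$positions[1:8, 1])
  dphi <- diff(phi) %% (2 * pi)
  expect_equal(dphi, rep(2 * pi / 8, 7), tolerance = 1e-12)
  # transaxial block-center distance = inner radius + half DOI depth
  expect_equal(sqrt(rowSums(bp$positions[, 1:2]^2)),
               rep(80, 24), tolerance = 1e-12)
  # set-invariance under rotation by one block pitch
  th <- 2 * pi / 8
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- bp$positions %*% t(Rz)
  d <- sapply(seq_len(24), function(i)
    min(sqrt(rowSums(sweep(bp$positions, 2, rot[i, ])^2))))
  expect_lt(max(d), 1e-9)
})

test_that("gaussian perturbations have the right scale and are reproducible", {
  set.seed(11)
  p <- perturb_alignment(3000, 2, 0.5)
  expect_lt(abs(sd(p$translations) - 2) / 2, 0.05)
  expect_lt(abs(sd(p$rotations) - 0.5) / 0.5, 0.05)
  expect_identical(perturb_alignment(5, 0, 0)$translations, matrix(0, 5, 3))
  set.seed(12); a <- perturb_alignment(6, 1, 1)
  set.seed(12); b <- perturb_alignment(6, 1, 1)
  expect_identical(a, b)
})

test_that("share maps tie parameters and must cover all detectors", {
  bp <- toy_scanner()
  pars <- alignment_params(matrix(1:6 / 10, 2, 3), matrix(0, 2, 3),
                           share_map = c(1L, 1L, 2L, 2L))
  ex <- petalign:::expand_params(pars, 4L)
  expect_equal(ex$translations[1, ], ex$translations[2, ])
  expect_equal(ex$translations[3, ], ex$translations[4, ])
  expect_error(alignment_params(matrix(0, 2, 3), matrix(0, 2, 3),
                                share_map = c(1L, 3L, 1L, 1L)), "share_map")
})

test_that("blueprint JSON round-trips", {
  bp <- cylindrical_blueprint(6, 2, 40, c(24, 10, 24))
  f <- tempfile(fileext = ".json")
  write_blueprint(bp, f)
  bp2 <- read_blueprint(f)
  expect_equal(bp2$positions, bp$positions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(bp2$axes_z, bp$axes_z, tolerance = 1e-12, ignore_attr = TRUE)
  unlink(f)
})
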
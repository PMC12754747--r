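test_that("line integrals match closed forms and a dense quadrature oracle", {
  # constant field: value * segment length
  gc_ <- voxel_grid(array(2, c(30, 30, 30)), c(-15, -15, -15), c(1, 1, 1))
  p0 <- c(-10, -3, 2); p1 <- c(9, 4, -6)
  expect_equal(line_integral(gc_, p0, p1), 2 * sqrt(sum((p1 - p0)^2)),
               tolerance = 1e-6)
  # fully outside the grid
  expect_equal(line_integral(gc_, c(40, 40, 0), c(40, 50, 3)), 0)
  expect_error(line_integral(gc_, p0, p0), "degenerate")
  # random smooth fields vs dense trilinear sampling
  g <- blob_grid(seed = 42)
  set.seed(43)
  for (i in 1:25) {
    p0 <- runif(3, -25, 25)
    tgt <- runif(3, -6, 6)
    p1 <- tgt + (tgt - p0) / sqrt(sum((tgt - p0)^2)) * 30
    a <- line_integral(g, p0, p1)
    b <- dense_line_integral(g, p0, p1)
    if (b > 0.5) expect_lt(abs(a - b) / b, 0.005)
  }
})

test_that("attenuation follows Beer-Lambert and is monotone in the map", {
  z <- voxel_grid(array(0, c(20, 20, 20)), c(-10, -10, -10), c(1, 1, 1))
  expect_equal(attenuation_factor(z, c(-8, 0, 0), c(8, 1, 1)), 1)
  mu <- 0.05
  u <- voxel_grid(array(mu, c(20, 20, 20)), c(-10, -10, -10), c(1, 1, 1))
  p0 <- c(-7, -2, 1); p1 <- c(6, 3, -2)
  s <- sqrt(sum((p1 - p0)^2))
  expect_equal(attenuation_factor(u, p0, p1), exp(-mu * s), tolerance = 1e-5)
  # increasing any voxel never increases the factor
  set.seed(44)
  g <- blob_grid(seed = 45)
  base <- attenuation_factor(g, c(-25, 1, 0), c(25, -2, 1))
  for (i in 1:10) {
    g2 <- g
    idx <- sapply(g$dims, function(n) sample(5:(n - 5), 1))
    g2$values[idx[1], idx[2], idx[3]] <- g2$values[idx[1], idx[2], idx[3]] +
      runif(1, 0, 2)
    expect_lte(attenuation_factor(g2, c(-25, 1, 0), c(25, -2, 1)), base)
  }
})

test_that("tof model constants and kernel behavior are consistent", {
  tof <- tof_model(500)
  expect_equal(tof$kernel_fwhm, 74.94811, tolerance = 1e-6)
  tof <- tof_model(250, range_mm = 60, exact = TRUE)
  g <- blob_grid(seed = 46)
  # empty field
  z <- voxel_grid(array(0, c(10, 10, 10)), c(-5, -5, -5), c(1, 1, 1))
  expect_equal(tof_weighted_integral(z, c(-4, 0, 0), c(4, 0, 0),
                                     (tof$n_bins + 1) / 2, tof), 0)
  # hot voxel far (>= 5 FWHM) from an off-center bin is suppressed
  hot <- array(0, c(300, 12, 12))
  hot[150, 6, 6] <- 1   # center (-0.5, -0.5, -0.5)
  gh <- voxel_grid(hot, c(-150, -6, -6), c(1, 1, 1))
  tof2 <- tof_model(150, range_mm = 140, exact = TRUE)
  p0 <- c(-160, -0.5, -0.5); p1 <- c(160, -0.5, -0.5)
  ctr_bin <- (tof2$n_bins + 1) / 2
  v_match <- tof_weighted_integral(gh, p0, p1, ctr_bin, tof2)
  far_bin <- which.min(abs(tof2$bin_centers - 0.5 -
                             5.5 * tof2$kernel_fwhm))
  v_far <- tof_weighted_integral(gh, p0, p1, far_bin, tof2)
  expect_gt(v_match, 0)
  expect_lt(v_far / v_match, 1e-6)
  # marginalizing over bins recovers the plain integral
  tot <- sum(sapply(seq_len(tof$n_bins), function(t)
    tof_weighted_integral(g, c(-30, 0, 0), c(30, 3, 1), t, tof)))
  plain <- line_integral(g, c(-30, 0, 0), c(30, 3, 1))
  expect_lt(abs(tot - plain) / plain, 0.01)
})

test_that("expected counts factorize and reduce to a center-line oracle", {
  bp <- toy_scanner()
  lut <- crystal_lut(bp$block_dims, c(4, 5, 4))
  g <- blob_grid(seed = 47)
  tof <- tof_model(250, range_mm = 50, exact = TRUE)
  tb <- (tof$n_bins + 1) / 2
  # zero efficiency kills the bin regardless of geometry
  E <- efficiency_table(bp$ndet, lut$ncr, 1)
  E[1, ] <- 0
  expect_equal(expected_count(0L, 3L, 2L, 5L, tb, geometry = bp, lut = lut,
                              activity = g, efficiencies = E, tof = tof),
               0)
  # unit efficiencies, no attenuation: the rate is the TOF-weighted integral
  # alone; with vanishing crystal extents it equals center-to-center
  lut0 <- lut
  lut0$half_extents[] <- 1e-9
  mu <- expected_count(0L, 3L, 2L, 5L, tb, geometry = bp, lut = lut0,
                       activity = g, tof = tof, n_samples = 1L)
  p1 <- crystal_center_global(bp, 0L, 3L, lut)
  p2 <- crystal_center_global(bp, 2L, 5L, lut)
  oracle <- tof_weighted_integral(g, rbind(p1), rbind(p2), tb, tof)
  expect_equal(mu, oracle, tolerance = 1e-7)
  # nonnegative always
  set.seed(48)
  mus <- expected_count(rep(0L, 20), sample(0:(lut$ncr - 1), 20, TRUE),
                        rep(2L, 20), sample(0:(lut$ncr - 1), 20, TRUE),
                        sample(tof$n_bins, 20, TRUE), geometry = bp,
                        lut = lut, activity = g, tof = tof, n_samples = 3L)
  expect_true(all(mus >= 0))
  expect_error(expected_count(1L, 0L, 1L, 1L, tb, geometry = bp, lut = lut,
                              activity = g, tof = tof), "distinct")
})

test_that("swapping endpoints with a mirrored TOF bin leaves the rate unchanged", {
  bp <- toy_scanner()
  lut <- crystal_lut(bp$block_dims, c(4, 5, 4))
  lut$half_extents[] <- 1e-9   # remove sampling stochasticity
  g <- blob_grid(seed = 49)
  tof <- tof_model(250, range_mm = 50, exact = TRUE)
  set.seed(50)
  for (i in 1:8) {
    cr1 <- sample(0:(lut$ncr - 1), 1); cr2 <- sample(0:(lut$ncr - 1), 1)
    t <- sample(tof$n_bins, 1)
    tm <- tof$n_bins + 1 - t  # mirrored bin
    a <- expected_count(0L, cr1, 2L, cr2, t, geometry = bp, lut = lut,
                        activity = g, tof = tof, n_samples = 1L)
    b <- expected_count(2L, cr2, 0L, cr1, tm, geometry = bp, lut = lut,
                        activity = g, tof = tof, n_samples = 1L)
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("forward-model gradients match central finite differences", {
  bp <- toy_scanner()
  lut <- crystal_lut(bp$block_dims, c(4, 5, 4))
  g <- blob_grid(seed = 51)
  tof <- tof_model(250, range_mm = 50, exact = TRUE)
  set.seed(52)
  pars <- alignment_params(matrix(rnorm(12, 0, 0.5), 4, 3),
                           matrix(rnorm(12, 0, 0.5), 4, 3))
  n <- 15
  d1 <- sample(0:2, n, TRUE); d2 <- d1 + 1L
  cr1 <- sample(0:(lut$ncr - 1), n, TRUE)
  cr2 <- sample(0:(lut$ncr - 1), n, TRUE)
  tb <- sample(seq_len(tof$n_bins), n, TRUE) - 1L
  fr <- function(params, want = FALSE) {
    arr <- petalign:::geometry_cpp_arrays(bp, params)
    petalign:::forward_raw(arr, lut, d1, cr1, d2, cr2, tb, g, NULL, tof,
                           n_samples = 3L, seed = 7, want_grad = want)
  }
  base <- fr(pars, TRUE)
  h <- 1e-4
  for (d in 1:4) {
    for (which in c("translations", "rotations")) {
      col0 <- if (which == "translations") 0 else 3
      an <- sapply(1:3, function(ax)
        sum(base$grad[d1 == d - 1, col0 + ax]) +
          sum(base$grad[d2 == d - 1, 6 + col0 + ax]))
      fd <- sapply(1:3, function(ax) {
        pp <- pars; pm <- pars
        pp[[which]][d, ax] <- pp[[which]][d, ax] + h
        pm[[which]][d, ax] <- pm[[which]][d, ax] - h
        (sum(fr(pp)$mu) - sum(fr(pm)$mu)) / (2 * h)
      })
      rel <- abs(an - fd) / pmax(abs(fd), 1e-8)
      expect_lt(max(rel), 1e-3)
    }
  }
})
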
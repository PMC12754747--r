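test_that("phantom voxelization conserves mass and matches simple shapes", {
  # single point source much smaller than a voxel: one hot voxel
  ph <- phantom_points(rbind(c(0.25, 0.25, 0.25)), radii = 0.01)
  g <- voxelize_phantom(ph, spacing = 0.5, padding = 1.5)
  expect_equal(sum(g$values > 0), 1L)
  # total mass proportional to total activity
  ph2 <- phantom_points(rbind(c(0, 0, 0), c(3, 1, -1)), radii = 0.3,
                        activities = c(2, 1))
  g2 <- voxelize_phantom(ph2, spacing = 0.25)
  expect_equal(sum(g2$values) * prod(g2$spacing), 3, tolerance = 1e-6)
  # straight "tube" (collinear control points): cylinder volume analytic.
  # Unit activity and uniform density inside mean volume = 1 / max density
  # once interior voxels are fully covered (diameter >> voxel).
  cp <- cbind(seq(-6, 6, length.out = 5), 0, 0)
  tube <- phantom_tube(cp, diameter = 1)
  gt <- voxelize_phantom(tube, spacing = 0.2)
  expect_equal(sum(gt$values) * prod(gt$spacing), 1, tolerance = 1e-9)
  vol <- 1 / max(gt$values)
  expect_equal(vol, pi * 0.5^2 * 12, tolerance = 0.05 * pi * 0.5^2 * 12)
  # the nominal 250-micron tube keeps unit mass too
  thin <- voxelize_phantom(phantom_tube(cp, diameter = 0.25),
                           spacing = 0.125)
  expect_equal(sum(thin$values) * prod(thin$spacing), 1, tolerance = 1e-9)
  expect_error(voxelize_phantom(phantom_points(rbind(c(0, 0, 0))),
                                spacing = 0.5, padding = 0.5), "padding")
})

test_that("b-spline tube phantoms stay within the control polygon reach", {
  set.seed(70)
  cp <- matrix(rnorm(30, 0, 10), 10, 3)
  tube <- phantom_tube(cp, diameter = 0.25)
  pts <- sample_emissions(tube, 500)
  # convex-hull property of B-splines: curve inside the control polygon hull
  expect_true(all(pts[, 1] >= min(cp[, 1]) - 0.2))
  expect_true(all(pts[, 1] <= max(cp[, 1]) + 0.2))
  g <- voxelize_phantom(tube, spacing = 0.5)
  expect_gt(sum(g$values), 0)
})

test_that("the simulator is deterministic, respects n = 0, and is block-symmetric", {
  bp <- ring6()
  tof <- tof_model(250, range_mm = 60, exact = TRUE)
  ph <- phantom_points(rbind(c(0, 0, 0)), radii = 0.5)
  expect_equal(nrow(simulate_events(bp, ph, 0, tof = tof)), 0L)
  set.seed(71); a <- simulate_events(bp, ph, 5000, tof = tof)
  set.seed(71); b <- simulate_events(bp, ph, 5000, tof = tof)
  expect_identical(a, b)
  # centered source: per-block singles uniform within 4 sigma multinomial
  set.seed(72)
  ev <- simulate_events(bp, ph, 6e4, tof = tof)
  cnt <- as.numeric(table(factor(c(ev$d1, ev$d2), levels = 0:5)))
  expected <- sum(cnt) / 6
  sdm <- sqrt(sum(cnt) * (1 / 6) * (5 / 6))
  expect_true(all(abs(cnt - expected) < 4 * sdm))
})

test_that("TOF offsets of a centered source follow the kernel distribution", {
  bp <- ring6()
  tof <- tof_model(250, range_mm = 60, exact = TRUE)
  ph <- phantom_points(rbind(c(0, 0, 0)), radii = 0.25)
  set.seed(73)
  ev <- simulate_events(bp, ph, 6e4, tof = tof)
  tb <- petalign:::tof_bin_of(tof, ev$s)
  emp <- table(factor(tb, levels = seq_len(tof$n_bins)))
  edges <- c(tof$bin_centers - tof$bin_width / 2,
             max(tof$bin_centers) + tof$bin_width / 2)
  pr <- diff(pnorm(edges / tof$sigma))
  pr <- pr / sum(pr)
  keep <- pr * length(tb) >= 5
  x2 <- sum((emp[keep] - length(tb) * pr[keep])^2 / (length(tb) * pr[keep]))
  expect_gt(pchisq(x2, sum(keep) - 1, lower.tail = FALSE), 0.001)
})

test_that("histogramming is an exact multiset count that round-trips", {
  b <- data.frame(d1 = c(0L, 0L, 0L, 1L), cr1 = c(2L, 2L, 2L, 0L),
                  d2 = c(3L, 3L, 3L, 2L), cr2 = c(1L, 1L, 1L, 0L),
                  t = c(4L, 4L, 4L, 2L))
  h <- histogram_events(b, ndet = 4L, ncr = 8L)
  expect_equal(sum(h$n), 4L)
  expect_equal(h$n[h$d1 == 0L], 3L)
  back <- petalign:::expand_histogram(h)
  key <- function(d) do.call(paste, d[c("d1", "cr1", "d2", "cr2", "t")])
  expect_equal(sort(key(back)), sort(key(b)))
  expect_equal(nrow(histogram_events(b[0, ])), 0L)
})

test_that("fan acceptance matches the nine-partner layout and is symmetric", {
  bp <- cylindrical_blueprint(8, 3, 75, c(48, 10, 48))
  acc <- fan_acceptance(bp, n_opposing = 3L, include_axial_neighbors = TRUE)
  # a middle-ring block sees 3 opposed blocks in 3 rings = 9 partners
  mid <- 8L  # first block of ring 2 (0-based index 8)
  expect_equal(sum(acc$matrix[mid + 1L, ]), 9L)
  # an edge-ring block sees 6
  expect_equal(sum(acc$matrix[1L, ]), 6L)
  expect_true(isSymmetric(acc$matrix))
  # single ring, single opposing block
  bp1 <- cylindrical_blueprint(8, 1, 40, c(24, 10, 24))
  acc1 <- fan_acceptance(bp1, n_opposing = 1L, include_axial_neighbors = FALSE)
  expect_equal(sum(acc1$matrix[1, ]), 1L)
  expect_true(acc1$matrix[1, 5])   # the diametrically opposed block
})

test_that("fan-sum efficiencies count coincidences and recover thinning ratios", {
  # two crystals with 7 mutual events
  b <- data.frame(d1 = rep(0L, 7), cr1 = rep(3L, 7), d2 = rep(3L, 7),
                  cr2 = rep(5L, 7), t = rep(1L, 7))
  h <- histogram_events(b, ndet = 6L, ncr = 8L)
  bp <- ring6()
  acc <- fan_acceptance(bp, n_opposing = 3L, include_axial_neighbors = FALSE)
  eff <- fan_sum_efficiencies(h, acc)
  expect_equal(eff[1, 4], 7)
  expect_equal(eff[4, 6], 7)
  expect_equal(sum(eff), 14)
  expect_error(fan_sum_efficiencies(h[0], acc), "empty")
  # known 2:1 efficiency ratio on otherwise symmetric crystals: halve one
  # crystal's efficiency and compare its fan sum with its transaxial mirror
  # (same |x| offset, equal rate by symmetry of the centered source)
  lut <- crystal_lut(bp$block_dims, c(6, 10, 6))   # 4 x 1 x 4 voxels
  tof <- tof_model(250, range_mm = 60, exact = TRUE)
  E <- efficiency_table(bp$ndet, lut$ncr, 1)
  cr_lo <- 1L + 4L * 2L    # (ix=1, iz=2)
  cr_hi <- 2L + 4L * 2L    # transaxial mirror (ix=2, iz=2)
  E[1, cr_lo + 1L] <- 0.5
  set.seed(74)
  ev <- simulate_events(bp, phantom_points(rbind(c(0, 0, 0)), radii = 0.5),
                        1.2e5, tof = tof, efficiencies = E, lut = lut)
  h2 <- histogram_events(bin_events(ev, lut, tof), ndet = bp$ndet,
                         ncr = lut$ncr)
  f <- fan_sum_efficiencies(h2, acc)
  n_lo <- f[1, cr_lo + 1L]
  n_hi <- f[1, cr_hi + 1L]
  ratio <- n_hi / n_lo
  se_rel <- sqrt(1 / n_lo + 1 / n_hi)
  expect_lt(abs(ratio - 2) / 2, 4 * se_rel)
})

test_that("halving all efficiencies quarters the coincidence acceptance rate", {
  bp <- ring6()
  lut <- crystal_lut(bp$block_dims, c(6, 10, 6))
  ph <- phantom_points(rbind(c(0, 0, 0)), radii = 0.5)
  E1 <- efficiency_table(bp$ndet, lut$ncr, 0.8)
  E2 <- efficiency_table(bp$ndet, lut$ncr, 0.4)
  # count candidates needed for a fixed accepted number via the chunk guard:
  # instead, simulate a fixed candidate stream through the low-level tracer
  set.seed(75)
  n <- 2e5
  em <- sample_emissions(ph, n)
  cz <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  dir <- cbind(sqrt(1 - cz^2) * cos(phi), sqrt(1 - cz^2) * sin(phi), cz)
  tr <- petalign:::cpp_trace_rays(bp$positions,
                                  cbind(bp$axes_x, bp$axes_y, bp$axes_z),
                                  bp$block_dims / 2, em, dir,
                                  runif(n), runif(n), 30)
  ok <- which(tr$ok)
  cr1 <- petalign:::crystal_index_from_local(lut, tr$l1[ok, ])
  cr2 <- petalign:::crystal_index_from_local(lut, tr$l2[ok, ])
  p1 <- E1[cbind(tr$d1[ok] + 1L, cr1 + 1L)] * E1[cbind(tr$d2[ok] + 1L, cr2 + 1L)]
  p2 <- E2[cbind(tr$d1[ok] + 1L, cr1 + 1L)] * E2[cbind(tr$d2[ok] + 1L, cr2 + 1L)]
  k1 <- sum(runif(length(ok)) < p1)
  k2 <- sum(runif(length(ok)) < p2)
  ratio <- k2 / k1
  se_rel <- sqrt(1 / k1 + 1 / k2)
  expect_lt(abs(ratio - 0.25) / 0.25, 4 * se_rel)
})

test_that("simulated bin counts are proportional to the forward model (central oracle)", {
  bp <- ring6()
  lut <- crystal_lut(bp$block_dims, c(3, 5, 3))   # 8x2x8 crystal voxels
  tof <- tof_model(250, range_mm = 60, exact = TRUE)
  ph <- phantom_points(rbind(c(0, 0, 0)), radii = 1.5)
  set.seed(76)
  ev <- simulate_events(bp, ph, 7e4, tof = tof)
  F <- voxelize_phantom(ph, spacing = 0.25)
  h <- histogram_events(bin_events(ev, lut, tof), ndet = bp$ndet,
                        ncr = lut$ncr)
  acc <- fan_acceptance(bp, n_opposing = 1L, max_ring_diff = 0L)
  h <- h[accepts(acc, h$d1, h$d2)]
  # a seeded random subset of bins keeps the oracle unbiased while holding
  # the Monte-Carlo rate evaluation to a few seconds
  set.seed(78)
  h <- h[sample(nrow(h), min(700L, nrow(h)))]
  mu <- expected_count(h$d1, h$cr1, h$d2, h$cr2, h$t, geometry = bp,
                       lut = lut, activity = F, tof = tof,
                       n_samples = 2500L, seed = 77)
  sc <- sum(h$n) / sum(mu)
  keep <- sc * mu >= 5
  x2 <- sum((h$n[keep] - sc * mu[keep])^2 / (sc * mu[keep]))
  df <- sum(keep) - 1
  expect_gt(pchisq(x2, df, lower.tail = FALSE), 0.001)
})
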
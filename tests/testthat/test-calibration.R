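# Fixture shared across the calibration unit tests: a 4-block toy with a
# smooth activity field, so model rates are well conditioned.
cal_fixture <- local({
  env <- new.env()
  function() {
    if (!is.null(env$fix)) return(env$fix)
    set.seed(80)
    bp <- toy_scanner()
    lut <- crystal_lut(bp$block_dims, c(4, 5, 4))
    tof <- tof_model(250, range_mm = 50, exact = TRUE)
    ph <- toy_points(n = 3, radius = 8, r_src = 0.8, seed = 81)
    gt_pars <- perturb_alignment(bp$ndet, 0.5, 0.5)
    gt <- apply_alignment(bp, gt_pars)
    ev <- simulate_events(gt, ph, 8e4, tof = tof)
    F <- voxelize_phantom(ph, spacing = 0.4)
    h <- histogram_events(bin_events(ev, lut, tof), ndet = bp$ndet,
                          ncr = lut$ncr)
    acc <- fan_acceptance(bp, 1L, max_ring_diff = 0L)
    h <- h[accepts(acc, h$d1, h$d2)]
    env$fix <- list(bp = bp, lut = lut, tof = tof, ph = ph, F = F, h = h,
                    acc = acc, gt = gt, gt_pars = gt_pars)
    env$fix
  }
})

test_that("batches cover the support exactly when the budget allows and are unbiased", {
  f <- cal_fixture()
  # full support, no zero bins
  b <- sample_batch(f$h, nrow(f$h) + 10, 0, f$acc, f$lut$ncr)
  expect_equal(nrow(b$support), nrow(f$h))
  expect_equal(b$w_support, 1)
  expect_null(b$zeros)
  # determinism under seed
  set.seed(5); b1 <- sample_batch(f$h, 500, 0.5, f$acc, f$lut$ncr)
  set.seed(5); b2 <- sample_batch(f$h, 500, 0.5, f$acc, f$lut$ncr)
  expect_identical(b1, b2)
  # importance weights: expected weighted support count reproduces the total
  set.seed(6)
  tot <- replicate(300, {
    b <- sample_batch(f$h, 400, 0.5, f$acc, f$lut$ncr)
    b$w_support * nrow(b$support)
  })
  expect_lt(abs(mean(tot) - nrow(f$h)) / nrow(f$h), 0.01)
  expect_error(sample_batch(f$h[0], 100, 0.5, f$acc, f$lut$ncr), "empty")
})

test_that("the Poisson score is stationary when counts equal model rates", {
  f <- cal_fixture()
  set.seed(7)
  b <- sample_batch(f$h, 2000, 0, f$acc, f$lut$ncr)
  # replace the observed counts by the model rates themselves: the profiled
  # scale is then exactly 1 and d(loss)/d(log scale) = 0
  mu <- expected_count(b$support$d1, b$support$cr1, b$support$d2,
                       b$support$cr2, b$support$t, geometry = f$bp,
                       lut = f$lut, activity = f$F, tof = f$tof,
                       n_samples = 4L, seed = 9)
  bb <- b
  bb$support$n <- mu   # bins with rate 0 get count 0 and contribute nothing
  ob <- nll_objective(zero_alignment(4), bb, f$bp, f$lut, f$F, tof = f$tof,
                      n_crystal_samples = 4L, seed = 9, rate_floor = 1e-12)
  expect_equal(ob$scale, 1, tolerance = 1e-9)
  # score in log-scale: sum(mu) - sum(C) = 0 at the profiled scale
  eps <- 1e-6
  up <- nll_objective(zero_alignment(4), bb, f$bp, f$lut, f$F, tof = f$tof,
                      n_crystal_samples = 4L, seed = 9,
                      scale = 1 + eps, rate_floor = 1e-12)$value
  dn <- nll_objective(zero_alignment(4), bb, f$bp, f$lut, f$F, tof = f$tof,
                      n_crystal_samples = 4L, seed = 9,
                      scale = 1 - eps, rate_floor = 1e-12)$value
  expect_lt(abs(up - dn) / (2 * eps) / abs(up), 1e-6)
})

test_that("adding a constant to all counts shifts the loss by -k * sum(w log L)", {
  f <- cal_fixture()
  set.seed(8)
  b <- sample_batch(f$h, 1500, 0.4, f$acc, f$lut$ncr)
  pars <- perturb_alignment(4, 0.2, 0.2)
  sc <- 2.5
  v0 <- nll_objective(pars, b, f$bp, f$lut, f$F, tof = f$tof,
                      n_crystal_samples = 3L, seed = 11, scale = sc,
                      rate_floor = 1e-12)$value
  k <- 3
  b2 <- b
  b2$support$n <- b2$support$n + k
  v1 <- nll_objective(pars, b2, f$bp, f$lut, f$F, tof = f$tof,
                      n_crystal_samples = 3L, seed = 11, scale = sc,
                      rate_floor = 1e-12)$value
  mu <- expected_count(b$support$d1, b$support$cr1, b$support$d2,
                       b$support$cr2, b$support$t, geometry = f$bp,
                       lut = f$lut, activity = f$F, tof = f$tof,
                       n_samples = 3L, seed = 11,
                       scale = sc)
  pars_arr <- petalign:::geometry_cpp_arrays(f$bp, pars)
  mu <- petalign:::forward_raw(pars_arr, f$lut, b$support$d1, b$support$cr1,
                               b$support$d2, b$support$cr2,
                               b$support$t - 1L, f$F, NULL, f$tof, 3L, 11,
                               FALSE)$mu * sc
  expected_shift <- -k * b$w_support * sum(log(mu + 1e-12))
  expect_equal(v1 - v0, expected_shift, tolerance = 1e-8)
})

test_that("objective gradients match finite differences on a 4-block toy", {
  f <- cal_fixture()
  set.seed(9)
  b <- sample_batch(f$h, 1200, 0.5, f$acc, f$lut$ncr)
  pars <- alignment_params(matrix(rnorm(12, 0, 0.3), 4, 3),
                           matrix(rnorm(12, 0, 0.3), 4, 3))
  sc <- 1.7
  ob <- nll_objective(pars, b, f$bp, f$lut, f$F, tof = f$tof,
                      n_crystal_samples = 3L, seed = 13, scale = sc,
                      want_grad = TRUE, rate_floor = 0.02)
  h0 <- 1e-4
  worst <- 0
  for (d in 1:4) for (which in c("translations", "rotations")) {
    an <- ob$gradient[[which]][d, ]
    fd <- sapply(1:3, function(ax) {
      pp <- pars; pm <- pars
      pp[[which]][d, ax] <- pp[[which]][d, ax] + h0
      pm[[which]][d, ax] <- pm[[which]][d, ax] - h0
      (nll_objective(pp, b, f$bp, f$lut, f$F, tof = f$tof,
                     n_crystal_samples = 3L, seed = 13, scale = sc,
                     rate_floor = 0.02)$value -
       nll_objective(pm, b, f$bp, f$lut, f$F, tof = f$tof,
                     n_crystal_samples = 3L, seed = 13, scale = sc,
                     rate_floor = 0.02)$value) / (2 * h0)
    })
    worst <- max(worst, max(abs(an - fd) / pmax(abs(fd), 1e-4 * max(abs(fd)))))
  }
  expect_lt(worst, 1e-3)
})

test_that("tied parameter groups receive summed gradients", {
  f <- cal_fixture()
  set.seed(10)
  b <- sample_batch(f$h, 800, 0.5, f$acc, f$lut$ncr)
  share <- c(1L, 1L, 2L, 2L)
  pars_g <- alignment_params(matrix(0.1, 2, 3), matrix(0.05, 2, 3),
                             share_map = share)
  ob_g <- nll_objective(pars_g, b, f$bp, f$lut, f$F, tof = f$tof,
                        n_crystal_samples = 2L, seed = 15, scale = 1,
                        want_grad = TRUE)
  pars_full <- petalign:::expand_params(pars_g, 4L)
  ob_f <- nll_objective(pars_full, b, f$bp, f$lut, f$F, tof = f$tof,
                        n_crystal_samples = 2L, seed = 15, scale = 1,
                        want_grad = TRUE)
  expect_equal(ob_g$gradient$translations[1, ],
               ob_f$gradient$translations[1, ] +
                 ob_f$gradient$translations[2, ], tolerance = 1e-9)
  expect_equal(ob_g$gradient$rotations[2, ],
               ob_f$gradient$rotations[3, ] + ob_f$gradient$rotations[4, ],
               tolerance = 1e-9)
})

test_that("calibration is reproducible and reduces the loss on recovery data", {
  f <- cal_fixture()
  ctrl <- align_control(iterations = 30, batch_size = 4000,
                        n_crystal_samples = 4L, lr_decay = "cosine",
                        average_last = 10L, seed = 33)
  fit1 <- calibrate_alignment(f$h, f$bp, f$lut, f$F, tof = f$tof,
                              acceptance = f$acc, control = ctrl)
  fit2 <- calibrate_alignment(f$h, f$bp, f$lut, f$F, tof = f$tof,
                              acceptance = f$acc, control = ctrl)
  expect_identical(coef(fit1), coef(fit2))
  expect_identical(fit1$loss_trace, fit2$loss_trace)
  # the smoothed loss goes down over the run
  expect_lt(mean(tail(fit1$loss_trace, 5)), mean(head(fit1$loss_trace, 5)))
  # methods exist and run
  expect_output(print(fit1), "alignment")
  expect_equal(dim(coef(fit1)), c(4L, 6L))
  s <- summary(fit1, reference = f$gt)
  expect_s3_class(s, "summary.pet_alignment")
})
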
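# Maximum-likelihood alignment calibration.
#
# The estimator minimizes the Poisson negative log-likelihood
#     sum_bins [ L(bin) - C(bin) * log L(bin) ]
# over the per-block translations and rotations, where L is the TOF-weighted
# line-integral forward model and C the measured coincidence histogram. The
# sum runs over ALL valid bins (occupied and empty); each Adam step uses an
# unbiased two-part batch estimate: a uniform sample of the occupied
# (support) bins for the data term, and a uniform sample of all
# acceptance-compatible crystal pairs — TOF-marginalized, which is the exact
# sum of the per-bin rates over the TOF axis — for the expectation term.
# The global rate calibration `scale` is profiled analytically at each
# evaluation (scale* = weighted counts / weighted model mass), which removes
# the arbitrary normalization of the activity image and of fan-sum raw-count
# efficiencies.

#' Optimizer and batching settings for alignment calibration
#'
#' Defaults follow the reference protocol: Adam with learning rates 1 mm for
#' translations and 0.1 degrees for rotations, 200 iterations, five point
#' pairs sampled inside the crystal voxels per bin, and a batch of five
#' million bins. `lr_decay` and `average_last` are stochastic-approximation
#' refinements for small-batch runs: cosine decay of both learning rates and
#' Polyak averaging of the final iterates.
#'
#' @param iterations Adam steps.
#' @param batch_size bins per step (support + zero parts together).
#' @param lr_rotation,lr_translation learning rates (degrees, mm).
#' @param n_crystal_samples point pairs per bin and evaluation.
#' @param zero_bin_fraction fraction of the batch spent on uniformly drawn
#'   acceptance-compatible bins carrying count zero; 0 reproduces a
#'   support-only objective.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param lr_decay `"none"` or `"cosine"`.
#' @param average_last average the parameters of the last k iterations
#'   (0 = return the final iterate).
#' @param rate_floor additive floor (in expected-count units) inside the
#'   log of the data term; keeps the objective finite and bounds the
#'   per-bin gradient coefficient when a counted bin's Monte-Carlo rate
#'   estimate underflows.
#' @param mass_mix fraction of the expectation-term batch proposed from the
#'   measured crystal-pair distribution (mixture importance sampling); 0
#'   reproduces plain uniform pair sampling.
#' @param seed master seed for batching and crystal sampling.
#' @export
align_control <- function(iterations = 200L, batch_size = 5e6,
                          lr_rotation = 0.1, lr_translation = 1,
                          n_crystal_samples = 5L, zero_bin_fraction = 0.5,
                          beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                          lr_decay = c("none", "cosine"), average_last = 0L,
                          rate_floor = 0.02, mass_mix = 0.5, seed = NULL) {
  lr_decay <- match.arg(lr_decay)
  stopifnot(iterations >= 1, batch_size >= 1, lr_rotation > 0,
            lr_translation > 0, n_crystal_samples >= 1,
            zero_bin_fraction >= 0, zero_bin_fraction < 1)
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 lr_rotation = lr_rotation, lr_translation = lr_translation,
                 n_crystal_samples = as.integer(n_crystal_samples),
                 zero_bin_fraction = zero_bin_fraction,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 lr_decay = lr_decay, average_last = as.integer(average_last),
                 rate_floor = rate_floor, mass_mix = mass_mix, seed = seed),
            class = "align_control")
}

#' Sample an importance-weighted bin batch
#'
#' Part A: `n_support` occupied bins drawn uniformly from the histogram
#' support (all of them if the budget allows), weight `N_support / n_support`
#' each. Part B: uniformly drawn acceptance-compatible crystal pairs with
#' count 0, weighted `N_pairs / n_zero`, evaluated TOF-marginally. Together
#' they give an unbiased estimate of the full-sum objective.
#'
#' @param histogram `coincidence_histogram`.
#' @param batch_size total bins in the batch.
#' @param zero_fraction share of the batch allocated to part B.
#' @param acceptance [fan_acceptance()] describing the valid detector pairs.
#' @param ncr crystals per block.
#' @param pair_counts collapsed pair-count table (see the source of
#'   `calibrate_alignment`); enables the mixture proposal for part B.
#' @param mix mixture weight on the measured-pair proposal.
#' @return list with `support` (data.frame + weight), `zeros`
#'   (data.frame + weight), and the population totals.
#' @export
sample_batch <- function(histogram, batch_size, zero_fraction = 0.5,
                         acceptance, ncr, pair_counts = NULL, mix = 0.5) {
  if (nrow(histogram) == 0) stop("empty histogram")
  n_zero <- as.integer(round(batch_size * zero_fraction))
  n_sup <- as.integer(batch_size) - n_zero
  nsup_tot <- nrow(histogram)
  if (n_sup >= nsup_tot) {
    sup <- as.data.frame(histogram)
    w_sup <- 1
  } else {
    idx <- sample.int(nsup_tot, n_sup)
    sup <- as.data.frame(histogram[idx])
    w_sup <- nsup_tot / n_sup
  }
  zeros <- NULL
  pairs <- accepted_pairs(acceptance)
  n_pairs_tot <- nrow(pairs) * as.numeric(ncr)^2
  if (n_zero > 0) {
    if (is.null(pair_counts) || mix <= 0) {
      pi <- sample.int(nrow(pairs), n_zero, replace = TRUE)
      zeros <- data.frame(d1 = pairs[pi, 1],
                          cr1 = sample.int(ncr, n_zero, replace = TRUE) - 1L,
                          d2 = pairs[pi, 2],
                          cr2 = sample.int(ncr, n_zero, replace = TRUE) - 1L,
                          w = rep(n_pairs_tot / n_zero, n_zero))
    } else {
      # mixture importance sampling for the expectation term: with
      # probability `mix` propose a crystal pair from the measured pair
      # distribution (where the model mass sits once the fit is close),
      # otherwise uniformly; the mixture density is exactly computable, so
      # the weighted sum stays an unbiased estimate of the total model mass
      # while its variance drops by orders of magnitude for sparse phantoms.
      nev <- attr(pair_counts, "n_events")
      from_sup <- runif(n_zero) < mix
      k1 <- sum(from_sup)
      zd <- data.table::data.table(
        d1 = integer(n_zero), cr1 = integer(n_zero),
        d2 = integer(n_zero), cr2 = integer(n_zero))
      if (k1 > 0) {
        j <- sample.int(nrow(pair_counts), k1, replace = TRUE,
                        prob = pair_counts$npair)
        zd[from_sup, c("d1", "cr1", "d2", "cr2") :=
             pair_counts[j, c("d1", "cr1", "d2", "cr2"), with = FALSE]]
      }
      if (k1 < n_zero) {
        pi <- sample.int(nrow(pairs), n_zero - k1, replace = TRUE)
        zd[!from_sup, c("d1", "cr1", "d2", "cr2") := list(
          pairs[pi, 1], sample.int(ncr, n_zero - k1, replace = TRUE) - 1L,
          pairs[pi, 2], sample.int(ncr, n_zero - k1, replace = TRUE) - 1L)]
      }
      # mixture density per draw
      m <- pair_counts[zd, on = c("d1", "cr1", "d2", "cr2")]
      np <- m$npair
      np[is.na(np)] <- 0
      q <- mix * np / nev + (1 - mix) / n_pairs_tot
      zeros <- as.data.frame(zd)
      zeros$w <- 1 / (q * n_zero)
    }
  }
  list(support = sup, w_support = w_sup, zeros = zeros,
       n_support_total = nsup_tot, n_pairs_total = n_pairs_tot)
}

# collapsed pair-count table used by the mixture mass sampler
pair_count_table <- function(histogram) {
  pc <- data.table::as.data.table(histogram)[, list(npair = sum(n)),
                                             by = c("d1", "cr1", "d2", "cr2")]
  data.table::setkeyv(pc, c("d1", "cr1", "d2", "cr2"))
  data.table::setattr(pc, "n_events", sum(pc$npair))
  pc
}

#' Poisson negative log-likelihood of an alignment (batched)
#'
#' Evaluates the weighted batch objective
#' `sum_B w L  -  sum_A w C log L` at the given alignment parameters, with
#' the global scale profiled analytically unless supplied. Optionally returns
#' the analytic gradient with respect to all per-block (or per-group)
#' translations and rotations.
#'
#' @param params `pet_alignment_params`.
#' @param batch a batch from [sample_batch()].
#' @param blueprint blueprint geometry.
#' @param lut crystal lookup table.
#' @param activity,attenuation voxel grids (attenuation optional).
#' @param efficiencies Ndet x Ncr matrix or `NULL` for uniform.
#' @param tof [tof_model()] or `NULL` (non-TOF objective).
#' @param n_crystal_samples point pairs per bin.
#' @param seed seed for the in-crystal sampling.
#' @param scale fixed global scale, or `NULL` to profile.
#' @param want_grad also compute the gradient.
#' @param rate_floor clamp for rates inside the log.
#' @return list(value, scale, gradient?, n_floor) where gradient is a list
#'   with Ndet x 3 (or group x 3) `translations` and `rotations`.
#' @export
nll_objective <- function(params, batch, blueprint, lut, activity,
                          attenuation = NULL, efficiencies = NULL, tof = NULL,
                          n_crystal_samples = 5L, seed = 1L, scale = NULL,
                          want_grad = FALSE, rate_floor = 0.02) {
  nd <- blueprint$ndet
  arr <- geometry_cpp_arrays(blueprint, params)
  sup <- batch$support
  nz <- if (is.null(batch$zeros)) 0L else nrow(batch$zeros)
  d1 <- c(sup$d1, if (nz) batch$zeros$d1)
  cr1 <- c(sup$cr1, if (nz) batch$zeros$cr1)
  d2 <- c(sup$d2, if (nz) batch$zeros$d2)
  cr2 <- c(sup$cr2, if (nz) batch$zeros$cr2)
  tbin <- if (is.null(tof)) rep(0L, length(d1))
          else c(sup$t - 1L, if (nz) rep(-1L, nz))
  res <- forward_raw(arr, lut, d1, cr1, d2, cr2, tbin, activity, attenuation,
                     tof, n_crystal_samples, seed, want_grad)
  effv <- if (is.null(efficiencies)) rep(1, length(d1))
          else efficiencies[cbind(d1 + 1L, cr1 + 1L)] *
               efficiencies[cbind(d2 + 1L, cr2 + 1L)]
  mu <- res$mu * effv
  ns <- nrow(sup)
  i_sup <- seq_len(ns)
  C <- as.numeric(sup$n)
  # expectation mass: part B if present, else the support part itself
  if (nz) {
    mass_idx <- setdiff(seq_along(mu), i_sup)
    mass_w <- batch$zeros$w
    mass <- sum(mass_w * mu[mass_idx])
  } else {
    mass_idx <- i_sup
    mass_w <- rep(batch$w_support, ns)
    mass <- batch$w_support * sum(mu[i_sup])
  }
  counts_w <- batch$w_support * sum(C)
  if (is.null(scale)) {
    if (mass <= 0) stop("model mass is zero: no activity seen by the batch")
    scale <- counts_w / mass
  }
  # additive floor keeps the log finite and the objective smooth where a
  # counted bin's model rate underflows early in optimization
  mu_s <- scale * mu[i_sup] + rate_floor
  n_floor <- sum(scale * mu[i_sup] < rate_floor & C > 0)
  value <- scale * mass - batch$w_support * sum(C * log(mu_s))
  if (!is.finite(value)) {
    bad <- which(!is.finite(log(mu_s)))
    stop("non-finite loss; offending bins: ", paste(head(bad), collapse = ","))
  }
  out <- list(value = value, scale = scale, n_floor = n_floor)
  if (want_grad) {
    G <- res$grad * effv   # column recycling over the 12 param columns
    coef <- numeric(length(mu))
    coef[mass_idx] <- coef[mass_idx] + scale * mass_w
    coef[i_sup] <- coef[i_sup] - batch$w_support * C * scale / mu_s
    Gc <- G * coef
    gT <- rowsum_pad(Gc[, 1:3, drop = FALSE], d1, nd) +
      rowsum_pad(Gc[, 7:9, drop = FALSE], d2, nd)
    gR <- rowsum_pad(Gc[, 4:6, drop = FALSE], d1, nd) +
      rowsum_pad(Gc[, 10:12, drop = FALSE], d2, nd)
    if (!is.null(params$share_map)) {
      gT <- rowsum_pad(gT, params$share_map - 1L, max(params$share_map))
      gR <- rowsum_pad(gR, params$share_map - 1L, max(params$share_map))
    }
    out$gradient <- list(translations = gT, rotations = gR)
  }
  out
}

# rowsum over 0-based groups with fixed output size
rowsum_pad <- function(x, g, n) {
  out <- matrix(0, n, ncol(x))
  a <- rowsum(x, g)
  out[as.integer(rownames(a)) + 1L, ] <- a
  out
}

#' Calibrate detector alignment by maximum likelihood
#'
#' Runs Adam on the batched Poisson NLL with separate learning rates for the
#' translation and rotation blocks, a fresh bin batch and fresh in-crystal
#' sampling every iteration, and (optionally) tied parameter groups via
#' `share_map`. Fully reproducible under `control$seed`.
#'
#' @param histogram measured `coincidence_histogram`.
#' @param blueprint designed geometry used as parameterization origin.
#' @param lut crystal-voxel lookup table matching the histogram binning.
#' @param activity known tracer distribution (`voxel_grid`).
#' @param attenuation optional attenuation map.
#' @param efficiencies per-crystal efficiencies (any overall normalization;
#'   `NULL` for uniform).
#' @param tof [tof_model()] or `NULL` to calibrate without TOF weighting.
#' @param acceptance [fan_acceptance()] defining valid detector pairs;
#'   default accepts the three most-opposed blocks across all ring
#'   combinations.
#' @param control an [align_control()].
#' @param init initial `pet_alignment_params` (default: zero, the blueprint).
#' @param share_map optional tied-parameter group map (length Ndet).
#' @return An object of class `pet_alignment`; see [coef.pet_alignment()],
#'   [summary.pet_alignment()], [plot.pet_alignment()].
#' @export
calibrate_alignment <- function(histogram, blueprint, lut, activity,
                                attenuation = NULL, efficiencies = NULL,
                                tof = NULL, acceptance = NULL,
                                control = align_control(), init = NULL,
                                share_map = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (nrow(histogram) == 0) stop("empty histogram")
  if (!is.null(control$seed)) set.seed(control$seed)
  if (is.null(acceptance))
    acceptance <- fan_acceptance(blueprint, n_opposing = 3L,
                                 max_ring_diff = Inf)
  nd <- blueprint$ndet
  ngrp <- if (is.null(share_map)) nd else max(share_map)
  if (is.null(init)) {
    Tm <- matrix(0, ngrp, 3)
    Rm <- matrix(0, ngrp, 3)
  } else {
    Tm <- init$translations
    Rm <- init$rotations
    if (is.null(share_map)) share_map <- init$share_map
    stopifnot(nrow(Tm) == ngrp)
  }
  mT <- vT <- matrix(0, ngrp, 3)
  mR <- vR <- matrix(0, ngrp, 3)
  it <- control$iterations
  loss <- numeric(it)
  scales <- numeric(it)
  grad_norms <- numeric(it)
  avg_k <- min(control$average_last, it)
  accT <- matrix(0, ngrp, 3)
  accR <- matrix(0, ngrp, 3)
  activity <- with_bricks(activity)
  pc <- if (control$zero_bin_fraction > 0) pair_count_table(histogram)
        else NULL
  for (i in seq_len(it)) {
    pars <- alignment_params(Tm, Rm, share_map)
    batch <- sample_batch(histogram, control$batch_size,
                          control$zero_bin_fraction, acceptance, lut$ncr,
                          pair_counts = pc, mix = control$mass_mix)
    seed_i <- sample.int(.Machine$integer.max, 1L)
    ob <- nll_objective(pars, batch, blueprint, lut, activity, attenuation,
                        efficiencies, tof, control$n_crystal_samples,
                        seed = seed_i, scale = NULL, want_grad = TRUE,
                        rate_floor = control$rate_floor)
    loss[i] <- ob$value
    scales[i] <- ob$scale
    gT <- ob$gradient$translations
    gR <- ob$gradient$rotations
    grad_norms[i] <- sqrt(sum(gT^2) + sum(gR^2))
    fac <- switch(control$lr_decay,
                  none = 1,
                  cosine = 0.5 * (1 + cos(pi * (i - 1) / it)))
    lrT <- control$lr_translation * fac
    lrR <- control$lr_rotation * fac
    mT <- control$beta1 * mT + (1 - control$beta1) * gT
    vT <- control$beta2 * vT + (1 - control$beta2) * gT^2
    mR <- control$beta1 * mR + (1 - control$beta1) * gR
    vR <- control$beta2 * vR + (1 - control$beta2) * gR^2
    bc1 <- 1 - control$beta1^i
    bc2 <- 1 - control$beta2^i
    Tm <- Tm - lrT * (mT / bc1) / (sqrt(vT / bc2) + control$epsilon)
    Rm <- Rm - lrR * (mR / bc1) / (sqrt(vR / bc2) + control$epsilon)
    if (!all(is.finite(Tm)) || !all(is.finite(Rm)))
      stop("optimization diverged at iteration ", i,
           "; loss trace: ", paste(signif(tail(loss[seq_len(i)], 5), 5),
                                   collapse = ", "))
    if (avg_k > 0 && i > it - avg_k) {
      accT <- accT + Tm
      accR <- accR + Rm
    }
  }
  if (avg_k > 0) {
    Tm <- accT / avg_k
    Rm <- accR / avg_k
  }
  pars <- alignment_params(Tm, Rm, share_map)
  fit <- structure(
    list(params = pars,
         translations = expand_params(pars, nd)$translations,
         rotations = expand_params(pars, nd)$rotations,
         loss_trace = loss, scale_trace = scales, scale = scales[it],
         grad_norms = grad_norms, control = control,
         blueprint = blueprint, lut = lut, tof = tof,
         acceptance = acceptance, init = init,
         geometry = apply_alignment(blueprint, pars),
         n_events = sum(histogram$n), n_bins = nrow(histogram),
         elapsed = proc.time()[["elapsed"]] - t0),
    class = "pet_alignment")
  fit
}
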
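# TOF list-mode OSEM reconstruction and sensitivity maps, built on the same
# projector as the calibration forward model (single source of truth for the
# system model).

#' Reconstruction settings
#'
#' @param n_subsets ordered subsets (events split by transaxial LOR azimuth).
#' @param n_iterations full OSEM iterations (each visits every subset once).
#' @param voxel_size reconstruction voxel size (mm).
#' @param lors_per_event sample lines drawn inside the crystal voxels per
#'   event during projection (mitigates discretization artifacts).
#' @param seed seed for the in-crystal sampling.
#' @export
recon_control <- function(n_subsets = 10L, n_iterations = 10L,
                          voxel_size = 0.2, lors_per_event = 10L,
                          seed = 1L) {
  stopifnot(n_subsets >= 1, n_iterations >= 1, voxel_size > 0,
            lors_per_event >= 1)
  structure(list(n_subsets = as.integer(n_subsets),
                 n_iterations = as.integer(n_iterations),
                 voxel_size = voxel_size,
                 lors_per_event = as.integer(lors_per_event),
                 seed = as.integer(seed)),
            class = "recon_control")
}

#' Split events into angularly interleaved subsets
#'
#' Each event's transaxial LOR azimuth (angle of the crystal-difference
#' vector projected on the transaxial plane, folded to `[0, pi)`) is binned
#' into fine sectors, and sectors are dealt out modulo `n_subsets`, giving
#' each subset an equal angular distribution. The subsets partition the
#' input exactly.
#'
#' @param binned crystal-binned events (data.frame with d1, cr1, d2, cr2).
#' @param geometry aligned `pet_blueprint`.
#' @param lut crystal lookup table.
#' @param n_subsets number of subsets.
#' @return List of row-index vectors into `binned`.
#' @export
subset_split <- function(binned, geometry, lut, n_subsets) {
  if (n_subsets == 1L) return(list(seq_len(nrow(binned))))
  p1 <- crystal_center_global(geometry, binned$d1, binned$cr1, lut)
  p2 <- crystal_center_global(geometry, binned$d2, binned$cr2, lut)
  az <- atan2(p2[, 2] - p1[, 2], p2[, 1] - p1[, 1]) %% pi
  # deal events in azimuth order round-robin: subsets are balanced to +-1
  # and each spans the full angular range
  ord <- order(az)
  sub <- integer(nrow(binned))
  sub[ord] <- (seq_along(ord) - 1L) %% n_subsets
  unname(split(seq_len(nrow(binned)), sub))
}

#' Sensitivity map
#'
#' Voxelwise sum of backprojected `E1 * E2 * attenuation` weights over the
#' acceptance-compatible crystal pairs (TOF-marginalized). This is the OSEM
#' normalization denominator. For large crystal counts a uniform random
#' subset of crystal pairs per block pair is used, scaled to the full sum.
#'
#' @param geometry aligned `pet_blueprint`.
#' @param lut crystal lookup table.
#' @param efficiencies Ndet x Ncr matrix or NULL (uniform).
#' @param attenuation optional attenuation map.
#' @param grid_spec list(origin, spacing, dims) of the output grid.
#' @param tof [tof_model()] or NULL.
#' @param acceptance [fan_acceptance()].
#' @param pairs_per_block crystal pairs sampled per accepted block pair
#'   (NULL = all pairs; only feasible for coarse luts).
#' @export
sensitivity_map <- function(geometry, lut, efficiencies = NULL,
                            attenuation = NULL, grid_spec, tof = NULL,
                            acceptance, pairs_per_block = 4000L) {
  bp <- accepted_pairs(acceptance)
  ncr <- lut$ncr
  img <- numeric(prod(grid_spec$dims))
  tspec <- tof_cpp_spec(tof)
  for (i in seq_len(nrow(bp))) {
    if (is.null(pairs_per_block) || ncr^2 <= pairs_per_block) {
      g <- expand.grid(cr1 = seq_len(ncr) - 1L, cr2 = seq_len(ncr) - 1L)
      cr1 <- g$cr1; cr2 <- g$cr2
      fac <- 1
    } else {
      cr1 <- sample.int(ncr, pairs_per_block, replace = TRUE) - 1L
      cr2 <- sample.int(ncr, pairs_per_block, replace = TRUE) - 1L
      fac <- ncr^2 / pairs_per_block
    }
    p1 <- crystal_center_global(geometry, bp[i, 1], cr1, lut)
    p2 <- crystal_center_global(geometry, bp[i, 2], cr2, lut)
    w <- rep(fac, length(cr1))
    if (!is.null(efficiencies))
      w <- w * efficiencies[cbind(bp[i, 1] + 1L, cr1 + 1L)] *
        efficiencies[cbind(bp[i, 2] + 1L, cr2 + 1L)]
    if (!is.null(attenuation))
      w <- w * exp(-line_integral(attenuation, p1, p2))
    tb <- rep(if (is.null(tof)) -2L else -1L, length(cr1))
    cpp_backproject(img, grid_spec$origin, grid_spec$spacing,
                    as.integer(grid_spec$dims), p1, p2, w, tb, tspec)
  }
  if (all(img == 0)) stop("sensitivity map is identically zero")
  voxel_grid(array(img, grid_spec$dims), grid_spec$origin, grid_spec$spacing)
}

#' List-mode OSEM reconstruction
#'
#' Standard multiplicative LM-OSEM: per subset, forward-project the current
#' image along each event's TOF-weighted LOR (averaging `lors_per_event`
#' lines sampled inside the two crystal voxels), backproject the ratios
#' `1 / forward`, and multiply the image by the backprojection divided by
#' the sensitivity map. Nonnegativity is preserved; voxels with zero
#' sensitivity stay zero. Events whose forward projection is zero are
#' skipped (count reported in the result attributes).
#'
#' @param binned crystal-binned events (with TOF bin column `t` when `tof`
#'   is supplied).
#' @param geometry aligned `pet_blueprint`.
#' @param lut crystal lookup table.
#' @param sensitivity sensitivity `voxel_grid` (from [sensitivity_map()]);
#'   defines the reconstruction grid.
#' @param efficiencies,attenuation optional model factors.
#' @param tof [tof_model()] or NULL.
#' @param control a [recon_control()].
#' @return Reconstructed `voxel_grid`; attribute `skipped` counts events
#'   with zero forward projection.
#' @export
lm_osem <- function(binned, geometry, lut, sensitivity, efficiencies = NULL,
                    attenuation = NULL, tof = NULL,
                    control = recon_control()) {
  stopifnot(nrow(binned) > 0)
  set.seed(control$seed)
  gs <- list(origin = sensitivity$origin, spacing = sensitivity$spacing,
             dims = sensitivity$dims)
  sens <- as.numeric(sensitivity$values)
  live <- sens > 0
  img <- as.numeric(live) # uniform start inside the sensitive FOV
  subsets <- subset_split(binned, geometry, lut, control$n_subsets)
  tspec <- tof_cpp_spec(tof)
  nskip <- 0L
  S <- control$lors_per_event
  for (iter in seq_len(control$n_iterations)) {
    for (sub in subsets) {
      ev <- binned[sub, , drop = FALSE]
      ne <- nrow(ev)
      if (ne == 0) next
      # sample S lines per event inside the crystal voxels
      rep_idx <- rep(seq_len(ne), each = S)
      o1 <- matrix(runif(3 * ne * S, -1, 1), ne * S, 3) *
        lut$half_extents[ev$cr1[rep_idx] + 1L, , drop = FALSE]
      o2 <- matrix(runif(3 * ne * S, -1, 1), ne * S, 3) *
        lut$half_extents[ev$cr2[rep_idx] + 1L, , drop = FALSE]
      l1 <- lut$centers[ev$cr1[rep_idx] + 1L, , drop = FALSE] + o1
      l2 <- lut$centers[ev$cr2[rep_idx] + 1L, , drop = FALSE] + o2
      p1 <- local_points_to_global(geometry, ev$d1[rep_idx], l1)
      p2 <- local_points_to_global(geometry, ev$d2[rep_idx], l2)
      tb <- if (is.null(tof)) rep(-2L, ne * S) else (ev$t[rep_idx] - 1L)
      cur <- voxel_grid(array(img, gs$dims), gs$origin, gs$spacing)
      ga <- grid_cpp_args(cur, use_bricks = FALSE)
      spec <- tspec
      spec$tbin <- pmax(tb, 0L)
      spec$mode <- if (is.null(tof)) 0L else 1L
      fp <- cpp_line_integrals(ga$values, ga$origin, ga$spacing, ga$dims,
                               ga$brick, ga$bdims, ga$bsz, ga$boxes, p1, p2,
                               spec, FALSE, NULL)
      fpe <- rowsum(fp, rep_idx)[, 1] / S
      att <- 1
      if (!is.null(attenuation) || !is.null(efficiencies)) {
        fac <- rep(1, ne)
        if (!is.null(efficiencies))
          fac <- fac * efficiencies[cbind(ev$d1 + 1L, ev$cr1 + 1L)] *
            efficiencies[cbind(ev$d2 + 1L, ev$cr2 + 1L)]
        if (!is.null(attenuation)) {
          c1 <- crystal_center_global(geometry, ev$d1, ev$cr1, lut)
          c2 <- crystal_center_global(geometry, ev$d2, ev$cr2, lut)
          fac <- fac * exp(-line_integral(attenuation, c1, c2))
        }
        fpe <- fpe * fac
        att <- fac
      }
      ok <- fpe > 0
      nskip <- nskip + sum(!ok)
      if (!any(ok)) next
      ratio <- numeric(ne)
      ratio[ok] <- (if (length(att) > 1) att[ok] else 1) / fpe[ok]
      back <- numeric(length(img))
      wline <- ratio[rep_idx] / S
      keep <- wline > 0
      cpp_backproject(back, gs$origin, gs$spacing, as.integer(gs$dims),
                      p1[keep, , drop = FALSE], p2[keep, , drop = FALSE],
                      wline[keep], tb[keep], tspec)
      img[live] <- img[live] * back[live] / sens[live]
      img[!live] <- 0
    }
  }
  out <- voxel_grid(array(img, gs$dims), gs$origin, gs$spacing)
  attr(out, "skipped") <- nskip
  out
}
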
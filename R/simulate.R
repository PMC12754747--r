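# Back-to-back coincidence simulator and histogramming.
#
# Emission points are drawn activity-proportionally from the phantom, paired
# photons are cast along a uniformly random direction, and each photon is
# assigned to the first detector block its ray enters. The interaction depth
# follows a uniform free-path model (thin-absorber limit): the photon
# interacts at a uniform random distance in [0, free_path_max] along its
# chord through the block, or escapes if that exceeds the chord. Detection
# probability is then proportional to path length in the crystal material,
# which is exactly the response the line-integral forward model assumes, and
# the within-voxel interaction distribution matches the model's
# uniform-in-voxel endpoint sampling to first order. Optional thinning by
# per-crystal efficiencies and by the attenuation survival probability; the
# TOF coordinate is the true signed midpoint offset plus Gaussian blur of the
# kernel FWHM. Events store block-local interaction coordinates so they can
# be rebinned under any crystal-voxel layout.

#' Simulate list-mode coincidence events
#'
#' @param geometry ground-truth `pet_blueprint` (simulation geometry).
#' @param phantom a `pet_phantom` or activity `voxel_grid`.
#' @param n_events number of accepted coincidences to produce.
#' @param tof a [tof_model()] or `NULL`; when given, the blurred TOF offset
#'   is stored (binning happens in [bin_events()]).
#' @param efficiencies optional Ndet x Ncr matrix of detection probabilities
#'   in `[0, 1]` (requires `lut`); events are thinned by `E1 * E2`.
#' @param lut crystal layout used only for efficiency thinning.
#' @param attenuation optional attenuation map; events are thinned by the
#'   Beer-Lambert survival along the path between the interaction points.
#' @param free_path_max scale of the uniform free-path depth model (mm);
#'   default three times the block DOI depth. Chords longer than this are
#'   truncated (rare, very oblique paths).
#' @param chunk_size candidate emissions per chunk.
#' @return A `data.frame` of class `pet_events` with detector indices,
#'   block-local interaction coordinates, and the (blurred) TOF offset `s`
#'   (mm, positive toward detector 1).
#' @export
simulate_events <- function(geometry, phantom, n_events, tof = NULL,
                            efficiencies = NULL, lut = NULL,
                            attenuation = NULL, free_path_max = NULL,
                            chunk_size = 500000L) {
  stopifnot(n_events >= 0)
  if (!is.null(efficiencies)) {
    if (is.null(lut)) stop("efficiency thinning requires a crystal lut")
    if (any(efficiencies > 1))
      stop("simulator efficiencies are probabilities and must be <= 1")
  }
  cols <- c("d1", "x1", "y1", "z1", "d2", "x2", "y2", "z2", "s")
  if (n_events == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, 9, dimnames = list(NULL, cols)))
    class(out) <- c("pet_events", class(out))
    return(out)
  }
  axes <- cbind(geometry$axes_x, geometry$axes_y, geometry$axes_z)
  half <- geometry$block_dims / 2
  if (is.null(free_path_max)) free_path_max <- 3 * geometry$block_dims[2]
  sigma <- if (is.null(tof)) 0 else tof$sigma
  acc <- vector("list", 0)
  got <- 0L
  guard <- 0L
  rate <- 0.05  # running acceptance estimate, refined after the first chunk
  while (got < n_events) {
    guard <- guard + 1L
    if (guard > 5000L) stop("acceptance rate too low; check the geometry")
    m <- as.integer(min(chunk_size,
                        max(ceiling(1.3 * (n_events - got) / rate), 50000L)))
    em <- sample_emissions(phantom, m)
    cz <- runif(m, -1, 1)
    cphi <- runif(m, 0, 2 * pi)
    st <- sqrt(1 - cz^2)
    dir <- cbind(st * cos(cphi), st * sin(cphi), cz)
    u1 <- runif(m)
    u2 <- runif(m)
    tr <- cpp_trace_rays(geometry$positions, axes, half, em, dir, u1, u2,
                         free_path_max)
    ok <- tr$ok
    if (!any(ok)) next
    d1 <- tr$d1[ok]; d2 <- tr$d2[ok]
    l1 <- tr$l1[ok, , drop = FALSE]; l2 <- tr$l2[ok, , drop = FALSE]
    s <- tr$s[ok]
    if (!is.null(efficiencies)) {
      cr1 <- crystal_index_from_local(lut, l1)
      cr2 <- crystal_index_from_local(lut, l2)
      p <- efficiencies[cbind(d1 + 1L, cr1 + 1L)] *
        efficiencies[cbind(d2 + 1L, cr2 + 1L)]
      keep <- runif(length(p)) < p
      d1 <- d1[keep]; d2 <- d2[keep]
      l1 <- l1[keep, , drop = FALSE]; l2 <- l2[keep, , drop = FALSE]
      s <- s[keep]
    }
    if (!is.null(attenuation) && length(d1) > 0) {
      # survival along the full path between the interaction points
      p1g <- local_points_to_global(geometry, d1, l1)
      p2g <- local_points_to_global(geometry, d2, l2)
      surv <- exp(-line_integral(attenuation, p1g, p2g))
      keep <- runif(length(surv)) < surv
      d1 <- d1[keep]; d2 <- d2[keep]
      l1 <- l1[keep, , drop = FALSE]; l2 <- l2[keep, , drop = FALSE]
      s <- s[keep]
    }
    rate <- max(0.5 * rate + 0.5 * sum(ok) / m, 1e-4)
    if (length(d1) == 0) next
    if (sigma > 0) s <- s + rnorm(length(s), 0, sigma)
    df <- data.frame(d1 = d1, x1 = l1[, 1], y1 = l1[, 2], z1 = l1[, 3],
                     d2 = d2, x2 = l2[, 1], y2 = l2[, 2], z2 = l2[, 3],
                     s = s)
    acc[[length(acc) + 1L]] <- df
    got <- got + nrow(df)
  }
  out <- do.call(rbind, acc)
  out <- out[seq_len(n_events), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pet_events", class(out))
  attr(out, "tof") <- tof
  out
}

local_points_to_global <- function(geometry, d, local) {
  geometry$positions[d + 1L, , drop = FALSE] +
    local[, 1] * geometry$axes_x[d + 1L, , drop = FALSE] +
    local[, 2] * geometry$axes_y[d + 1L, , drop = FALSE] +
    local[, 3] * geometry$axes_z[d + 1L, , drop = FALSE]
}

#' Bin events into crystal-pair / TOF coincidence bins
#'
#' Assigns each interaction to the crystal voxel containing it, bins the TOF
#' offset, and canonicalizes each event so that `d1 < d2` (the TOF sign is
#' mirrored on swap, keeping "positive toward detector 1"). Events whose TOF
#' offset falls outside the tiled bin range are dropped.
#'
#' @param events `pet_events`.
#' @param lut crystal layout (`pet_crystal_lut`).
#' @param tof [tof_model()] or `NULL` (then `t` is 0 for all events).
#' @return data.frame with columns d1, cr1, d2, cr2, t.
#' @export
bin_events <- function(events, lut, tof = NULL) {
  d1 <- events$d1; d2 <- events$d2
  s <- events$s
  cr1 <- crystal_index_from_local(lut, cbind(events$x1, events$y1, events$z1))
  cr2 <- crystal_index_from_local(lut, cbind(events$x2, events$y2, events$z2))
  swap <- d1 > d2
  if (any(swap)) {
    tmp <- d1[swap]; d1[swap] <- d2[swap]; d2[swap] <- tmp
    tmp <- cr1[swap]; cr1[swap] <- cr2[swap]; cr2[swap] <- tmp
    s[swap] <- -s[swap]
  }
  if (is.null(tof)) {
    t <- rep(0L, length(d1))
  } else {
    t <- tof_bin_of(tof, s)
  }
  keep <- !is.na(t)
  data.frame(d1 = d1[keep], cr1 = cr1[keep], d2 = d2[keep], cr2 = cr2[keep],
             t = t[keep])
}

#' Coincidence histogram
#'
#' Exact multiset count of binned events, stored sparsely.
#'
#' @param binned data.frame with d1, cr1, d2, cr2, t (from [bin_events()]).
#' @param ndet,ncr geometry metadata carried for bookkeeping.
#' @return data.table of class `coincidence_histogram` with a count column
#'   `n`; `sum(n)` equals the number of events.
#' @export
histogram_events <- function(binned, ndet = NULL, ncr = NULL) {
  dt <- data.table::as.data.table(binned)
  h <- dt[, list(n = .N), by = c("d1", "cr1", "d2", "cr2", "t")]
  data.table::setattr(h, "class",
                      c("coincidence_histogram", class(h)))
  data.table::setattr(h, "ndet", ndet)
  data.table::setattr(h, "ncr", ncr)
  h
}

#' @export
print.coincidence_histogram <- function(x, ...) {
  cat("coincidence_histogram:", nrow(x), "occupied bins,",
      sum(x$n), "events\n")
  invisible(x)
}

# expand a histogram back to one row per event (testing utility)
expand_histogram <- function(hist) {
  idx <- rep(seq_len(nrow(hist)), hist$n)
  as.data.frame(hist[idx, c("d1", "cr1", "d2", "cr2", "t"), with = FALSE])
}

#' Detector-pair acceptance fan
#'
#' Accepts pairs `(d, d')` where `d'` is among the `n_opposing` transaxially
#' most-opposed blocks of `d`'s ring, within a maximum ring difference
#' (1 when `include_axial_neighbors`, 0 otherwise, or any explicit value).
#' The predicate is symmetric.
#'
#' @param blueprint a ring-structured `pet_blueprint`.
#' @param n_opposing number of most-opposed blocks accepted per ring.
#' @param include_axial_neighbors also accept the axially adjacent rings.
#' @param max_ring_diff explicit maximum ring difference (overrides the
#'   neighbor flag; use `Inf` for all ring combinations).
#' @return Object of class `fan_acceptance` holding the symmetric Ndet x Ndet
#'   logical acceptance matrix.
#' @export
fan_acceptance <- function(blueprint, n_opposing = 3L,
                           include_axial_neighbors = TRUE,
                           max_ring_diff = NULL) {
  stopifnot(n_opposing >= 1)
  meta <- blueprint$meta
  if (is.null(meta$blocks_per_ring))
    stop("fan acceptance requires ring metadata on the blueprint")
  npr <- meta$blocks_per_ring
  if (is.null(max_ring_diff))
    max_ring_diff <- if (include_axial_neighbors) 1L else 0L
  ring <- meta$ring
  in_ring <- meta$in_ring
  nd <- blueprint$ndet
  # transaxial opposition: circular index distance closest to npr/2
  di <- abs(outer(in_ring, in_ring, "-"))
  di <- pmin(di, npr - di)
  opp <- abs(di - npr / 2)
  ranks <- sort(unique(as.vector(opp)))
  # accept the n_opposing distinct offsets closest to full opposition
  keep_off <- numeric(0)
  cnt <- 0
  for (r in ranks) {
    sel <- which(opp[1, ] == r & seq_len(nd) != 1 & ring == ring[1])
    cnt <- cnt + length(sel)
    keep_off <- c(keep_off, r)
    if (cnt >= n_opposing) break
  }
  ok_trans <- matrix(opp %in% keep_off, nd, nd)
  ok_ring <- abs(outer(ring, ring, "-")) <= max_ring_diff
  A <- ok_trans & ok_ring
  diag(A) <- FALSE
  # trim to exactly n_opposing per ring if the last offset overshoots
  structure(list(matrix = A, n_opposing = n_opposing,
                 max_ring_diff = max_ring_diff),
            class = "fan_acceptance")
}

#' @rdname fan_acceptance
#' @param acceptance a `fan_acceptance`.
#' @param d,dp 0-based detector indices (vectorized).
#' @export
accepts <- function(acceptance, d, dp) {
  acceptance$matrix[cbind(d + 1L, dp + 1L)]
}

# unordered accepted block pairs as a 2-column 0-based matrix
accepted_pairs <- function(acceptance) {
  w <- which(acceptance$matrix & upper.tri(acceptance$matrix), arr.ind = TRUE)
  cbind(d1 = w[, 1] - 1L, d2 = w[, 2] - 1L)
}

#' Fan-sum crystal efficiency estimation
#'
#' For each crystal voxel, sums the coincidences it shares with partners in
#' its acceptance fan; the raw counts are used directly as efficiency
#' estimates with no geometric correction (applying one would require the
#' true alignment, which is what the calibration is trying to find).
#'
#' @param histogram a `coincidence_histogram`.
#' @param acceptance a [fan_acceptance()].
#' @param ndet,ncr table dimensions (defaults from histogram attributes).
#' @return Ndet x Ncr matrix of raw fan-sum counts.
#' @export
fan_sum_efficiencies <- function(histogram, acceptance, ndet = NULL,
                                 ncr = NULL) {
  if (nrow(histogram) == 0) stop("empty histogram")
  if (is.null(ndet)) ndet <- attr(histogram, "ndet")
  if (is.null(ncr)) ncr <- attr(histogram, "ncr")
  if (is.null(ndet) || is.null(ncr))
    stop("ndet and ncr must be supplied (or set as histogram attributes)")
  ok <- accepts(acceptance, histogram$d1, histogram$d2)
  h <- histogram[ok]
  eff <- matrix(0, ndet, ncr)
  if (nrow(h) > 0) {
    # column-major linear index of (d, cr) in the Ndet x Ncr matrix
    a1 <- rowsum(as.numeric(h$n), h$d1 + ndet * h$cr1)
    eff[as.integer(rownames(a1)) + 1L] <- eff[as.integer(rownames(a1)) + 1L] +
      a1[, 1]
    a2 <- rowsum(as.numeric(h$n), h$d2 + ndet * h$cr2)
    eff[as.integer(rownames(a2)) + 1L] <- eff[as.integer(rownames(a2)) + 1L] +
      a2[, 1]
  }
  eff
}
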
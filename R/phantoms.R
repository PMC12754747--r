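# Analytic calibration phantoms: point-source sets, thin B-spline tube,
# cylindrical shell, and a Derenzo-style hot-rod pattern. Each phantom can be
# (a) voxelized onto a grid (the known activity image handed to the
# calibration) and (b) sampled analytically for emission points (the
# simulator), avoiding double discretization.

#' Point-source phantom
#'
#' Small uniform spheres with relative activities.
#'
#' @param centers n x 3 matrix of source centers (mm).
#' @param radii source radii (mm), recycled.
#' @param activities relative activities, recycled.
#' @export
phantom_points <- function(centers, radii = 0.125, activities = 1) {
  centers <- as_point_matrix(centers)
  n <- nrow(centers)
  radii <- rep_len(radii, n)
  activities <- rep_len(activities, n)
  stopifnot(all(radii > 0), all(activities > 0))
  structure(list(kind = "point_sources", centers = centers, radii = radii,
                 activities = activities), class = "pet_phantom")
}

#' Thin-tube phantom along a cubic B-spline
#'
#' A tube of constant diameter whose axis is a clamped cubic B-spline with
#' the given control points (the control polygon is not interpolated, as
#' usual for B-splines); activity is uniform along the tube.
#'
#' @param control_points m x 3 matrix (m >= 2) of control points (mm).
#' @param diameter tube diameter (mm).
#' @export
phantom_tube <- function(control_points, diameter = 0.25) {
  control_points <- as_point_matrix(control_points)
  stopifnot(nrow(control_points) >= 2, diameter > 0)
  structure(list(kind = "bspline_tube", control_points = control_points,
                 diameter = diameter), class = "pet_phantom")
}

#' Cylindrical-shell phantom
#'
#' Annular cylinder of the given mean radius, wall thickness and axial
#' length, centered at the origin with axis z.
#'
#' @param radius,thickness,length geometry (mm), all positive.
#' @export
phantom_shell <- function(radius, thickness, length) {
  stopifnot(radius > 0, thickness > 0, length > 0, thickness / 2 < radius)
  structure(list(kind = "cylindrical_shell", radius = radius,
                 thickness = thickness, length = length),
            class = "pet_phantom")
}

#' Hot-rod (Derenzo-style) resolution phantom
#'
#' Six triangular sectors of parallel rods, one rod diameter per sector,
#' center-to-center spacing twice the diameter, extruded axially; plus a
#' uniformly filled annular shell around the rod region (used for the
#' uniformity / COV evaluation).
#'
#' @param diameters rod diameters per sector (mm).
#' @param sector_radius radial extent of the rod region (mm).
#' @param axial_length phantom length (mm).
#' @param shell_width radial width of the uniform annulus (0 disables it).
#' @param r0 inner radial offset of the first rod row (mm).
#' @export
phantom_hotrod <- function(diameters = c(2, 1.5, 1.2, 1.0, 0.9, 0.8),
                           sector_radius = 12, axial_length = 10,
                           shell_width = 2.5, r0 = 3) {
  stopifnot(all(diameters > 0), sector_radius > 0, axial_length > 0)
  structure(list(kind = "hotrod", diameters = diameters,
                 sector_radius = sector_radius, axial_length = axial_length,
                 shell_width = shell_width, r0 = r0,
                 layout = hotrod_layout(diameters, sector_radius, r0)),
            class = "pet_phantom")
}

# triangular rod lattice per 60 degree sector; returns per-diameter rod
# centers and inter-rod valley midpoints (transaxial mm)
hotrod_layout <- function(diameters, sector_radius, r0) {
  out <- vector("list", length(diameters))
  for (k in seq_along(diameters)) {
    d <- diameters[k]
    s <- 2 * d
    pts <- NULL
    j <- 0
    repeat {
      r <- r0 + j * s * sqrt(3) / 2
      if (r > sector_radius - d / 2) break
      off <- (seq_len(j + 1) - 1 - j / 2) * s
      pts <- rbind(pts, cbind(off, r))
      j <- j + 1
    }
    if (is.null(pts)) stop("sector too small for rod diameter ", d)
    # keep rods inside a 60-degree wedge around +y
    ang <- atan2(pts[, 1], pts[, 2])
    pts <- pts[abs(ang) <= pi / 6 + 1e-9, , drop = FALSE]
    # valleys: midpoints of nearest-neighbor rod pairs
    valleys <- NULL
    if (nrow(pts) > 1) {
      for (i in seq_len(nrow(pts) - 1)) {
        dd <- sqrt(rowSums((pts[-(1:i), , drop = FALSE] -
                              matrix(pts[i, ], nrow(pts) - i, 2,
                                     byrow = TRUE))^2))
        nb <- which(dd < s * 1.05)
        if (length(nb))
          valleys <- rbind(valleys,
                           (pts[i + nb, , drop = FALSE] +
                              matrix(pts[i, ], length(nb), 2,
                                     byrow = TRUE)) / 2)
      }
    }
    # rotate sector k into place (sectors at 60 degree steps)
    th <- (k - 1) * pi / 3
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    out[[k]] <- list(diameter = d, centers = pts %*% t(Rm),
                     valleys = if (is.null(valleys)) NULL
                               else valleys %*% t(Rm))
  }
  names(out) <- paste0("d", diameters)
  out
}

# clamped cubic B-spline curve through the control polygon, evaluated densely
bspline_curve <- function(control_points, n_eval = 2000) {
  cp <- as.matrix(control_points)
  m <- nrow(cp)
  if (m < 4) {  # fall back to lower degree for short polygons
    deg <- m - 1
  } else deg <- 3
  ord <- deg + 1
  nknot <- m + ord
  inner <- nknot - 2 * ord
  knots <- c(rep(0, ord), if (inner > 0) seq_len(inner) / (inner + 1),
             rep(1, ord))
  u <- seq(0, 1, length.out = n_eval)
  u[n_eval] <- 1 - 1e-9   # splineDesign right-end convention
  B <- splines::splineDesign(knots, u, ord = ord, outer.ok = FALSE)
  B %*% cp
}

phantom_bbox <- function(spec) {
  switch(spec$kind,
    point_sources = {
      r <- max(spec$radii)
      rbind(apply(spec$centers, 2, min) - r, apply(spec$centers, 2, max) + r)
    },
    bspline_tube = {
      cv <- bspline_curve(spec$control_points)
      r <- spec$diameter / 2
      rbind(apply(cv, 2, min) - r, apply(cv, 2, max) + r)
    },
    cylindrical_shell = {
      ro <- spec$radius + spec$thickness / 2
      rbind(c(-ro, -ro, -spec$length / 2), c(ro, ro, spec$length / 2))
    },
    hotrod = {
      ro <- spec$sector_radius + spec$shell_width + 1
      rbind(c(-ro, -ro, -spec$axial_length / 2),
            c(ro, ro, spec$axial_length / 2))
    },
    stop("unknown phantom kind"))
}

# fraction of each voxel (rows of `centers`) inside the phantom, by
# supersampling each voxel with sub^3 points; indicator(points) -> logical
partial_volume <- function(centers, spacing, indicator, sub = 3L) {
  off <- (seq_len(sub) - 0.5) / sub - 0.5
  og <- as.matrix(expand.grid(x = off * spacing[1], y = off * spacing[2],
                              z = off * spacing[3]))
  frac <- numeric(nrow(centers))
  for (i in seq_len(nrow(og))) {
    pts <- sweep(centers, 2, og[i, ], "+")
    frac <- frac + indicator(pts)
  }
  frac / nrow(og)
}

#' Voxelize an analytic phantom
#'
#' Rasterizes the phantom onto a regular grid with partial-volume
#' supersampling (each candidate voxel subdivided 3x3x3). The grid covers the
#' phantom bounding box plus `padding` mm of zeros on every side, so line
#' integrals see a clean zero margin. Voxel values are activity per mm^3;
#' total mass equals the total phantom activity.
#'
#' @param spec a `pet_phantom`.
#' @param spacing voxel size (mm, isotropic scalar or length-3).
#' @param padding zero margin (mm).
#' @return A [voxel_grid()] with brick occupancy cached for fast projection.
#' @export
voxelize_phantom <- function(spec, spacing = 0.25, padding = 3) {
  spacing <- rep_len(spacing, 3)
  stopifnot(all(spacing > 0), padding >= 2 * max(spacing))
  bb <- phantom_bbox(spec)
  origin <- bb[1, ] - padding
  dims <- as.integer(ceiling((bb[2, ] - bb[1, ] + 2 * padding) / spacing))
  vals <- array(0, dims)
  voxvol <- prod(spacing)

  add_mass <- function(idx, mass) {
    # idx: n x 3 1-based voxel indices; mass: activity per voxel
    lin <- idx[, 1] + dims[1] * ((idx[, 2] - 1L) + dims[2] * (idx[, 3] - 1L))
    acc <- rowsum(mass, lin)
    vals[as.integer(rownames(acc))] <<- vals[as.integer(rownames(acc))] +
      acc[, 1] / voxvol
  }

  candidate_centers <- function(lo, hi) {
    il <- pmax(floor((lo - origin) / spacing) + 1L, 1L)
    ih <- pmin(ceiling((hi - origin) / spacing), dims)
    if (any(il > ih)) return(NULL)
    g <- as.matrix(expand.grid(x = il[1]:ih[1], y = il[2]:ih[2],
                               z = il[3]:ih[3]))
    list(idx = g, centers = sweep((g - 0.5) * rep(spacing, each = nrow(g)),
                                  2, origin, "+"))
  }

  if (spec$kind == "point_sources") {
    for (i in seq_len(nrow(spec$centers))) {
      ctr <- spec$centers[i, ]
      r <- spec$radii[i]
      cc <- candidate_centers(ctr - r - spacing, ctr + r + spacing)
      frac <- partial_volume(cc$centers, spacing, function(p)
        rowSums(sweep(p, 2, ctr)^2) <= r^2, sub = 4L)
      keep <- frac > 0
      if (!any(keep)) {  # source smaller than a voxel: deposit at nearest
        idx <- pmin(pmax(floor((ctr - origin) / spacing) + 1L, 1L), dims)
        add_mass(matrix(idx, 1), spec$activities[i])
      } else {
        w <- frac[keep] / sum(frac[keep])
        add_mass(cc$idx[keep, , drop = FALSE], spec$activities[i] * w)
      }
    }
  } else if (spec$kind == "bspline_tube") {
    r <- spec$diameter / 2
    if (spec$diameter <= 2 * min(spacing)) {
      # thin tube (up to about two voxels wide): deposit arclength-weighted
      # mass by trilinear splatting of dense axis samples. This conserves
      # mass exactly and preserves the local first moment (the axis
      # position), which is what the forward model needs; the radial
      # footprint is the trilinear kernel itself (about one voxel),
      # symmetric about the axis.
      cv <- bspline_curve(spec$control_points,
                          n_eval = max(4000,
                                       ceiling(800 / min(spacing))))
      seg <- diff(cv)
      seglen <- sqrt(rowSums(seg^2))
      mid <- (cv[-1, , drop = FALSE] + cv[-nrow(cv), , drop = FALSE]) / 2
      wgt <- seglen / sum(seglen)
      g <- sweep(mid, 2, origin) / rep(spacing, each = nrow(mid)) - 0.5
      i0 <- floor(g)
      fr <- g - i0
      for (k in 0:7) {
        dx <- k %% 2; dy <- (k %/% 2) %% 2; dz <- k %/% 4
        idx <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz) + 1L
        wk <- (dx * fr[, 1] + (1 - dx) * (1 - fr[, 1])) *
          (dy * fr[, 2] + (1 - dy) * (1 - fr[, 2])) *
          (dz * fr[, 3] + (1 - dz) * (1 - fr[, 3]))
        ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
          idx[, 2] >= 1 & idx[, 2] <= dims[2] &
          idx[, 3] >= 1 & idx[, 3] <= dims[3]
        add_mass(idx[ok, , drop = FALSE], wgt[ok] * wk[ok])
      }
    } else {
      cv <- bspline_curve(spec$control_points,
                          n_eval = max(2000, ceiling(400 / min(spacing))))
      # gather candidate voxels near the curve, then exact min distance to
      # the polyline via its dense point cloud
      reach <- r + max(spacing) * 1.5
      cand <- unique(do.call(rbind,
        lapply(seq(1, nrow(cv), by = 4), function(i)
          candidate_centers(cv[i, ] - reach, cv[i, ] + reach)$idx)))
      centers <- sweep((cand - 0.5) * rep(spacing, each = nrow(cand)), 2,
                       origin, "+")
      frac <- partial_volume(centers, spacing, function(p)
        point_cloud_within(p, cv, r), sub = 3L)
      keep <- frac > 0
      w <- frac[keep] / sum(frac[keep])
      add_mass(cand[keep, , drop = FALSE], w)  # unit total activity
    }
  } else if (spec$kind == "cylindrical_shell") {
    ro <- spec$radius + spec$thickness / 2
    ri <- spec$radius - spec$thickness / 2
    cc <- candidate_centers(c(-ro, -ro, -spec$length / 2) - spacing,
                            c(ro, ro, spec$length / 2) + spacing)
    frac <- partial_volume(cc$centers, spacing, function(p) {
      rr <- sqrt(p[, 1]^2 + p[, 2]^2)
      rr >= ri & rr <= ro & abs(p[, 3]) <= spec$length / 2
    })
    keep <- frac > 0
    add_mass(cc$idx[keep, , drop = FALSE],
             frac[keep] / sum(frac[keep]))
  } else if (spec$kind == "hotrod") {
    rods <- hotrod_rods(spec)
    cc <- candidate_centers(phantom_bbox(spec)[1, ] - spacing,
                            phantom_bbox(spec)[2, ] + spacing)
    frac <- partial_volume(cc$centers, spacing, function(p)
      hotrod_inside(spec, rods, p))
    keep <- frac > 0
    add_mass(cc$idx[keep, , drop = FALSE], frac[keep] / sum(frac[keep]))
  }
  if (sum(vals) == 0) stop("phantom rasterized to an empty grid")
  with_bricks(voxel_grid(vals, origin, spacing))
}

# TRUE where points lie within r of the dense polyline (point-cloud metric;
# the cloud is sampled finely enough that the error is << spacing). Both
# dimensions are processed in blocks to bound memory.
point_cloud_within <- function(p, cloud, r) {
  np <- nrow(p)
  d2min <- rep(Inf, np)
  pb <- 20000L
  cb <- 400L
  for (j0 in seq(1, np, by = pb)) {
    j1 <- min(j0 + pb - 1L, np)
    pj <- p[j0:j1, , drop = FALSE]
    dmin <- rep(Inf, j1 - j0 + 1L)
    for (i0 in seq(1, nrow(cloud), by = cb)) {
      i1 <- min(i0 + cb - 1L, nrow(cloud))
      cl <- cloud[i0:i1, , drop = FALSE]
      d2 <- outer(pj[, 1], cl[, 1], "-")^2
      d2 <- d2 + outer(pj[, 2], cl[, 2], "-")^2
      d2 <- d2 + outer(pj[, 3], cl[, 3], "-")^2
      dmin <- pmin(dmin, do.call(pmin, as.data.frame(d2)))
    }
    d2min[j0:j1] <- dmin
  }
  d2min <= r^2
}

hotrod_rods <- function(spec) {
  do.call(rbind, lapply(spec$layout, function(l)
    cbind(l$centers, d = l$diameter)))
}

hotrod_inside <- function(spec, rods, p) {
  inside <- logical(nrow(p))
  okz <- abs(p[, 3]) <= spec$axial_length / 2
  for (i in seq_len(nrow(rods))) {
    inside <- inside | ((p[, 1] - rods[i, 1])^2 + (p[, 2] - rods[i, 2])^2 <=
                          (rods[i, 3] / 2)^2)
  }
  if (spec$shell_width > 0) {
    rr <- sqrt(p[, 1]^2 + p[, 2]^2)
    ri <- spec$sector_radius + 0.5
    inside <- inside | (rr >= ri & rr <= ri + spec$shell_width)
  }
  inside & okz
}

# mask of the uniform annulus (for COV evaluation) on a given grid
hotrod_uniform_mask <- function(spec, grid) {
  stopifnot(spec$kind == "hotrod", spec$shell_width > 0)
  cx <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * grid$spacing[1]
  cy <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * grid$spacing[2]
  cz <- grid$origin[3] + (seq_len(grid$dims[3]) - 0.5) * grid$spacing[3]
  ri <- spec$sector_radius + 0.5 + 0.4
  ro <- spec$sector_radius + 0.5 + spec$shell_width - 0.4
  rr <- sqrt(outer(cx^2, cy^2, "+"))
  m2d <- rr >= ri & rr <= ro
  zin <- abs(cz) <= spec$axial_length / 2 - 0.4
  array(outer(m2d, zin, "&"), grid$dims)
}

#' Sample emission points from a phantom
#'
#' Analytic activity-proportional sampling (uniform in each ball, uniform in
#' arclength along the tube axis plus a uniform disc offset, uniform in the
#' shell / rod volumes). Uses the R RNG.
#'
#' @param spec a `pet_phantom` or a `voxel_grid` (sampled voxel-wise).
#' @param n number of points.
#' @return n x 3 matrix of points (mm).
#' @export
sample_emissions <- function(spec, n) {
  if (inherits(spec, "voxel_grid")) {
    w <- as.numeric(spec$values)
    nz <- which(w > 0)
    pick <- nz[sample.int(length(nz), n, replace = TRUE, prob = w[nz])]
    idx <- arrayInd(pick, spec$dims)
    jit <- matrix(runif(3 * n) - 0.5, n, 3)
    return(sweep((idx - 0.5 + jit) * rep(spec$spacing, each = n), 2,
                 spec$origin, "+"))
  }
  switch(spec$kind,
    point_sources = {
      probs <- spec$activities / sum(spec$activities)
      src <- sample.int(nrow(spec$centers), n, replace = TRUE, prob = probs)
      r <- spec$radii[src] * runif(n)^(1 / 3)
      u <- rnorm(3 * n)
      dim(u) <- c(n, 3)
      u <- u / sqrt(rowSums(u^2))
      spec$centers[src, , drop = FALSE] + u * r
    },
    bspline_tube = {
      cv <- bspline_curve(spec$control_points)
      seg <- diff(cv)
      seglen <- sqrt(rowSums(seg^2))
      cum <- c(0, cumsum(seglen))
      s <- runif(n) * cum[length(cum)]
      i <- findInterval(s, cum, rightmost.closed = TRUE)
      f <- (s - cum[i]) / seglen[i]
      pts <- cv[i, , drop = FALSE] + seg[i, , drop = FALSE] * f
      tang <- seg[i, , drop = FALSE] / seglen[i]
      # orthonormal frame per point
      ref <- matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE)
      par <- abs(tang[, 3]) > 0.9
      ref[par, ] <- matrix(rep(c(1, 0, 0), sum(par)), sum(par), 3,
                           byrow = TRUE)
      n1 <- cbind(tang[, 2] * ref[, 3] - tang[, 3] * ref[, 2],
                  tang[, 3] * ref[, 1] - tang[, 1] * ref[, 3],
                  tang[, 1] * ref[, 2] - tang[, 2] * ref[, 1])
      n1 <- n1 / sqrt(rowSums(n1^2))
      n2 <- cbind(tang[, 2] * n1[, 3] - tang[, 3] * n1[, 2],
                  tang[, 3] * n1[, 1] - tang[, 1] * n1[, 3],
                  tang[, 1] * n1[, 2] - tang[, 2] * n1[, 1])
      rho <- spec$diameter / 2 * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      pts + n1 * (rho * cos(th)) + n2 * (rho * sin(th))
    },
    cylindrical_shell = {
      ro <- spec$radius + spec$thickness / 2
      ri <- spec$radius - spec$thickness / 2
      r <- sqrt(runif(n) * (ro^2 - ri^2) + ri^2)
      th <- runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th), runif(n, -0.5, 0.5) * spec$length)
    },
    hotrod = {
      rods <- hotrod_rods(spec)
      vol_rod <- pi * (rods[, 3] / 2)^2
      ri <- spec$sector_radius + 0.5
      vol_shell <- if (spec$shell_width > 0)
        pi * ((ri + spec$shell_width)^2 - ri^2) else 0
      w <- c(vol_rod, vol_shell)
      pick <- sample.int(length(w), n, replace = TRUE, prob = w)
      z <- runif(n, -0.5, 0.5) * spec$axial_length
      out <- matrix(0, n, 3)
      rod_ev <- pick <= nrow(rods)
      if (any(rod_ev)) {
        k <- pick[rod_ev]
        rr <- rods[k, 3] / 2 * sqrt(runif(sum(rod_ev)))
        th <- runif(sum(rod_ev), 0, 2 * pi)
        out[rod_ev, 1] <- rods[k, 1] + rr * cos(th)
        out[rod_ev, 2] <- rods[k, 2] + rr * sin(th)
      }
      if (any(!rod_ev)) {
        m <- sum(!rod_ev)
        r <- sqrt(runif(m) * ((ri + spec$shell_width)^2 - ri^2) + ri^2)
        th <- runif(m, 0, 2 * pi)
        out[!rod_ev, 1] <- r * cos(th)
        out[!rod_ev, 2] <- r * sin(th)
      }
      out[, 3] <- z
      out
    },
    stop("unknown phantom kind"))
}
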
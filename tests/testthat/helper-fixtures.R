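# Shared fixtures: smooth random fields, small scanners, tiny phantoms.

# sum of Gaussian blobs with an enforced zero margin; smooth enough that
# plane-stepping quadrature and dense sampling agree closely
blob_grid <- function(dims = c(40, 36, 32), sp = c(1, 1, 1),
                      origin = -dims * sp / 2, nblob = 6, sigma = c(3, 5),
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * sp[1]
  cy <- origin[2] + (seq_len(dims[2]) - 0.5) * sp[2]
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * sp[3]
  v <- array(0, dims)
  for (b in seq_len(nblob)) {
    ctr <- runif(3, -8, 8)
    s <- runif(1, sigma[1], sigma[2])
    v <- v + outer(outer(exp(-(cx - ctr[1])^2 / (2 * s^2)),
                         exp(-(cy - ctr[2])^2 / (2 * s^2))),
                   exp(-(cz - ctr[3])^2 / (2 * s^2))) * runif(1, 0.5, 2)
  }
  v[c(1:3, dims[1] - 2:0), , ] <- 0
  v[, c(1:3, dims[2] - 2:0), ] <- 0
  v[, , c(1:3, dims[3] - 2:0)] <- 0
  voxel_grid(v, origin, sp)
}

# dense trilinear quadrature along a segment (independent oracle)
dense_line_integral <- function(grid, p0, p1, n = 10000) {
  t <- (seq_len(n) - 0.5) / n
  pts <- outer(1 - t, p0) + outer(t, p1)
  mean(petalign:::interp3(grid, pts)) * sqrt(sum((p1 - p0)^2))
}

# 4-block single-ring toy scanner
toy_scanner <- function() cylindrical_blueprint(4, 1, 30, c(20, 10, 20))

# 6-block ring used for simulator statistics
ring6 <- function() cylindrical_blueprint(6, 1, 40, c(24, 10, 24))

# small off-center point phantom inside a given transaxial radius
toy_points <- function(n = 3, radius = 8, half_z = 4, r_src = 0.4,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  phantom_points(cbind(r * cos(th), r * sin(th), runif(n, -half_z, half_z)),
                 radii = r_src)
}
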
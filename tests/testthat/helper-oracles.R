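# Independent oracles and fixture builders shared across the suite.
# All fixtures are generated in code; nothing is read from disk.

# Exhaustive point-to-segment rasterization oracle: counts (and optionally
# returns) every voxel of a volume whose centre lies within `radius` of the
# segment center +/- halfLength * dir. Deliberately brute force over the full
# voxel grid, independent of the package's chunked bounding-box rasterizer.
oracleCylinderMask <- function(shape, center, dir, radius, halfLength) {
  co <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                              z = seq_len(shape[3])))
  p1 <- center - halfLength * dir
  rel <- sweep(co, 2, p1)
  t <- pmin(pmax(rel %*% dir, 0), 2 * halfLength)
  d2 <- rowSums((rel - t %*% t(dir))^2)
  mask <- array(FALSE, dim = shape)
  mask[co[d2 <= radius^2, , drop = FALSE]] <- TRUE
  mask
}

# 1D squared-distance transform (lower-envelope algorithm); helper for the
# separable exact Euclidean distance transform below.
dt1dSquared <- function(f) {
  n <- length(f)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  if (n > 1) for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (k > 1 && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Exact Euclidean distance (voxels) from every voxel to the nearest
# background (FALSE) voxel of a logical volume.
oracleEDT <- function(b) {
  BIG <- 1e12
  d <- array(ifelse(b, BIG, 0), dim = dim(b))
  dm <- dim(d)
  for (y in seq_len(dm[2])) for (z in seq_len(dm[3]))
    d[, y, z] <- dt1dSquared(d[, y, z])
  for (x in seq_len(dm[1])) for (z in seq_len(dm[3]))
    d[x, , z] <- dt1dSquared(d[x, , z])
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2]))
    d[x, y, ] <- dt1dSquared(d[x, y, ])
  sqrt(d)
}

# Analytic oriented stripe image: intensity constant along the direction
# alphaDeg, sinusoidal across it.
stripeImage <- function(n, alphaDeg, period = 8) {
  a <- alphaDeg * pi / 180
  x <- matrix(seq_len(n), n, n)
  y <- matrix(seq_len(n), n, n, byrow = TRUE)
  sin(2 * pi * (-x * sin(a) + y * cos(a)) / period)
}

# Small phantom builders used by several files.
alignedConfig <- function(side, nFibers, seed, diameter = c(3, 20),
                          theta = 27, phi = 15) {
  simulationConfig(volumeShape = rep(as.integer(side), 3),
                   nFibersRange = nFibers,
                   azimuthRangeDeg = c(theta, theta),
                   elevationRangeDeg = c(phi, phi),
                   diameterRangeVox = diameter, rngSeed = as.integer(seed))
}

# A solid axis cylinder through the volume centre, plus its true axis voxels.
centeredCylinder <- function(side, thetaDeg, phiDeg, diameterVox, lengthVox) {
  fibramorph:::.singleFiberVolume(side, thetaDeg, phiDeg, diameterVox,
                                  lengthVox)
}

# Tiny hand-built phantom: one pre-labelled voxel block with given angles,
# for exercising angularError on constructed orientation fields.
tinyPhantom <- function(thetaDeg, phiDeg) {
  lab <- array(0L, dim = c(8L, 8L, 8L))
  lab[3:6, 4, 4] <- 1L
  fib <- data.frame(label = 1L, theta_deg = thetaDeg, phi_deg = phiDeg,
                    diameter_vox = 1, length_vox = 4,
                    seed_x = 4.5, seed_y = 4, seed_z = 4,
                    dir_x = NA_real_, dir_y = NA_real_, dir_z = NA_real_)
  new("FiberPhantom", volume = array(as.integer(lab > 0), dim = dim(lab)),
      labels = lab, fibers = fib,
      config = simulationConfig(volumeShape = c(8L, 8L, 8L)))
}

orientationFieldAt <- function(coords, thetaDeg, phiDeg, window = 32) {
  new("OrientationField", coords = coords,
      thetaDeg = rep_len(thetaDeg, nrow(coords)),
      phiDeg = rep_len(phiDeg, nrow(coords)),
      windowVox = window, gradientSigmaVox = 1, diagnostics = list())
}
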
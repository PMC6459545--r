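#' @include utils.R
NULL

# Voxelize a solid cylinder: all voxel centres within `radius` of the axis
# segment centre +/- halfLength * dir (<= comparison, boundary included).
# Works in axial chunks so the candidate bounding box stays small. Returns
# the in-volume voxel coordinates plus candidate-voxel counts (including
# voxels falling outside the volume, needed for the rejection rule).
.cylinderVoxels <- function(shape, center, dir, radius, halfLength,
                            chunkLen = 24) {
  L <- 2 * halfLength
  c1 <- center - halfLength * dir
  nChunks <- max(1L, ceiling(L / chunkLen))
  breaks <- seq(0, L, length.out = nChunks + 1)
  coords <- vector("list", nChunks)
  nTotal <- 0L
  nOutside <- 0L
  pad <- radius + 1
  for (k in seq_len(nChunks)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    p0 <- c1 + t0 * dir; p1 <- c1 + t1 * dir
    lo <- floor(pmin(p0, p1) - pad)
    hi <- ceiling(pmax(p0, p1) + pad)
    xs <- seq.int(lo[1], hi[1]); ys <- seq.int(lo[2], hi[2])
    zs <- seq.int(lo[3], hi[3])
    nx <- length(xs); ny <- length(ys); nz <- length(zs)
    px <- rep.int(xs, ny * nz) - c1[1]
    py <- rep.int(rep(ys, each = nx), nz) - c1[2]
    pz <- rep(zs, each = nx * ny) - c1[3]
    tt <- pmin(pmax(px * dir[1] + py * dir[2] + pz * dir[3], 0), L)
    d2 <- (px - tt * dir[1])^2 + (py - tt * dir[2])^2 + (pz - tt * dir[3])^2
    # assign each voxel to exactly one chunk by its clamped axial parameter
    inChunk <- d2 <= radius^2 & tt >= t0 &
      (if (k == nChunks) tt <= t1 else tt < t1)
    if (!any(inChunk)) next
    cx <- px[inChunk] + c1[1]; cy <- py[inChunk] + c1[2]
    cz <- pz[inChunk] + c1[3]
    nTotal <- nTotal + sum(inChunk)
    inVol <- cx >= 1 & cx <= shape[1] & cy >= 1 & cy <= shape[2] &
      cz >= 1 & cz <= shape[3]
    nOutside <- nOutside + sum(!inVol)
    if (any(inVol))
      coords[[k]] <- cbind(as.integer(cx[inVol]), as.integer(cy[inVol]),
                           as.integer(cz[inVol]))
  }
  list(coords = do.call(rbind, coords), nTotal = nTotal, nOutside = nOutside)
}

#' Generate a synthetic fiber phantom
#'
#' Rasterizes straight cylindrical fibers into a 3D volume. Each candidate
#' fiber is drawn by sampling azimuth/elevation angles, a diameter, a length
#' fraction of the minimum side, a gap and a uniformly placed midpoint; it is
#' rasterized as a solid cylinder (a filled circular profile propagated along
#' the fiber axis). A candidate is rejected -- and counted as a failed
#' attempt -- when more than `outsideFractionThreshold` of its voxels fall
#' outside the volume, or (for `allowIntersections = FALSE`) when the
#' cylinder dilated by the sampled gap touches any previously placed fiber.
#' Generation halts on the configured stop rule, or unconditionally after
#' `maxFailedAttempts` rejections.
#'
#' @param config a [SimulationConfig-class], see [simulationConfig()].
#' @return a [FiberPhantom-class] with the binary volume, label volume and
#'   ground-truth fiber table. Fully reproducible from `config@rngSeed`.
#' @examples
#' cfg <- simulationConfig(volumeShape = c(64, 64, 64), nFibersRange = c(3, 5),
#'                         diameterRangeVox = c(3, 6), rngSeed = 7L)
#' ph <- simulateFibers(cfg)
#' fiberTable(ph)
#' @export
simulateFibers <- function(config) {
  validObject(config)
  shape <- config@volumeShape
  if (any(shape < 8)) stop("each volume dimension must be >= 8")
  .withSeed(config@rngSeed, {
    labels <- array(0L, dim = shape)
    minSide <- min(shape)
    fibers <- list()
    failures <- 0L
    targetN <- if (config@stopRule == "max_fibers") {
      if (!is.na(config@stopParam)) config@stopParam
      else {
        r <- round(config@nFibersRange)
        s <- seq.int(r[1], r[2]) # guard against sample()'s scalar behaviour
        s[sample.int(length(s), 1L)]
      }
    } else Inf
    failCap <- if (config@stopRule == "max_failed_attempts")
      config@stopParam else config@maxFailedAttempts
    repeat {
      if (length(fibers) >= targetN) break
      if (config@stopRule == "volume_fraction" &&
          mean(labels > 0) >= config@stopParam) break
      if (failures >= failCap) break
      theta <- runif(1, config@azimuthRangeDeg[1], config@azimuthRangeDeg[2])
      phi <- runif(1, config@elevationRangeDeg[1], config@elevationRangeDeg[2])
      diam <- runif(1, config@diameterRangeVox[1], config@diameterRangeVox[2])
      lfrac <- runif(1, config@lengthFractionRange[1],
                     config@lengthFractionRange[2])
      gap <- runif(1, config@gapRangeVox[1], config@gapRangeVox[2])
      center <- runif(3, min = 1, max = shape)
      dir <- as.numeric(anglesToVector(theta, phi))
      ang <- vectorToAngles(dir) # canonical angle representative
      len <- lfrac * minSide
      ras <- .cylinderVoxels(shape, center, dir, diam / 2, len / 2)
      if (ras$nTotal == 0L || ras$nOutside / ras$nTotal >
            config@outsideFractionThreshold || is.null(ras$coords)) {
        failures <- failures + 1L
        next
      }
      if (!config@allowIntersections) {
        dil <- .cylinderVoxels(shape, center, dir, diam / 2 + gap,
                               len / 2 + gap)
        if (!is.null(dil$coords) && any(labels[dil$coords] > 0L)) {
          failures <- failures + 1L
          next
        }
      }
      lab <- length(fibers) + 1L
      labels[ras$coords] <- lab
      fibers[[lab]] <- data.frame(
        label = lab, theta_deg = ang[1], phi_deg = ang[2],
        diameter_vox = diam, length_vox = len,
        seed_x = center[1], seed_y = center[2], seed_z = center[3],
        dir_x = dir[1], dir_y = dir[2], dir_z = dir[3])
    }
    if (!length(fibers))
      warning("no fibers could be placed; phantom is empty")
    fibers <- if (length(fibers)) do.call(rbind, fibers) else
      data.frame(label = integer(), theta_deg = numeric(),
                 phi_deg = numeric(), diameter_vox = numeric(),
                 length_vox = numeric(), seed_x = numeric(),
                 seed_y = numeric(), seed_z = numeric(), dir_x = numeric(),
                 dir_y = numeric(), dir_z = numeric())
    new("FiberPhantom", volume = array(as.integer(labels > 0L), dim = shape),
        labels = labels, fibers = fibers, config = config)
  })
}

#' Contaminate a volume with noise and smoothing
#'
#' Adds independent additive Gaussian noise per voxel, then convolves with an
#' isotropic Gaussian filter -- the standard degradation model for phantom
#' robustness studies (noise first, smoothing second).
#'
#' @param vol 3D numeric array (a binary phantom volume is float-cast).
#' @param sigmaAgn standard deviation of the additive Gaussian noise; `0`
#'   skips the noise step.
#' @param sigmaSmooth standard deviation of the Gaussian smoothing filter;
#'   `0` skips smoothing.
#' @param rngSeed integer seed for the noise; `NULL` uses the current RNG
#'   state.
#' @return numeric array of the same dimensions.
#' @export
contaminateVolume <- function(vol, sigmaAgn, sigmaSmooth, rngSeed = NULL) {
  .assertVolume(vol)
  if (sigmaAgn < 0 || sigmaSmooth < 0)
    stop("sigmaAgn and sigmaSmooth must be >= 0")
  v <- vol + 0 # float cast
  if (sigmaAgn > 0)
    v <- .withSeed(rngSeed,
                   v + array(rnorm(length(v), sd = sigmaAgn), dim = dim(v)))
  if (sigmaSmooth > 0) v <- gaussianSmooth3D(v, sigmaSmooth)
  v
}
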
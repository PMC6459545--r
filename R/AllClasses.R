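#' @include fibramorph-package.R
NULL

.checkRange <- function(r, what, lo = -Inf, hi = Inf) {
  if (length(r) != 2 || any(!is.finite(r)))
    return(sprintf("%s must be two finite numbers", what))
  if (r[1] > r[2]) return(sprintf("%s must satisfy lo <= hi", what))
  if (r[1] < lo || r[2] > hi)
    return(sprintf("%s must lie within [%g, %g]", what, lo, hi))
  NULL
}

#' Simulation configuration for synthetic fiber phantoms
#'
#' Holds the sampling ranges and stop rule used by [simulateFibers()]. All
#' linear quantities are in voxels; angles in degrees. Defaults follow the
#' disordered electrospun-scaffold regime: fiber diameters 3--20 voxels,
#' inter-fiber gaps 3--10 voxels, fiber lengths 20--80% of the minimum side
#' length, azimuth -89..90 degrees, elevation 0..90 degrees, and a rejection
#' threshold of 50% for candidate fibers extending outside the volume.
#'
#' @slot volumeShape integer(3), volume dimensions (nx, ny, nz).
#' @slot nFibersRange numeric(2), range the target fiber count is drawn from
#'   when `stopRule == "max_fibers"` and `stopParam` is `NA`.
#' @slot azimuthRangeDeg numeric(2) within \[-90, 90\].
#' @slot elevationRangeDeg numeric(2) within \[0, 90\].
#' @slot diameterRangeVox numeric(2), each >= 1.
#' @slot lengthFractionRange numeric(2) in (0, 1\], fractions of the minimum
#'   side length.
#' @slot gapRangeVox numeric(2), each >= 0; a gap is drawn per candidate
#'   fiber and enforced against all previously placed fibers.
#' @slot outsideFractionThreshold numeric(1) in \[0, 1\]; candidates with a
#'   larger fraction of their voxels outside the volume are rejected.
#' @slot stopRule one of `"max_fibers"`, `"volume_fraction"`,
#'   `"max_failed_attempts"`.
#' @slot stopParam numeric parameter of the stop rule (`NA` to sample the
#'   fiber count from `nFibersRange`).
#' @slot allowIntersections logical; if `FALSE` the per-fiber gap is enforced.
#' @slot maxFailedAttempts numeric(1), secondary stop: generation always halts
#'   after this many rejected candidates.
#' @slot rngSeed integer seed; the phantom is fully reproducible from it.
#' @seealso [simulationConfig()], [simulateFibers()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    volumeShape = "integer",
    nFibersRange = "numeric",
    azimuthRangeDeg = "numeric",
    elevationRangeDeg = "numeric",
    diameterRangeVox = "numeric",
    lengthFractionRange = "numeric",
    gapRangeVox = "numeric",
    outsideFractionThreshold = "numeric",
    stopRule = "character",
    stopParam = "numeric",
    allowIntersections = "logical",
    maxFailedAttempts = "numeric",
    rngSeed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  errs <- c(
    if (length(object@volumeShape) != 3 || any(object@volumeShape < 1))
      "volumeShape must be 3 positive integers",
    .checkRange(object@nFibersRange, "nFibersRange", 0),
    .checkRange(object@azimuthRangeDeg, "azimuthRangeDeg", -90, 90),
    .checkRange(object@elevationRangeDeg, "elevationRangeDeg", 0, 90),
    .checkRange(object@diameterRangeVox, "diameterRangeVox", 1),
    .checkRange(object@lengthFractionRange, "lengthFractionRange", 0, 1),
    .checkRange(object@gapRangeVox, "gapRangeVox", 0),
    if (object@outsideFractionThreshold < 0 || object@outsideFractionThreshold > 1)
      "outsideFractionThreshold must be in [0, 1]",
    if (!object@stopRule %in% c("max_fibers", "volume_fraction",
                                "max_failed_attempts"))
      "stopRule must be one of max_fibers, volume_fraction, max_failed_attempts",
    if (object@maxFailedAttempts < 1)
      "maxFailedAttempts must be >= 1"
  )
  if (length(errs)) errs else TRUE
})

#' @describeIn SimulationConfig constructor with the default phantom regime.
#' @param volumeShape,nFibersRange,azimuthRangeDeg,elevationRangeDeg
#'   see slots.
#' @param diameterRangeVox,lengthFractionRange,gapRangeVox,outsideFractionThreshold
#'   see slots.
#' @param stopRule,stopParam,allowIntersections,maxFailedAttempts,rngSeed
#'   see slots.
#' @return a validated `SimulationConfig`.
#' @export
simulationConfig <- function(volumeShape = c(512L, 512L, 512L),
                             nFibersRange = c(20, 100),
                             azimuthRangeDeg = c(-89, 90),
                             elevationRangeDeg = c(0, 90),
                             diameterRangeVox = c(3, 20),
                             lengthFractionRange = c(0.2, 0.8),
                             gapRangeVox = c(3, 10),
                             outsideFractionThreshold = 0.5,
                             stopRule = c("max_fibers", "volume_fraction",
                                          "max_failed_attempts"),
                             stopParam = NA_real_,
                             allowIntersections = FALSE,
                             maxFailedAttempts = 100,
                             rngSeed = 1L) {
  stopRule <- match.arg(stopRule)
  new("SimulationConfig",
      volumeShape = as.integer(volumeShape),
      nFibersRange = as.numeric(nFibersRange),
      azimuthRangeDeg = as.numeric(azimuthRangeDeg),
      elevationRangeDeg = as.numeric(elevationRangeDeg),
      diameterRangeVox = as.numeric(diameterRangeVox),
      lengthFractionRange = as.numeric(lengthFractionRange),
      gapRangeVox = as.numeric(gapRangeVox),
      outsideFractionThreshold = as.numeric(outsideFractionThreshold),
      stopRule = stopRule,
      stopParam = as.numeric(stopParam),
      allowIntersections = isTRUE(allowIntersections),
      maxFailedAttempts = as.numeric(maxFailedAttempts),
      rngSeed = as.integer(rngSeed))
}

#' Synthetic fiber phantom with ground truth
#'
#' A binary volume of rasterized straight cylindrical fibers together with an
#' integer label volume (0 = background, label k = fiber k) and the per-fiber
#' ground-truth table.
#'
#' @slot volume integer 3D array, 0/1 foreground mask.
#' @slot labels integer 3D array, 0 background, fiber labels 1..n.
#' @slot fibers data.frame with one row per fiber: `label`, `theta_deg`,
#'   `phi_deg`, `diameter_vox`, `length_vox`, `seed_x`, `seed_y`, `seed_z`,
#'   `dir_x`, `dir_y`, `dir_z` (unit axis vector).
#' @slot config the [SimulationConfig-class] the phantom was generated from.
#' @seealso [simulateFibers()], [phantomVolume()], [fiberTable()]
#' @exportClass FiberPhantom
setClass("FiberPhantom",
  representation(volume = "array", labels = "array", fibers = "data.frame",
                 config = "SimulationConfig"))

setValidity("FiberPhantom", function(object) {
  errs <- c(
    if (!identical(dim(object@volume), dim(object@labels)))
      "volume and labels must have identical dimensions",
    if (any((object@labels > 0) != (object@volume > 0)))
      "nonzero labels and foreground voxels must coincide",
    if (nrow(object@fibers) &&
        !all(unique(object@labels[object@labels > 0]) %in%
             object@fibers$label))
      "every label value must appear in the fiber table"
  )
  if (length(errs)) errs else TRUE
})

#' One-voxel-thick medial-axis skeleton of a binary volume
#'
#' @slot skeleton logical 3D array; `TRUE` voxels form the curve skeleton.
#' @slot sourceDim integer(3), dimensions of the binary volume it came from.
#' @seealso [skeletonize3D()]
#' @exportClass SkeletonVolume
setClass("SkeletonVolume",
  representation(skeleton = "array", sourceDim = "integer"))

setValidity("SkeletonVolume", function(object) {
  if (!is.logical(object@skeleton)) return("skeleton must be a logical array")
  if (!identical(dim(object@skeleton), object@sourceDim))
    return("skeleton dimensions must match sourceDim")
  TRUE
})

#' Sparse per-voxel fiber orientation field
#'
#' Maps skeleton voxels to estimated azimuth/elevation angles; produced by
#' [estimateTensorOrientation()].
#'
#' @slot coords integer matrix (n x 3) of 1-based `x,y,z` voxel coordinates.
#' @slot thetaDeg numeric azimuth in (-90, 90\] degrees.
#' @slot phiDeg numeric elevation in \[0, 90\] degrees.
#' @slot windowVox side length of the cubic averaging window (voxels).
#' @slot gradientSigmaVox sigma of the Gaussian-derivative gradient filter.
#' @slot diagnostics list of counters (skeleton voxels seen, flat-tensor and
#'   eigenvalue-tie omissions).
#' @exportClass OrientationField
setClass("OrientationField",
  representation(coords = "matrix", thetaDeg = "numeric", phiDeg = "numeric",
                 windowVox = "numeric", gradientSigmaVox = "numeric",
                 diagnostics = "list"))

setValidity("OrientationField", function(object) {
  n <- nrow(object@coords)
  errs <- c(
    if (ncol(object@coords) != 3) "coords must have 3 columns",
    if (length(object@thetaDeg) != n || length(object@phiDeg) != n)
      "angle vectors must match the number of coordinates",
    if (n && (any(object@thetaDeg <= -90 - 1e-9) ||
              any(object@thetaDeg > 90 + 1e-9)))
      "thetaDeg must be in (-90, 90]",
    if (n && (any(object@phiDeg < -1e-9) || any(object@phiDeg > 90 + 1e-9)))
      "phiDeg must be in [0, 90]"
  )
  if (length(errs)) errs else TRUE
})

#' Sparse per-voxel fiber diameter field
#'
#' Produced by [estimateDiameter()]; one entry per oriented skeleton voxel for
#' which at least one opposite-ray pair terminated inside the volume.
#'
#' @slot coords integer matrix (n x 3) of `x,y,z` voxel coordinates.
#' @slot diameterVox numeric estimated diameters (voxels), >= 1 by convention
#'   (a foreground medial voxel occupies at least its own voxel).
#' @slot censored logical; `TRUE` where a contributing ray was stopped at the
#'   marching limit, so the value is a lower bound.
#' @slot nRays,stepVox ray-casting parameters used.
#' @slot diagnostics list of counters (inputs, off-foreground skips,
#'   no-valid-pair skips).
#' @exportClass DiameterField
setClass("DiameterField",
  representation(coords = "matrix", diameterVox = "numeric",
                 censored = "logical", nRays = "numeric", stepVox = "numeric",
                 diagnostics = "list"))

setValidity("DiameterField", function(object) {
  n <- nrow(object@coords)
  errs <- c(
    if (ncol(object@coords) != 3) "coords must have 3 columns",
    if (length(object@diameterVox) != n || length(object@censored) != n)
      "diameterVox and censored must match the number of coordinates"
  )
  if (length(errs)) errs else TRUE
})

# ---- accessors ----

#' @export
setGeneric("phantomVolume", function(x) standardGeneric("phantomVolume"))
#' @export
setGeneric("phantomLabels", function(x) standardGeneric("phantomLabels"))
#' @export
setGeneric("fiberTable", function(x) standardGeneric("fiberTable"))
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))
#' @export
setGeneric("skeletonMask", function(x) standardGeneric("skeletonMask"))
#' @export
setGeneric("orientationTable", function(x) standardGeneric("orientationTable"))
#' @export
setGeneric("diameterTable", function(x) standardGeneric("diameterTable"))

#' @describeIn FiberPhantom the binary 0/1 volume.
#' @param x object.
#' @aliases phantomVolume
#' @export
setMethod("phantomVolume", "FiberPhantom", function(x) x@volume)

#' @describeIn FiberPhantom the integer label volume.
#' @aliases phantomLabels
#' @export
setMethod("phantomLabels", "FiberPhantom", function(x) x@labels)

#' @describeIn FiberPhantom the ground-truth fiber table.
#' @aliases fiberTable
#' @export
setMethod("fiberTable", "FiberPhantom", function(x) x@fibers)

#' @describeIn FiberPhantom the generating configuration.
#' @aliases simConfig
#' @export
setMethod("simConfig", "FiberPhantom", function(x) x@config)

#' @describeIn SkeletonVolume the logical skeleton array.
#' @param x object.
#' @aliases skeletonMask
#' @export
setMethod("skeletonMask", "SkeletonVolume", function(x) x@skeleton)

#' @describeIn OrientationField orientation entries as a data.frame with
#'   columns `x,y,z,theta_deg,phi_deg`.
#' @param x object.
#' @aliases orientationTable
#' @export
setMethod("orientationTable", "OrientationField", function(x) {
  data.frame(x = x@coords[, 1], y = x@coords[, 2], z = x@coords[, 3],
             theta_deg = x@thetaDeg, phi_deg = x@phiDeg)
})

#' @describeIn DiameterField diameter entries as a data.frame with columns
#'   `x,y,z,diameter_vox,censored`.
#' @param x object.
#' @aliases diameterTable
#' @export
setMethod("diameterTable", "DiameterField", function(x) {
  data.frame(x = x@coords[, 1], y = x@coords[, 2], z = x@coords[, 3],
             diameter_vox = x@diameterVox, censored = x@censored)
})

# ---- show methods ----

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  volume      : %s voxels\n",
              paste(object@volumeShape, collapse = " x ")))
  cat(sprintf("  fibers      : %g-%g, azimuth [%g, %g] deg, elevation [%g, %g] deg\n",
              object@nFibersRange[1], object@nFibersRange[2],
              object@azimuthRangeDeg[1], object@azimuthRangeDeg[2],
              object@elevationRangeDeg[1], object@elevationRangeDeg[2]))
  cat(sprintf("  diameter    : [%g, %g] vox, gap [%g, %g] vox, length [%g, %g] of min side\n",
              object@diameterRangeVox[1], object@diameterRangeVox[2],
              object@gapRangeVox[1], object@gapRangeVox[2],
              object@lengthFractionRange[1], object@lengthFractionRange[2]))
  cat(sprintf("  stop rule   : %s (param %s), max failed attempts %g\n",
              object@stopRule,
              ifelse(is.na(object@stopParam), "auto", object@stopParam),
              object@maxFailedAttempts))
  cat(sprintf("  seed        : %d\n", object@rngSeed))
})

setMethod("show", "FiberPhantom", function(object) {
  d <- dim(object@volume)
  cat(sprintf("FiberPhantom: %d fibers in a %s volume (%.2f%% foreground)\n",
              nrow(object@fibers), paste(d, collapse = " x "),
              100 * mean(object@volume > 0)))
})

setMethod("show", "SkeletonVolume", function(object) {
  cat(sprintf("SkeletonVolume: %d skeleton voxels in a %s volume\n",
              sum(object@skeleton), paste(object@sourceDim, collapse = " x ")))
})

setMethod("show", "OrientationField", function(object) {
  cat(sprintf(
    "OrientationField: %d voxels (window %g, gradient sigma %g)\n",
    nrow(object@coords), object@windowVox, object@gradientSigmaVox))
})

setMethod("show", "DiameterField", function(object) {
  cat(sprintf(
    "DiameterField: %d voxels (%d rays, step %g vox), %d censored\n",
    nrow(object@coords), as.integer(object@nRays), object@stepVox,
    sum(object@censored)))
})
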
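#' @include utils.R
NULL

.azimuthDistance <- function(a, b) {
  d <- abs(a - b)
  pmin(d, 180 - d)
}

# Angle (degrees) between two headless axes given as (theta, phi) pairs.
# The (theta, phi) convention folds the sign of z (phi = asin(|z|)), so each
# pair represents an axis up to a z-mirror; the metric quotients over that
# fold by taking the smaller angle of the two representatives.
.axisAngle <- function(theta1, phi1, theta2, phi2) {
  v1 <- anglesToVector(theta1, phi1)
  v2 <- anglesToVector(theta2, phi2)
  if (!is.matrix(v1)) v1 <- matrix(v1, ncol = 3)
  if (!is.matrix(v2)) v2 <- matrix(v2, ncol = 3)
  if (nrow(v2) == 1 && nrow(v1) > 1) v2 <- v2[rep(1, nrow(v1)), , drop = FALSE]
  if (nrow(v1) == 1 && nrow(v2) > 1) v1 <- v1[rep(1, nrow(v2)), , drop = FALSE]
  dPlus <- abs(rowSums(v1 * v2))
  dMinus <- abs(v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2] - v1[, 3] * v2[, 3])
  acos(pmin(1, pmax(dPlus, dMinus))) * 180 / pi
}

#' Angular error of an orientation estimate against phantom ground truth
#'
#' Each estimated skeleton voxel is assigned the ground-truth angles of the
#' fiber whose label it carries in the phantom label volume (falling back to
#' the nearest labeled voxel when skeletonization of a contaminated volume
#' drifts off the true fiber; the small default radius keeps the fallback to
#' genuine drift, so spurious skeleton voxels far from any fiber -- e.g.
#' segmented noise speckle -- are excluded from the summary and counted as
#' unmatched). The azimuth error is wraparound-aware,
#' `min(|dtheta|, 180 - |dtheta|)`; the elevation error is `|dphi|`. Errors
#' are summarised as mean and standard deviation over all evaluated voxels.
#'
#' @param estimated an [OrientationField-class].
#' @param phantom the [FiberPhantom-class] the volume came from.
#' @param maxMatchRadius search radius (voxels) for the nearest labeled voxel.
#' @return one-row data.frame: `mean_azimuth_err_deg`, `std_azimuth_err_deg`,
#'   `mean_elevation_err_deg`, `std_elevation_err_deg`, `n_points`,
#'   `n_unmatched`.
#' @export
angularError <- function(estimated, phantom, maxMatchRadius = 3) {
  if (!is(estimated, "OrientationField"))
    stop("estimated must be an OrientationField")
  if (!is(phantom, "FiberPhantom")) stop("phantom must be a FiberPhantom")
  if (!nrow(estimated@coords)) stop("empty orientation field")
  lab <- cpp_nearest_label(phantomLabels(phantom), dim(phantomLabels(phantom)),
                           matrix(as.integer(estimated@coords), ncol = 3),
                           as.integer(maxMatchRadius))
  fib <- fiberTable(phantom)
  m <- match(lab, fib$label)
  ok <- !is.na(m)
  azErr <- .azimuthDistance(estimated@thetaDeg[ok], fib$theta_deg[m[ok]])
  elErr <- abs(estimated@phiDeg[ok] - fib$phi_deg[m[ok]])
  data.frame(mean_azimuth_err_deg = mean(azErr),
             std_azimuth_err_deg = stats::sd(azErr),
             mean_elevation_err_deg = mean(elErr),
             std_elevation_err_deg = stats::sd(elErr),
             n_points = sum(ok), n_unmatched = sum(!ok))
}

#' Window-size sweep of the tensor orientation estimator
#'
#' Re-estimates orientation on the clean phantom for each window size and
#' summarises the angular error against ground truth; used to locate the
#' error plateau that fixes the default window.
#'
#' @param phantom a [FiberPhantom-class].
#' @param windows ascending integer window sizes; windows larger than the
#'   minimum side are skipped with a warning.
#' @param gradientSigmaVox gradient filter sigma.
#' @return data.frame with a `window` column plus the [angularError()]
#'   summary per window.
#' @export
windowSweep <- function(phantom, windows, gradientSigmaVox = 1.0) {
  if (is.unsorted(windows)) stop("windows must be sorted ascending")
  keep <- windows <= min(dim(phantomVolume(phantom)))
  if (any(!keep))
    warning("skipping windows larger than the minimum side: ",
            paste(windows[!keep], collapse = ", "))
  sk <- skeletonize3D(phantomVolume(phantom))
  do.call(rbind, lapply(windows[keep], function(w) {
    est <- estimateTensorOrientation(phantomVolume(phantom), sk,
                                     windowVox = w,
                                     gradientSigmaVox = gradientSigmaVox)
    cbind(window = w, angularError(est, phantom))
  }))
}

#' Noise sweep of the tensor orientation estimator
#'
#' For each noise level the phantom volume is contaminated (additive Gaussian
#' noise, then Gaussian smoothing), re-segmented with the Otsu threshold,
#' skeletonized, and orientation is re-estimated; the angular error is
#' summarised against ground truth. A level where segmentation fails is
#' flagged rather than fatal.
#'
#' @param phantom a [FiberPhantom-class].
#' @param sigmas ascending noise standard deviations.
#' @param sigmaSmooth smoothing filter sigma applied after the noise.
#' @param rngSeed integer seed; level i uses `rngSeed + i - 1`.
#' @param windowVox tensor window size.
#' @param matchRadius ground-truth match radius passed to [angularError()].
#'   The sweep default (10 voxels, the maximum fiber radius of the default
#'   phantom regime) follows the protocol of summarising over all estimated
#'   medial-axis points, attributing each to its nearest fiber: under heavy
#'   noise the segmentation admits spurious structures near fiber surfaces,
#'   and their misestimates are part of the measured degradation. A small
#'   radius would instead restrict the summary to the true skeleton and
#'   report an almost flat noise response.
#' @return data.frame with `sigma_agn` and `flagged` columns plus the
#'   [angularError()] summary per level (NA rows where flagged). The
#'   segmentation and pipeline order are recorded in attribute `"pipeline"`.
#' @export
noiseSweep <- function(phantom, sigmas, sigmaSmooth = 1.0, rngSeed = 1L,
                       windowVox = 32, matchRadius = 10) {
  if (is.unsorted(sigmas)) stop("sigmas must be sorted ascending")
  rows <- lapply(seq_along(sigmas), function(i) {
    v <- contaminateVolume(phantomVolume(phantom), sigmas[i], sigmaSmooth,
                           rngSeed = rngSeed + i - 1L)
    res <- tryCatch({
      b <- binarizeVolume(v, "otsu")
      if (!any(b)) stop("empty segmentation")
      sk <- skeletonize3D(b)
      est <- estimateTensorOrientation(b + 0, sk, windowVox = windowVox)
      cbind(sigma_agn = sigmas[i], flagged = FALSE,
            angularError(est, phantom, maxMatchRadius = matchRadius))
    }, error = function(e) {
      data.frame(sigma_agn = sigmas[i], flagged = TRUE,
                 mean_azimuth_err_deg = NA_real_,
                 std_azimuth_err_deg = NA_real_,
                 mean_elevation_err_deg = NA_real_,
                 std_elevation_err_deg = NA_real_,
                 n_points = 0L, n_unmatched = 0L)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "pipeline") <-
    "contaminate -> otsu binarize -> skeletonize -> tensor orientation (binary volume)"
  out
}

# Rasterize one fiber of known orientation through the volume centre.
.singleFiberVolume <- function(side, thetaDeg, phiDeg, diameterVox,
                               lengthVox) {
  shape <- rep(as.integer(side), 3)
  dir <- as.numeric(anglesToVector(thetaDeg, phiDeg))
  ras <- .cylinderVoxels(shape, (shape + 1) / 2, dir, diameterVox / 2,
                         lengthVox / 2)
  vol <- array(FALSE, dim = shape)
  if (!is.null(ras$coords)) vol[ras$coords] <- TRUE
  vol
}

#' Angular-range error scan on single-fiber phantoms
#'
#' Maps the error-prone angular zones of the tensor estimator: for each
#' (theta, phi) cell on a regular grid over theta in \[-90, 90\], phi in
#' \[0, 90\], a small single-fiber phantom at that orientation is generated,
#' skeletonized and estimated, and the per-cell error is recorded. The
#' headline `max_axis_err_deg` is the wraparound-aware angle between the
#' estimated and true fiber axes, which stays well-defined at the elevation
#' pole where azimuth degenerates; raw azimuth/elevation errors are reported
#' alongside.
#'
#' @param stepDeg grid step; must divide 180 and 90.
#' @param windowVox tensor window size.
#' @param side cube side of each single-fiber phantom.
#' @param diameterVox,lengthVox fiber geometry (length defaults to 75% of the
#'   side).
#' @return data.frame with columns `theta_deg`, `phi_deg`,
#'   `max_axis_err_deg`, `mean_axis_err_deg`, `max_azimuth_err_deg`,
#'   `max_elevation_err_deg`, `n_points`.
#' @export
angularRangeScan <- function(stepDeg = 5, windowVox = 32, side = 64,
                             diameterVox = 9, lengthVox = NULL) {
  if (180 %% stepDeg != 0 || 90 %% stepDeg != 0)
    stop("stepDeg must divide both 180 and 90")
  if (is.null(lengthVox)) lengthVox <- 0.75 * side
  grid <- expand.grid(theta_deg = seq(-90, 90, by = stepDeg),
                      phi_deg = seq(0, 90, by = stepDeg))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    th <- grid$theta_deg[i]; ph <- grid$phi_deg[i]
    vol <- .singleFiberVolume(side, th, ph, diameterVox, lengthVox)
    sk <- skeletonize3D(vol)
    est <- estimateTensorOrientation(vol + 0, sk, windowVox = windowVox)
    n <- length(est@thetaDeg)
    if (!n)
      return(data.frame(theta_deg = th, phi_deg = ph,
                        max_axis_err_deg = NA_real_,
                        mean_axis_err_deg = NA_real_,
                        max_azimuth_err_deg = NA_real_,
                        max_elevation_err_deg = NA_real_, n_points = 0L))
    axErr <- .axisAngle(est@thetaDeg, est@phiDeg, th, ph)
    data.frame(theta_deg = th, phi_deg = ph,
               max_axis_err_deg = max(axErr),
               mean_axis_err_deg = mean(axErr),
               max_azimuth_err_deg = max(.azimuthDistance(est@thetaDeg, th)),
               max_elevation_err_deg = max(abs(est@phiDeg - ph)),
               n_points = n)
  })
  do.call(rbind, rows)
}
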
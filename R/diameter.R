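#' @include utils.R
NULL

#' Local fiber diameter by perpendicular ray casting
#'
#' At each oriented skeleton voxel an orthonormal basis `{u, v}` perpendicular
#' to the local fiber direction is built (`u = normalize(d x e)` with `e` the
#' coordinate axis least parallel to `d`, `v = d x u`), and `nRays` rays at
#' angles `2*pi*k/nRays` in the `{u, v}` plane are marched from the voxel
#' centre in increments of `stepVox`, sampling the binary volume by
#' nearest-voxel lookup until leaving foreground or exceeding
#' `maxMarchVox`. Opposite rays are paired; each pair's chord length is the
#' sum of the two marched distances (midpoint-corrected by half a step), and
#' the voxel's diameter is the mean over all pairs whose rays both terminated
#' inside the volume. Estimates are floored at 1 voxel: a foreground medial
#' voxel occupies at least its own voxel.
#'
#' Skeleton voxels off the foreground are skipped; voxels where every ray ran
#' to `maxMarchVox` are recorded as censored at that bound.
#'
#' @param vol binary 3D array.
#' @param orientation an [OrientationField-class] for the skeleton voxels.
#' @param nRays even number of rays >= 4.
#' @param stepVox marching step in voxels.
#' @param maxMarchVox marching limit; default half the maximum side length.
#' @return a [DiameterField-class].
#' @export
estimateDiameter <- function(vol, orientation, nRays = 16, stepVox = 0.5,
                             maxMarchVox = NULL) {
  b <- .asBinary(vol)
  if (!is(orientation, "OrientationField"))
    stop("orientation must be an OrientationField")
  if (nRays < 4 || nRays %% 2 != 0) stop("nRays must be even and >= 4")
  if (stepVox <= 0) stop("stepVox must be > 0")
  if (is.null(maxMarchVox)) maxMarchVox <- max(dim(b)) / 2
  n <- nrow(orientation@coords)
  if (!n)
    return(new("DiameterField", coords = matrix(integer(), 0, 3),
               diameterVox = numeric(), censored = logical(),
               nRays = nRays, stepVox = stepVox,
               diagnostics = list(nInput = 0L, nOffForeground = 0L,
                                  nNoPairs = 0L)))
  dirs <- anglesToVector(orientation@thetaDeg, orientation@phiDeg)
  if (!is.matrix(dirs)) dirs <- matrix(dirs, ncol = 3)
  res <- cpp_cast_rays(as.logical(b), dim(b),
                       matrix(as.numeric(orientation@coords), ncol = 3),
                       dirs, as.integer(nRays), stepVox, maxMarchVox)
  onFg <- res[, "on_fg"] > 0
  ok <- onFg & res[, "n_pairs"] > 0 & is.finite(res[, "diameter"])
  new("DiameterField",
      coords = orientation@coords[ok, , drop = FALSE],
      diameterVox = unname(pmax(res[ok, "diameter"], 1)),
      censored = unname(res[ok, "censored"] > 0),
      nRays = nRays, stepVox = stepVox,
      diagnostics = list(nInput = n, nOffForeground = sum(!onFg),
                         nNoPairs = sum(onFg & !ok)))
}
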
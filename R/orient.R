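#' @include utils.R
NULL

#' Convert axis vectors to azimuth/elevation angles
#'
#' Fiber axes are headless orientations, so each vector is first flipped to a
#' canonical sign (positive x; if x = 0, positive y), then azimuth
#' `theta = atan2(y, x)` and elevation `phi = asin(|z| / |v|)` are taken in
#' degrees. The result lies in theta in (-90, 90], phi in [0, 90]; `v` and
#' `-v` map to identical angles. Inverse of [anglesToVector()] on that range.
#'
#' @param v numeric vector of length 3, or an n x 3 matrix of row vectors.
#' @return numeric vector `c(theta_deg, phi_deg)`, or an n x 2 matrix.
#' @examples
#' vectorToAngles(c(1, 0, 0)) # c(0, 0)
#' vectorToAngles(c(0, 0, 1)) # c(0, 90)
#' @export
vectorToAngles <- function(v) {
  m <- if (is.matrix(v)) v else matrix(v, ncol = 3)
  if (ncol(m) != 3) stop("v must have 3 components")
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0) || any(!is.finite(nrm)))
    stop("zero or non-finite vector has no orientation")
  flip <- m[, 1] < 0 | (m[, 1] == 0 & m[, 2] < 0)
  m[flip, ] <- -m[flip, , drop = FALSE]
  theta <- atan2(m[, 2], m[, 1]) * 180 / pi
  phi <- asin(pmin(1, abs(m[, 3]) / nrm)) * 180 / pi
  degenerate <- m[, 1] == 0 & m[, 2] == 0
  theta[degenerate] <- 0
  out <- cbind(theta_deg = theta, phi_deg = phi)
  if (is.matrix(v)) out else c(out)
}

#' Convert azimuth/elevation angles to a unit axis vector
#'
#' The package-wide convention:
#' `v = (cos(phi) cos(theta), cos(phi) sin(theta), sin(phi))`, with azimuth
#' theta measured in the XY plane and elevation phi measured from the XY
#' plane (phi = 90 degrees points along Z).
#'
#' @param thetaDeg azimuth in degrees.
#' @param phiDeg elevation in degrees.
#' @return unit vector of length 3, or an n x 3 matrix for vector inputs.
#' @export
anglesToVector <- function(thetaDeg, phiDeg) {
  t <- thetaDeg * pi / 180
  p <- phiDeg * pi / 180
  out <- cbind(x = cos(p) * cos(t), y = cos(p) * sin(t), z = sin(p))
  if (length(thetaDeg) == 1 && length(phiDeg) == 1) c(out) else out
}

#' Per-voxel 3D fiber orientation from the structure tensor
#'
#' At every skeleton voxel, image gradients of the float-cast volume are
#' computed by Gaussian-derivative filtering, the 3 x 3 structure tensor
#' (average of gradient outer products) is formed over a cubic window of side
#' `windowVox` centred on the voxel (uniform weights; the window is clipped
#' at the volume border and averaged over its valid part), and the fiber
#' direction is taken as the unit eigenvector of the smallest eigenvalue:
#' gradients of a tubular structure are perpendicular to its axis, so the
#' axis is the direction of least gradient energy.
#'
#' Voxels with a vanishing tensor (flat neighbourhood) or a tie between the
#' two smallest eigenvalues (no well-defined axis) are omitted and counted in
#' the diagnostics.
#'
#' @param vol 3D numeric array (grayscale or binary).
#' @param skeleton a [SkeletonVolume-class] derived from `vol`, or a logical
#'   array of the same dimensions.
#' @param windowVox side of the cubic averaging window in voxels (>= 4);
#'   32 is a robust default for fibers a few to ~20 voxels thick.
#' @param gradientSigmaVox sigma of the Gaussian-derivative filter (voxels).
#' @return an [OrientationField-class].
#' @export
estimateTensorOrientation <- function(vol, skeleton, windowVox = 32,
                                      gradientSigmaVox = 1.0) {
  .assertVolume(vol)
  if (windowVox < 4) stop("windowVox must be >= 4")
  if (gradientSigmaVox <= 0) stop("gradientSigmaVox must be > 0")
  sk <- if (is(skeleton, "SkeletonVolume")) skeletonMask(skeleton) else
    .asBinary(skeleton, "skeleton")
  if (!identical(dim(sk), dim(vol)))
    stop("skeleton dimensions do not match the volume")
  idx <- which(sk)
  if (!length(idx))
    return(new("OrientationField",
               coords = matrix(integer(), 0, 3), thetaDeg = numeric(),
               phiDeg = numeric(), windowVox = windowVox,
               gradientSigmaVox = gradientSigmaVox,
               diagnostics = list(nSkeleton = 0L, nFlat = 0L, nTie = 0L)))
  coords <- arrayInd(idx, dim(vol))
  g <- .gradient3d(vol, gradientSigmaVox)
  d <- dim(vol)
  w <- as.integer(windowVox)
  comps <- list(c("x", "x"), c("x", "y"), c("x", "z"),
                c("y", "y"), c("y", "z"), c("z", "z"))
  tens <- matrix(NA_real_, length(idx), 6)
  for (i in seq_along(comps)) {
    prod <- g[[comps[[i]][1]]] * g[[comps[[i]][2]]]
    tens[, i] <- cpp_box_filter3d(as.double(prod), d, w)[idx]
  }
  rm(g, prod)
  eg <- cpp_smallest_eigvec3(tens)
  trace <- tens[, 1] + tens[, 4] + tens[, 6]
  flat <- trace <= 1e-12
  tie <- !flat & (eg$values[, 2] - eg$values[, 1]) <= 1e-9 * pmax(trace, 1e-12)
  keep <- !flat & !tie
  ang <- vectorToAngles(eg$vectors[keep, , drop = FALSE])
  new("OrientationField",
      coords = coords[keep, , drop = FALSE],
      thetaDeg = ang[, 1], phiDeg = ang[, 2],
      windowVox = windowVox, gradientSigmaVox = gradientSigmaVox,
      diagnostics = list(nSkeleton = length(idx), nFlat = sum(flat),
                         nTie = sum(tie)))
}

#' Global 2D orientation from the Fourier power spectrum
#'
#' Computes the power spectrum of a 2D image (DC removed), treats spectral
#' power as point weights on the frequency coordinates, and extracts the
#' principal axes of the weighted coordinates. Because structures elongated
#' along an image direction concentrate spectral power perpendicular to that
#' direction, the dominant image orientation is perpendicular to the
#' spectrum's major axis. Anisotropy is `1 - minor/major` eigenvalue: 0 for
#' an isotropic spectrum, 1 for a perfectly oriented one.
#'
#' @param img 2D numeric matrix, both sides >= 16. The matrix is indexed
#'   `[x, y]`; theta = 0 means structures constant along x.
#' @return list with `theta_deg` in (-90, 90], `anisotropy` in \[0, 1\], and
#'   `reliable` (`FALSE` when anisotropy < 0.1, where the angle is
#'   meaningless).
#' @export
estimateFourierOrientation <- function(img) {
  if (!is.matrix(img) || any(dim(img) < 16))
    stop("img must be a 2D matrix with both sides >= 16")
  P <- Mod(stats::fft(img - mean(img)))^2
  P[1, 1] <- 0
  if (sum(P) <= 0) stop("constant image: no spectral energy")
  n1 <- nrow(P); n2 <- ncol(P)
  f1 <- (seq_len(n1) - 1); f1[f1 > n1 / 2] <- f1[f1 > n1 / 2] - n1
  f2 <- (seq_len(n2) - 1); f2[f2 > n2 / 2] <- f2[f2 > n2 / 2] - n2
  fx <- matrix(f1 / n1, n1, n2)
  fy <- matrix(rep(f2 / n2, each = n1), n1, n2)
  s <- sum(P)
  Sxx <- sum(P * fx * fx) / s
  Syy <- sum(P * fy * fy) / s
  Sxy <- sum(P * fx * fy) / s
  e <- eigen(matrix(c(Sxx, Sxy, Sxy, Syy), 2, 2), symmetric = TRUE)
  major <- e$vectors[, 1] # largest eigenvalue first
  dir <- c(-major[2], major[1]) # image orientation is perpendicular
  theta <- atan2(dir[2], dir[1]) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  aniso <- 1 - e$values[2] / e$values[1]
  list(theta_deg = theta, anisotropy = aniso, reliable = aniso >= 0.1)
}
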
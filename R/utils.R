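#' @include AllClasses.R
NULL

.assertVolume <- function(vol, what = "volume") {
  if (!is.array(vol) || length(dim(vol)) != 3)
    stop(what, " must be a 3D array", call. = FALSE)
  if (any(dim(vol) < 1)) stop(what, " has an empty dimension", call. = FALSE)
  invisible(vol)
}

.asBinary <- function(vol, what = "volume") {
  .assertVolume(vol, what)
  if (is.logical(vol)) return(vol)
  array(vol > 0, dim = dim(vol))
}

# Sampled Gaussian kernel; deriv = 1 yields a derivative kernel normalised so
# that correlation with a unit ramp returns exactly 1.
.gaussianKernel <- function(sigma, deriv = 0, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- seq.int(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  if (deriv == 0) return(g / sum(g))
  k <- x * g
  k / sum(x * k)
}

# Separable correlation of a 3D array with one kernel per axis.
.sepConv3d <- function(vol, kx, ky, kz) {
  d <- dim(vol)
  v <- as.double(vol)
  if (!is.null(kx)) v <- cpp_conv3d_axis(v, d, kx, 0L)
  if (!is.null(ky)) v <- cpp_conv3d_axis(v, d, ky, 1L)
  if (!is.null(kz)) v <- cpp_conv3d_axis(v, d, kz, 2L)
  array(v, dim = d)
}

#' Gaussian smoothing of a 3D volume
#'
#' Isotropic separable Gaussian filter (mirror boundary, kernel truncated at
#' 4 sigma).
#'
#' @param vol 3D numeric array.
#' @param sigma standard deviation in voxels; `0` returns the input unchanged.
#' @return smoothed numeric array of the same dimensions.
#' @export
gaussianSmooth3D <- function(vol, sigma) {
  .assertVolume(vol)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(vol + 0)
  g <- .gaussianKernel(sigma)
  .sepConv3d(vol, g, g, g)
}

# Gaussian-derivative gradient of a 3D volume: list of gx, gy, gz arrays.
.gradient3d <- function(vol, sigma) {
  g0 <- .gaussianKernel(sigma)
  g1 <- .gaussianKernel(sigma, deriv = 1)
  list(x = .sepConv3d(vol, g1, g0, g0),
       y = .sepConv3d(vol, g0, g1, g0),
       z = .sepConv3d(vol, g0, g0, g1))
}

.withSeed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}
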
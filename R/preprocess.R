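#' @include utils.R
NULL

#' Binarize a grayscale volume
#'
#' Global thresholding of a grayscale volume. `method = "otsu"` computes the
#' Otsu threshold on a 256-bin histogram of the whole volume (via
#' \pkg{EBImage}); `method = "fixed"` uses the supplied threshold. Foreground
#' is strictly above the threshold, so binarization is bit-reproducible.
#'
#' @param vol 3D numeric array.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold value for `method = "fixed"`.
#' @return logical array of the same dimensions (`TRUE` = foreground), with
#'   the threshold used attached as attribute `"threshold"`.
#' @export
binarizeVolume <- function(vol, method = c("otsu", "fixed"),
                           threshold = NULL) {
  .assertVolume(vol)
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(threshold) || !is.finite(threshold))
      stop("method = 'fixed' requires a finite threshold")
    th <- threshold
  } else {
    rng <- range(vol)
    if (rng[1] == rng[2])
      stop("constant-valued volume: Otsu is undefined, use method = 'fixed'")
    v01 <- (as.numeric(vol) - rng[1]) / (rng[2] - rng[1])
    th01 <- EBImage::otsu(EBImage::Image(matrix(v01, ncol = 1L)),
                          range = c(0, 1), levels = 256)
    th <- rng[1] + th01 * (rng[2] - rng[1])
  }
  out <- array(vol > th, dim = dim(vol))
  attr(out, "threshold") <- th
  out
}

#' Skeletonize a binary volume in 3D
#'
#' Curve thinning of a binary volume to a one-voxel-thick medial-axis
#' approximation. The algorithm iteratively deletes simple border points
#' (Bertrand--Malandain characterization: exactly one foreground 26-component
#' in the 26-neighbourhood and one background 6-component in the
#' 18-neighbourhood) in six directional subiterations per pass, preserving
#' curve endpoints; deleting only simple points guarantees that the
#' connectivity of every foreground component is preserved.
#'
#' @param vol binary 3D array (logical, or numeric where `> 0` is
#'   foreground).
#' @return a [SkeletonVolume-class]. An empty volume yields an empty
#'   skeleton.
#' @export
skeletonize3D <- function(vol) {
  b <- .asBinary(vol)
  sk <- cpp_skeletonize3d(as.logical(b), dim(b))
  new("SkeletonVolume", skeleton = array(sk, dim = dim(b)),
      sourceDim = as.integer(dim(b)))
}
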
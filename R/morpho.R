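#' @include utils.R
NULL

#' Porosity of a labeled material volume
#'
#' Exact voxel counting on a segmented volume with materials labeled 1..M on
#' a zero background: porosity is the fraction of background ("air") voxels,
#' and a volume fraction is reported for every material label present.
#'
#' @param labels non-negative integer 3D array.
#' @return list with `porosity` (background fraction), `perMaterial` (named
#'   numeric vector of material fractions) and `totalVoxels`. The fractions
#'   sum to 1 exactly.
#' @examples
#' v <- array(0L, c(10, 10, 10)); v[1:100] <- 1L
#' calcPorosity(v)$porosity # 0.9
#' @export
calcPorosity <- function(labels) {
  .assertVolume(labels, "labels")
  if (any(labels < 0)) stop("labels must be non-negative integers")
  total <- length(labels)
  vals <- as.integer(labels[labels > 0])
  perMaterial <- numeric(0)
  if (length(vals)) {
    counts <- tabulate(vals)
    present <- which(counts > 0)
    perMaterial <- counts[present] / total
    names(perMaterial) <- present
  }
  list(porosity = 1 - sum(perMaterial), perMaterial = perMaterial,
       totalVoxels = total)
}

#' Count and measure non-adjacent objects
#'
#' Connected-component analysis of particles/inclusions in a segmented
#' volume. Binary input is labeled internally under the chosen voxel
#' connectivity (labels in scan order of each component's first voxel);
#' integer input with values other than 0/1 is treated as pre-labeled. Each
#' object row carries its voxel count, centroid, bounding box and
#' equivalent-sphere diameter `(6 V / pi)^(1/3)`.
#'
#' @param vol binary or integer-labeled 3D array.
#' @param connectivity 6, 18 or 26 (face / face+edge / face+edge+corner).
#' @return data.frame with columns `label`, `voxel_count`, `centroid_x/y/z`,
#'   `bbox_xmin/xmax/ymin/ymax/zmin/zmax`, `equivalent_diameter_vox`, ordered
#'   by label.
#' @export
objectCounter <- function(vol, connectivity = 26) {
  .assertVolume(vol)
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  vals <- unique(as.vector(vol))
  preLabeled <- !is.logical(vol) && any(!vals %in% c(0, 1))
  lab <- if (preLabeled) {
    if (any(vals < 0)) stop("labels must be non-negative")
    array(as.integer(vol), dim = dim(vol))
  } else {
    array(cpp_label3d(as.logical(vol > 0), dim(vol),
                      as.integer(connectivity)), dim = dim(vol))
  }
  fg <- which(lab > 0L)
  if (!length(fg))
    return(data.frame(label = integer(), voxel_count = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      centroid_z = numeric(), bbox_xmin = integer(),
                      bbox_xmax = integer(), bbox_ymin = integer(),
                      bbox_ymax = integer(), bbox_zmin = integer(),
                      bbox_zmax = integer(),
                      equivalent_diameter_vox = numeric()))
  co <- arrayInd(fg, dim(lab))
  l <- lab[fg]
  f <- factor(l, levels = sort(unique(l)))
  cnt <- as.integer(table(f))
  agg <- function(v, fun) as.numeric(tapply(v, f, fun))
  data.frame(
    label = as.integer(levels(f)),
    voxel_count = cnt,
    centroid_x = agg(co[, 1], mean), centroid_y = agg(co[, 2], mean),
    centroid_z = agg(co[, 3], mean),
    bbox_xmin = agg(co[, 1], min), bbox_xmax = agg(co[, 1], max),
    bbox_ymin = agg(co[, 2], min), bbox_ymax = agg(co[, 2], max),
    bbox_zmin = agg(co[, 3], min), bbox_zmax = agg(co[, 3], max),
    equivalent_diameter_vox = (6 * cnt / pi)^(1 / 3))
}
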
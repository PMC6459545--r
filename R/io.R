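#' @include utils.R
NULL

.readSlice <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, all = FALSE, as.is = TRUE),
    png = {
      m <- png::readPNG(path)
      if (length(dim(m)) == 3) m <- m[, , 1] # first channel of RGB(A)
      round(m * 255)
    },
    stop("unsupported slice format: ", path))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

# A slice matrix [row, col] maps to volume coordinates [x = col, y = row].
.sliceToXY <- function(m) t(m)
.xyToSlice <- function(m) t(m)

#' Read a volume from TIFF stack or slice directory
#'
#' Accepts a multipage TIFF or a directory of equally sized 2D TIFF/PNG
#' slices stacked in lexicographic filename order. Slices are stored as
#' `vol[x, y, z]` with `x` the slice column, `y` the slice row and `z` the
#' page/slice index; a single 2D image yields a one-slice volume.
#'
#' @param path file or directory path.
#' @return 3D numeric array; integer sample values are preserved exactly.
#' @export
readVolume <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no TIFF/PNG slices in ", path)
    slices <- lapply(files, .readSlice)
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("mixed slice shapes in ", path, ": ",
           paste(basename(files[dims[1, ] != dims[1, 1] |
                                  dims[2, ] != dims[2, 1]]), collapse = ", "))
    arr <- array(0, dim = c(dims[2, 1], dims[1, 1], length(slices)))
    for (i in seq_along(slices)) arr[, , i] <- .sliceToXY(slices[[i]])
    return(arr)
  }
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- paste0(path, ".meta.json")
  # float32 files (affine sidecar present) are stored normalized to [0, 1];
  # integer files are read back at their raw sample values
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !file.exists(meta))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  d1 <- dim(pages[[1]])
  if (any(vapply(pages, function(p) !identical(dim(p), d1), logical(1))))
    stop("mixed page shapes in ", path)
  arr <- array(0, dim = c(d1[2], d1[1], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- .sliceToXY(pages[[i]])
  if (file.exists(meta)) { # float32 affine sidecar written by writeVolume
    m <- jsonlite::read_json(meta, simplifyVector = TRUE)
    arr <- arr * m$scale + m$offset
  }
  arr
}

#' Write a volume as a multipage TIFF
#'
#' `uint8` and `uint16` store integer values 0..255 / 0..65535 exactly.
#' `float32` stores min/max-normalized 32-bit floats plus a JSON sidecar
#' (`<path>.meta.json`) with the affine scale/offset that [readVolume()]
#' re-applies; the round trip is accurate to 32-bit float precision.
#'
#' @param vol 3D numeric array `[x, y, z]`.
#' @param path output file; must not exist unless `force = TRUE`.
#' @param dtype `"uint8"`, `"uint16"` or `"float32"`.
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path, dtype = c("uint8", "uint16", "float32"),
                        force = FALSE) {
  .assertVolume(vol)
  dtype <- match.arg(dtype)
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  maxv <- switch(dtype, uint8 = 255, uint16 = 65535, float32 = NA)
  if (!is.na(maxv) && (any(vol < 0) || any(vol > maxv) ||
                       any(vol != round(vol))))
    stop("values out of range for ", dtype)
  scale <- 1; offset <- 0
  if (is.na(maxv)) { # float32: normalize into [0,1], record the affine map
    rng <- range(vol)
    offset <- rng[1]
    scale <- max(rng[2] - rng[1], .Machine$double.xmin)
    jsonlite::write_json(list(scale = scale, offset = offset),
                         paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  pages <- lapply(seq_len(dim(vol)[3]), function(z) {
    m <- .xyToSlice(vol[, , z])
    if (is.na(maxv)) (m - offset) / scale else m / maxv
  })
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Export a phantom with its ground truth
#'
#' Writes `volume.tif` (uint8 0/1), `labels.tif` (uint16), `fibers.csv`
#' (columns `label,theta_deg,phi_deg,diameter_vox,length_vox,seed_x,seed_y,
#' seed_z`) and `config.json` into a directory.
#'
#' @param phantom a [FiberPhantom-class].
#' @param dir output directory (created if needed).
#' @param force overwrite existing files.
#' @return `dir`, invisibly.
#' @export
exportPhantom <- function(phantom, dir, force = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeVolume(phantomVolume(phantom), file.path(dir, "volume.tif"), "uint8",
              force = force)
  writeVolume(phantomLabels(phantom), file.path(dir, "labels.tif"), "uint16",
              force = force)
  fib <- fiberTable(phantom)
  utils::write.csv(fib[, c("label", "theta_deg", "phi_deg", "diameter_vox",
                           "length_vox", "seed_x", "seed_y", "seed_z")],
                   file.path(dir, "fibers.csv"), row.names = FALSE)
  cfg <- simConfig(phantom)
  cfgList <- sapply(slotNames(cfg), function(s) slot(cfg, s),
                    simplify = FALSE)
  jsonlite::write_json(cfgList, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write an orientation field to CSV
#'
#' @param orientation an [OrientationField-class].
#' @param path output CSV (`x,y,z,theta_deg,phi_deg`, 1-based voxel indices).
#' @param force overwrite an existing file.
#' @export
writeOrientationCSV <- function(orientation, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  utils::write.csv(orientationTable(orientation), path, row.names = FALSE)
  invisible(path)
}

#' Read an orientation field from CSV
#'
#' @param path CSV written by [writeOrientationCSV()].
#' @return an [OrientationField-class] (window metadata unknown, `NA`).
#' @export
readOrientationCSV <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("x", "y", "z", "theta_deg", "phi_deg")
  if (!all(need %in% names(tab)))
    stop("orientation CSV must have columns ", paste(need, collapse = ","))
  new("OrientationField",
      coords = as.matrix(tab[, c("x", "y", "z")]),
      thetaDeg = tab$theta_deg, phiDeg = tab$phi_deg,
      windowVox = NA_real_, gradientSigmaVox = NA_real_,
      diagnostics = list())
}

#' Write a diameter field to CSV
#'
#' @param diameter a [DiameterField-class].
#' @param path output CSV (`x,y,z,diameter_vox,censored`).
#' @param voxelSizeUm optional physical voxel size; when given, an extra
#'   `diameter_um` column is added at export (the field itself stays in
#'   voxels).
#' @param force overwrite an existing file.
#' @export
writeDiameterCSV <- function(diameter, path, voxelSizeUm = NULL,
                             force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  tab <- diameterTable(diameter)
  if (!is.null(voxelSizeUm)) tab$diameter_um <- tab$diameter_vox * voxelSizeUm
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
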
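#' 3-D scalar volume with voxel spacing and world coordinates
#'
#' The raster currency of the pipeline: a 3-D array of signal intensities
#' plus the geometry needed to move between voxel indices and world
#' millimetre coordinates. The world axes follow the anatomical convention
#' used throughout the package: x runs posterior to anterior, y left to
#' right, z inferior to superior. The centre of voxel `(i, j, k)` (1-based)
#' sits at `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @param data 3-D numeric array of intensities (finite).
#' @param spacing numeric length-3, voxel size per axis in mm (positive).
#' @param origin numeric length-3, world position of the grid corner in mm.
#' @param meta named list of free-form provenance tags.
#' @return An object of class `cow_volume`.
#' @export
cow_volume <- function(data, spacing, origin = c(0, 0, 0), meta = list()) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L,
            length(origin) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive and finite")
  if (any(!is.finite(data)))
    stop("volume data must be finite")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), meta = meta),
            class = "cow_volume")
}

#' @export
print.cow_volume <- function(x, ...) {
  cat(sprintf("<cow_volume> %s voxels @ %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel to world transform (4 x 4 affine)
#'
#' @param volume a [cow_volume].
#' @return 4 x 4 matrix mapping homogeneous 1-based voxel indices to world mm.
#' @export
vox_affine <- function(volume) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(volume$spacing, 3)
  a[1:3, 4] <- volume$origin - 0.5 * volume$spacing
  a
}

#' Convert world mm coordinates to (continuous, 1-based) voxel indices
#' @param volume a [cow_volume].
#' @param xyz numeric vector of length 3 or an n x 3 matrix.
#' @return same shape as `xyz`, continuous voxel indices.
#' @export
world_to_voxel <- function(volume, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, volume$origin, "-"), 2, volume$spacing, "/") + 0.5
}

#' Convert (1-based) voxel indices to world mm coordinates of voxel centres
#' @inheritParams world_to_voxel
#' @param ijk numeric vector of length 3 or an n x 3 matrix.
#' @export
voxel_to_world <- function(volume, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 0.5, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' Read a NIfTI-1 volume
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [cow_volume]; the NIfTI sform offset is mapped to `origin`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- as.numeric(attr(img, "pixdim")[1:3])
  xf <- RNifti::xform(img)
  # NIfTI maps 0-based indices: world = M %*% c(i0, j0, k0, 1);
  # our origin satisfies world(voxel 1) = origin + 0.5 * spacing
  origin <- as.numeric(xf[1:3, 4]) + 0.5 * sp
  data <- array(as.numeric(img), dim(img))
  cow_volume(data, spacing = sp, origin = origin)
}

#' Write a volume as NIfTI-1
#' @param volume a [cow_volume].
#' @param path output path (`.nii.gz` recommended).
#' @param datatype NIfTI storage type, e.g. `"float"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "float") {
  xf <- diag(4)
  xf[1:3, 1:3] <- diag(volume$spacing, 3)
  xf[1:3, 4] <- volume$origin - 0.5 * volume$spacing
  arr <- volume$data
  attr(arr, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(arr, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Binary mask helper
#' @param volume a [cow_volume].
#' @param mask logical array with the volume's dimensions.
#' @return a [cow_volume] holding 0/1 data with the same geometry.
#' @export
mask_volume <- function(volume, mask) {
  cow_volume(array(as.numeric(mask), dim(volume$data)),
             spacing = volume$spacing, origin = volume$origin,
             meta = volume$meta)
}
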
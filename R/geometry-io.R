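#' Voxel geometry
#'
#' Edge lengths of a voxel in millimetres plus a voxel-to-world affine.
#' Volumes everywhere in the package are derived from this object by voxel
#' counting; no resampling is performed anywhere in the pipeline, so the
#' geometry of an image is fixed at read/generation time.
#'
#' @param dx,dy,dz voxel edge lengths in mm; must be positive.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a scaling
#'   matrix built from the edge lengths.
#' @return an object of class `voxel_geometry`.
#' @export
voxel_geometry <- function(dx, dy, dz, affine = NULL) {
  d <- c(dx, dy, dz)
  if (!is.numeric(d) || length(d) != 3L || anyNA(d) || any(d <= 0)) {
    stop("voxel edge lengths must be positive finite numbers", call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(c(d, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(dx = dx, dy = dy, dz = dz, affine = affine),
            class = "voxel_geometry")
}

#' Volume of a single voxel in mm^3
#'
#' @param geometry a [voxel_geometry()].
#' @return `dx * dy * dz` in mm^3.
#' @export
voxel_volume <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  geometry$dx * geometry$dy * geometry$dz
}

#' 3-D intensity volume
#'
#' @param data 3-D numeric array of finite intensities.
#' @param geometry a [voxel_geometry()].
#' @return an object of class `vol_image`.
#' @export
vol_image <- function(data, geometry) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("image data must be a 3-D array", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("image intensities must be finite", call. = FALSE)
  stopifnot(inherits(geometry, "voxel_geometry"))
  structure(list(data = data, geometry = geometry), class = "vol_image")
}

#' Binary voxel mask
#'
#' Shares the geometry of the image it applies to; values are strictly 0/1.
#'
#' @param data 3-D array of 0/1 values.
#' @param geometry a [voxel_geometry()].
#' @return an object of class `bin_mask`.
#' @export
bin_mask <- function(data, geometry) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("mask data must be a 3-D array", call. = FALSE)
  }
  if (!all(data %in% c(0, 1))) {
    stop("mask values must be 0 or 1", call. = FALSE)
  }
  stopifnot(inherits(geometry, "voxel_geometry"))
  storage.mode(data) <- "integer"
  structure(list(data = data, geometry = geometry), class = "bin_mask")
}

same_geometry <- function(a, b, tol = 1e-6) {
  abs(a$geometry$dx - b$geometry$dx) < tol &&
    abs(a$geometry$dy - b$geometry$dy) < tol &&
    abs(a$geometry$dz - b$geometry$dz) < tol &&
    identical(dim(a$data), dim(b$data))
}

stop_if_geometry_mismatch <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b)) {
    stop(sprintf("%s must share shape and voxel geometry", what), call. = FALSE)
  }
  invisible(TRUE)
}

nifti_geometry <- function(img) {
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  voxel_geometry(pd[1], pd[2], pd[3], affine = unclass(RNifti::xform(img)))
}

#' Read a 3-D NIfTI volume
#'
#' 4-D files whose trailing axis is a singleton are squeezed to 3-D;
#' any other dimensionality is rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [vol_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.numeric(img), dim = d)
  } else {
    stop("expected a 3-D volume, got ", length(d), " dimensions", call. = FALSE)
  }
  vol_image(img2, nifti_geometry(img))
}

#' Write a volume to NIfTI
#'
#' @param image a [vol_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "vol_image"))
  img <- RNifti::asNifti(image$data)
  RNifti::pixdim(img) <- c(image$geometry$dx, image$geometry$dy, image$geometry$dz)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Values above 0.5 are treated as 1 (masks are stored as uint8 on disk).
#'
#' @inheritParams read_volume
#' @return a [bin_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  bin_mask(array(as.integer(v$data > 0.5), dim = dim(v$data)), v$geometry)
}

#' Write a binary mask to NIfTI (uint8)
#'
#' @param mask a [bin_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "bin_mask"))
  img <- RNifti::asNifti(mask$data)
  RNifti::pixdim(img) <- c(mask$geometry$dx, mask$geometry$dy, mask$geometry$dz)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Volume of a mask in cc
#'
#' Number of set voxels times the voxel volume, converted from mm^3 to cc.
#'
#' @param mask a [bin_mask()].
#' @return volume in cc (cm^3).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "bin_mask"))
  sum(mask$data) * voxel_volume(mask$geometry) / 1000
}
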
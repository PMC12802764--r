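#' Estimate a smooth multiplicative bias field
#'
#' Robust log-domain polynomial surrogate for the slowly varying coil
#' inhomogeneity field: a degree-`degree` trivariate polynomial is fitted by
#' least squares to the log-intensities inside `mask`, residuals beyond
#' 2.5 median absolute deviations are discarded (robustness against tissue
#' contrast, which is not bias), and the model is refitted once. The returned
#' field is `exp` of the fit, rescaled to geometric mean 1 over the mask so
#' that correction preserves the overall intensity scale.
#'
#' @param image a [vol_image()]; intensities inside `mask` must be positive.
#' @param mask a [bin_mask()] sharing the image geometry.
#' @param degree polynomial degree (default 3).
#' @param max_fit_voxels cap on the number of voxels entering the fit;
#'   masked voxels are thinned deterministically beyond it.
#' @return an object of class `bias_field` with elements `data` (strictly
#'   positive 3-D array), `geometry`, `degree`.
#' @export
estimate_bias <- function(image, mask, degree = 3, max_fit_voxels = 2e5) {
  stopifnot(inherits(image, "vol_image"), inherits(mask, "bin_mask"))
  stop_if_geometry_mismatch(image, mask, "image and mask")
  idx <- which(mask$data == 1L)
  vals <- image$data[idx]
  if (any(vals <= 0)) {
    stop("bias estimation requires positive intensities inside the mask",
         call. = FALSE)
  }
  ex <- poly_exponents(degree)
  if (length(idx) < nrow(ex)) {
    stop("too few masked voxels (", length(idx), ") for a degree-", degree,
         " fit (", nrow(ex), " terms)", call. = FALSE)
  }
  fit_idx <- thin_index(idx, max_fit_voxels)
  B <- poly_basis_at(dim(image$data), fit_idx, ex)
  y <- log(image$data[fit_idx])
  fit <- stats::lm.fit(B, y)
  r <- fit$residuals
  s <- stats::mad(r)
  if (s > 0) {
    keep <- abs(r - stats::median(r)) <= 2.5 * s
    if (sum(keep) >= nrow(ex)) {
      fit <- stats::lm.fit(B[keep, , drop = FALSE], y[keep])
    }
  }
  logfield <- eval_poly_field(dim(image$data), fit$coefficients, ex)
  logfield <- logfield - mean(logfield[idx])
  structure(list(data = exp(logfield), geometry = image$geometry,
                 degree = degree),
            class = "bias_field")
}

#' Remove a multiplicative bias field
#'
#' Voxelwise division by the (strictly positive) field; zero voxels stay zero.
#'
#' @param image a [vol_image()].
#' @param field a `bias_field` from [estimate_bias()], matching geometry.
#' @return the corrected [vol_image()].
#' @export
correct_bias <- function(image, field) {
  stopifnot(inherits(image, "vol_image"), inherits(field, "bias_field"))
  stop_if_geometry_mismatch(image, field, "image and bias field")
  vol_image(image$data / field$data, image$geometry)
}

#' Write a bias field to NIfTI for quality control
#'
#' @param field a `bias_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bias_field <- function(field, path) {
  stopifnot(inherits(field, "bias_field"))
  write_volume(vol_image(field$data, field$geometry), path)
}
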
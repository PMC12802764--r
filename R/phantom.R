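#' Specification of a FLAIR-like head phantom
#'
#' The phantom is a set of nested ellipsoids emulating the compartments seen
#' on clinical FLAIR: an intracranial ellipsoid filled by a peripheral CSF
#' rim, a cortical grey-matter shell, a white-matter core and a central
#' ventricular CSF ellipsoid. CSF is suppressed (dark), WM is the intensity
#' anchor, GM is mildly brighter than WM. Voxels are labeled by their centre
#' point, so the ground-truth masks are exact; partial-volume effects arise
#' only from voxelization.
#'
#' @param icv_semiaxes numeric(3), semi-axes of the intracranial ellipsoid (mm).
#' @param csf_rim_mm thickness of the peripheral CSF shell (mm).
#' @param gm_rim_mm thickness of the cortical GM shell (mm).
#' @param ventricle_semiaxes numeric(3), semi-axes of the central CSF
#'   ellipsoid (mm); must fit inside the WM core.
#' @param intensities named numeric: `csf`, `wm`, `gm` in arbitrary units;
#'   CSF must be darker than half the WM intensity (FLAIR suppression).
#' @param noise_sd additive Gaussian noise SD in intensity units, applied
#'   inside the ICV only and clipped at zero.
#' @param bias_coeffs coefficients of a log-domain polynomial bias field
#'   (see [poly_exponents()]); `NULL` or all-zero means no bias.
#' @param geometry a [voxel_geometry()]; the default emulates thick-slice
#'   clinical axial FLAIR (0.9 x 0.9 x 6 mm).
#' @param seed RNG seed for the noise realization.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(icv_semiaxes = c(85, 65, 70),
                         csf_rim_mm = 4,
                         gm_rim_mm = 3,
                         ventricle_semiaxes = c(40, 18, 18),
                         intensities = c(csf = 0.10, wm = 1.00, gm = 1.15),
                         noise_sd = 0,
                         bias_coeffs = NULL,
                         geometry = voxel_geometry(0.9, 0.9, 6.0),
                         seed = 1L) {
  stopifnot(length(icv_semiaxes) == 3, all(icv_semiaxes > 0),
            csf_rim_mm >= 0, gm_rim_mm >= 0,
            length(ventricle_semiaxes) == 3, all(ventricle_semiaxes >= 0),
            all(c("csf", "wm", "gm") %in% names(intensities)),
            noise_sd >= 0)
  if (csf_rim_mm + gm_rim_mm >= min(icv_semiaxes)) {
    stop("CSF and GM rims must be thinner than the smallest ICV semi-axis",
         call. = FALSE)
  }
  core <- icv_semiaxes - csf_rim_mm - gm_rim_mm
  if (any(ventricle_semiaxes >= core)) {
    stop("ventricle must fit inside the white-matter core", call. = FALSE)
  }
  if (intensities["csf"] >= intensities["wm"] / 2) {
    stop("CSF intensity must be suppressed below half the WM intensity",
         call. = FALSE)
  }
  if (intensities["wm"] <= 0 || intensities["gm"] <= 0) {
    stop("WM and GM intensities must be positive", call. = FALSE)
  }
  structure(list(icv_semiaxes = icv_semiaxes, csf_rim_mm = csf_rim_mm,
                 gm_rim_mm = gm_rim_mm, ventricle_semiaxes = ventricle_semiaxes,
                 intensities = intensities, noise_sd = noise_sd,
                 bias_coeffs = bias_coeffs, geometry = geometry,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_cc <- function(semi) 4 / 3 * pi * prod(semi) / 1000

#' Closed-form compartment volumes of a phantom
#'
#' Exact ellipsoid/shell volumes in cc, against which voxel-count volumes
#' converge as the voxel size shrinks.
#'
#' @param spec a [phantom_spec()].
#' @return named numeric: `icv`, `brain`, `wm`, `gm`, `csf`, `ventricle`,
#'   and `bpf` (brain/icv), all volumes in cc.
#' @export
analytic_volumes <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  icv <- ellipsoid_cc(spec$icv_semiaxes)
  brain_outer <- ellipsoid_cc(spec$icv_semiaxes - spec$csf_rim_mm)
  gm_inner <- ellipsoid_cc(spec$icv_semiaxes - spec$csf_rim_mm - spec$gm_rim_mm)
  vent <- if (all(spec$ventricle_semiaxes > 0)) ellipsoid_cc(spec$ventricle_semiaxes) else 0
  gm <- brain_outer - gm_inner
  wm <- gm_inner - vent
  brain <- wm + gm
  c(icv = icv, brain = brain, wm = wm, gm = gm,
    csf = icv - brain, ventricle = vent, bpf = brain / icv)
}

# squared normalized radius of every voxel centre wrt an ellipsoid
ellipsoid_r2 <- function(xs, ys, zs, semi) {
  rx <- (xs / semi[1])^2
  ry <- (ys / semi[2])^2
  rz <- (zs / semi[3])^2
  nx <- length(rx); ny <- length(ry); nz <- length(rz)
  as.vector(outer(rx, ry, "+")) + rep(rz, each = nx * ny)
}

#' Generate a phantom image with ground truth
#'
#' Voxelizes the nested ellipsoids of `spec` on its voxel grid, assigns
#' compartment intensities, then applies the multiplicative bias field and
#' additive noise. Truth masks and volumes are recorded before bias and
#' noise, so they are exact labels.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom` with elements `image` ([vol_image()]),
#'   `truth` (masks `brain_mask`, `icv_mask`, `wm_mask`, `gm_mask`,
#'   `csf_mask`; `volumes_voxel` and `volumes_analytic` in cc) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  margin <- 4
  half <- spec$icv_semiaxes + margin
  dims <- c(max(3L, ceiling(2 * half[1] / g$dx)),
            max(3L, ceiling(2 * half[2] / g$dy)),
            max(3L, ceiling(2 * half[3] / g$dz)))
  xs <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * g$dx
  ys <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * g$dy
  zs <- (seq_len(dims[3]) - (dims[3] + 1) / 2) * g$dz

  in_icv <- ellipsoid_r2(xs, ys, zs, spec$icv_semiaxes) <= 1
  if (!any(in_icv)) stop("voxel grid too coarse: phantom has no interior voxels",
                         call. = FALSE)
  in_brain <- ellipsoid_r2(xs, ys, zs, spec$icv_semiaxes - spec$csf_rim_mm) <= 1
  in_core <- ellipsoid_r2(xs, ys, zs,
                          spec$icv_semiaxes - spec$csf_rim_mm - spec$gm_rim_mm) <= 1
  in_vent <- if (all(spec$ventricle_semiaxes > 0)) {
    ellipsoid_r2(xs, ys, zs, spec$ventricle_semiaxes) <= 1
  } else rep(FALSE, length(in_icv))

  wm <- in_core & !in_vent
  gm <- in_brain & !in_core
  brain <- wm | gm
  csf <- in_icv & !brain

  inten <- numeric(length(in_icv))
  inten[csf] <- spec$intensities["csf"]
  inten[wm] <- spec$intensities["wm"]
  inten[gm] <- spec$intensities["gm"]
  img <- array(inten, dim = dims)

  if (!is.null(spec$bias_coeffs) && any(spec$bias_coeffs != 0)) {
    ex <- poly_exponents(degree_from_length(length(spec$bias_coeffs)))
    img <- img * exp(eval_poly_field(dims, spec$bias_coeffs, ex))
  }
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed, {
      noise <- array(0, dim = dims)
      noise[in_icv] <- stats::rnorm(sum(in_icv), 0, spec$noise_sd)
      pmax(img + noise, 0)
    })
  }

  vx <- voxel_volume(g) / 1000
  as_mask <- function(v) bin_mask(array(as.integer(v), dim = dims), g)
  volumes_voxel <- c(icv = sum(in_icv) * vx, brain = sum(brain) * vx,
                     wm = sum(wm) * vx, gm = sum(gm) * vx,
                     csf = sum(csf) * vx,
                     ventricle = sum(in_vent & in_icv) * vx)
  structure(list(
    image = vol_image(img, g),
    truth = list(brain_mask = as_mask(brain), icv_mask = as_mask(in_icv),
                 wm_mask = as_mask(wm), gm_mask = as_mask(gm),
                 csf_mask = as_mask(csf),
                 volumes_voxel = volumes_voxel,
                 volumes_analytic = analytic_volumes(spec)),
    spec = spec), class = "phantom")
}

#' Apply a multiplicative log-polynomial bias field
#'
#' Multiplies the image voxelwise by `exp(P(x))`, where `P` is a trivariate
#' polynomial in coordinates normalized to `[-1, 1]` per axis. The field is
#' strictly positive by construction.
#'
#' @param image a [vol_image()].
#' @param bias_coeffs coefficients in the [poly_exponents()] basis; the
#'   length must be a complete basis size (1, 4, 10, 20, ...).
#' @return the biased [vol_image()].
#' @export
apply_bias <- function(image, bias_coeffs) {
  stopifnot(inherits(image, "vol_image"))
  ex <- poly_exponents(degree_from_length(length(bias_coeffs)))
  field <- exp(eval_poly_field(dim(image$data), bias_coeffs, ex))
  vol_image(image$data * field, image$geometry)
}

#' Write a phantom to disk
#'
#' Writes the image, the five truth masks, and a JSON sidecar carrying the
#' generating spec (including seed) and both voxel-count and analytic
#' volumes, so the phantom is fully reproducible.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(dir, paste0(prefix, "_flair.nii.gz")))
  write_volume(phantom$image, paths[["image"]])
  for (m in c("brain_mask", "icv_mask", "wm_mask", "gm_mask", "csf_mask")) {
    p <- file.path(dir, paste0(prefix, "_", m, ".nii.gz"))
    write_mask(phantom$truth[[m]], p)
    paths[[m]] <- p
  }
  sidecar <- list(
    spec = list(icv_semiaxes = phantom$spec$icv_semiaxes,
                csf_rim_mm = phantom$spec$csf_rim_mm,
                gm_rim_mm = phantom$spec$gm_rim_mm,
                ventricle_semiaxes = phantom$spec$ventricle_semiaxes,
                intensities = as.list(phantom$spec$intensities),
                noise_sd = phantom$spec$noise_sd,
                bias_coeffs = phantom$spec$bias_coeffs,
                voxel_mm = c(phantom$spec$geometry$dx, phantom$spec$geometry$dy,
                             phantom$spec$geometry$dz),
                seed = phantom$spec$seed),
    volumes_voxel_cc = as.list(phantom$truth$volumes_voxel),
    volumes_analytic_cc = as.list(phantom$truth$volumes_analytic))
  sp <- file.path(dir, paste0(prefix, "_sidecar.json"))
  jsonlite::write_json(sidecar, sp, auto_unbox = TRUE, digits = NA, null = "null")
  paths[["sidecar"]] <- sp
  invisible(paths)
}
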
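#' Volumetrics pipeline configuration
#'
#' @param threshold segmentation threshold on the normalized intensity scale;
#'   half the white-matter anchor by default, so CSF (suppressed well below
#'   the anchor) is excluded and parenchyma retained.
#' @param anchor normalized intensity assigned to the white-matter mode.
#' @param bias_degree polynomial degree of the bias-field surrogate.
#' @param meanshift a [mean_shift_config()].
#' @return an object of class `volumetrics_config`.
#' @export
volumetrics_config <- function(threshold = 0.375, anchor = 0.75,
                               bias_degree = 3,
                               meanshift = mean_shift_config()) {
  stopifnot(threshold >= 0, anchor > 0, bias_degree >= 0)
  structure(list(threshold = threshold, anchor = anchor,
                 bias_degree = bias_degree, meanshift = meanshift),
            class = "volumetrics_config")
}

#' Segment brain parenchyma by thresholding
#'
#' On the normalized image (white-matter mode at the anchor), parenchyma is
#' the set of brain-masked voxels with intensity at or above the threshold.
#' The comparison is inclusive, so `threshold = 0` returns the brain mask
#' restricted to non-negative voxels.
#'
#' @param norm_image normalized [vol_image()].
#' @param brain_mask [bin_mask()] matching the image.
#' @param threshold intensity threshold (default 0.375).
#' @return parenchyma [bin_mask()].
#' @export
segment_parenchyma <- function(norm_image, brain_mask, threshold = 0.375) {
  stopifnot(inherits(norm_image, "vol_image"), inherits(brain_mask, "bin_mask"))
  stop_if_geometry_mismatch(norm_image, brain_mask, "image and brain mask")
  seg <- (norm_image$data >= threshold) & (brain_mask$data == 1L)
  if (!any(seg)) {
    stop("segmentation produced an empty mask; check normalization",
         call. = FALSE)
  }
  bin_mask(array(as.integer(seg), dim = dim(seg)), norm_image$geometry)
}

#' Brain parenchymal fraction
#'
#' @param brain_volume_cc brain (grey + white matter) volume in cc.
#' @param icv_cc intracranial volume in cc.
#' @return `brain_volume_cc / icv_cc`, a fraction in (0, 1].
#' @export
compute_bpf <- function(brain_volume_cc, icv_cc) {
  if (any(brain_volume_cc <= 0) || any(icv_cc <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  if (any(brain_volume_cc > icv_cc)) {
    stop("brain volume exceeds ICV; masks are inconsistent", call. = FALSE)
  }
  brain_volume_cc / icv_cc
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full FLAIR volumetrics pipeline on one subject
#'
#' Stages, mirroring the clinical pipeline: bias correction over the whole
#' head (non-zero voxels), a second bias correction restricted to the brain
#' mask, mean-shift white-matter normalization to the anchor, inclusive
#' thresholding at `threshold`, and voxel-count volumetry. Brain extraction
#' and ICV segmentation are inputs (masks from external tools or phantom
#' truth), not computations.
#'
#' @param flair a [vol_image()].
#' @param brain_mask brain [bin_mask()]; must be contained in `icv_mask`.
#' @param icv_mask intracranial [bin_mask()].
#' @param config a [volumetrics_config()].
#' @return object of class `volumetrics_result`: `brain_volume_cc`,
#'   `icv_cc`, `bpf`, `logit_bpf`, `wm_mode` (pre-normalization modal
#'   intensity), `converged`, plus the parenchyma mask in `parenchyma_mask`.
#' @export
run_volumetrics <- function(flair, brain_mask, icv_mask,
                            config = volumetrics_config()) {
  stopifnot(inherits(flair, "vol_image"), inherits(brain_mask, "bin_mask"),
            inherits(icv_mask, "bin_mask"), inherits(config, "volumetrics_config"))
  stop_if_geometry_mismatch(flair, brain_mask, "FLAIR and brain mask")
  stop_if_geometry_mismatch(flair, icv_mask, "FLAIR and ICV mask")
  if (sum(brain_mask$data) == 0 || sum(icv_mask$data) == 0) {
    stop("masks must be non-empty", call. = FALSE)
  }
  if (any(brain_mask$data == 1L & icv_mask$data == 0L)) {
    stop("brain mask is not contained in the ICV mask", call. = FALSE)
  }

  head_mask <- bin_mask(array(as.integer(flair$data > 0), dim = dim(flair$data)),
                        flair$geometry)
  corr1 <- run_stage("bias-pass-1", {
    correct_bias(flair, estimate_bias(flair, head_mask, config$bias_degree))
  })
  corr2 <- run_stage("bias-pass-2", {
    correct_bias(corr1, estimate_bias(corr1, brain_mask, config$bias_degree))
  })
  norm <- run_stage("wm-normalization", {
    normalize_to_wm(corr2, brain_mask, anchor = config$anchor,
                    config = config$meanshift)
  })
  seg <- run_stage("segmentation", {
    segment_parenchyma(norm$image, brain_mask, config$threshold)
  })
  bv <- mask_volume(seg)
  icv <- mask_volume(icv_mask)
  bpf <- run_stage("volumetry", compute_bpf(bv, icv))
  structure(list(brain_volume_cc = bv, icv_cc = icv, bpf = bpf,
                 logit_bpf = logit(bpf), wm_mode = norm$wm_mode,
                 converged = norm$converged,
                 parenchyma_mask = seg, normalized = norm$image),
            class = "volumetrics_result")
}

#' One-row data frame view of a volumetrics result
#'
#' @param result a `volumetrics_result`.
#' @param subject_id subject identifier for the row.
#' @return data.frame with columns `subject_id`, `brain_volume_cc`,
#'   `icv_cc`, `bpf`, `logit_bpf`, `wm_mode`, `converged`.
#' @export
volumetrics_row <- function(result, subject_id = "subject") {
  stopifnot(inherits(result, "volumetrics_result"))
  data.frame(subject_id = subject_id,
             brain_volume_cc = result$brain_volume_cc,
             icv_cc = result$icv_cc, bpf = result$bpf,
             logit_bpf = result$logit_bpf, wm_mode = result$wm_mode,
             converged = result$converged)
}
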
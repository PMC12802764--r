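test_that("thresholding separates parenchyma from suppressed CSF", {
  ph <- generate_phantom(small_spec())
  norm <- normalize_to_wm(ph$image, ph$truth$brain_mask)
  seg <- segment_parenchyma(norm$image, ph$truth$brain_mask, 0.375)
  # noise-free: segmentation recovers the brain mask exactly, CSF excluded
  expect_identical(seg$data, ph$truth$brain_mask$data)
  csf_norm <- norm$image$data[ph$truth$csf_mask$data == 1]
  expect_true(all(csf_norm < 0.375))

  # threshold 0 keeps the brain mask restricted to positive voxels
  seg0 <- segment_parenchyma(norm$image, ph$truth$brain_mask, 0)
  expect_identical(seg0$data, ph$truth$brain_mask$data)

  expect_error(segment_parenchyma(norm$image, ph$truth$brain_mask, 99), "empty")
})

test_that("BPF is the brain-to-ICV ratio with its logit transform", {
  expect_equal(compute_bpf(1306.9, 1613.5), 0.80998, tolerance = 1e-4)
  expect_equal(compute_bpf(7, 7), 1)
  expect_equal(compute_bpf(3.5, 7), 0.5)
  expect_error(compute_bpf(8, 7), "exceeds")
  expect_error(compute_bpf(-1, 7), "positive")

  expect_equal(logit(0.5), 0)
  expect_equal(logit(0.81), 1.4500, tolerance = 5e-4)
  p <- c(0.05, 0.3, 0.81, 0.97)
  expect_equal(logit(p), -logit(1 - p))
  expect_error(logit(1), "0, 1")
  expect_error(logit(0), "0, 1")
})

test_that("the full pipeline recovers phantom volumes", {
  # clean phantom at 1 mm isotropic: within 2% of truth
  ph <- generate_phantom(small_spec(geometry = voxel_geometry(1, 1, 1)))
  res <- run_volumetrics(ph$image, ph$truth$brain_mask, ph$truth$icv_mask)
  truth_bv <- ph$truth$volumes_voxel[["brain"]]
  expect_lt(abs(res$brain_volume_cc / truth_bv - 1), 0.02)
  expect_equal(res$icv_cc, ph$truth$volumes_voxel[["icv"]])
  truth_bpf <- truth_bv / ph$truth$volumes_voxel[["icv"]]
  expect_lt(abs(res$bpf - truth_bpf), 0.02)
  expect_equal(res$logit_bpf, logit(res$bpf))
  expect_true(res$converged)

  # degree-2 bias spanning ~±30% plus noise: within 5%
  cf <- c(0, 0.12, -0.1, 0.15, 0.08, 0, -0.06, 0.05, 0, -0.07)
  phb <- generate_phantom(small_spec(noise_sd = 0.05, bias_coeffs = cf,
                                     geometry = voxel_geometry(1, 1, 1),
                                     seed = 9))
  resb <- run_volumetrics(phb$image, phb$truth$brain_mask, phb$truth$icv_mask)
  expect_lt(abs(resb$brain_volume_cc / phb$truth$volumes_voxel[["brain"]] - 1),
            0.05)
})

test_that("the pipeline output is invariant to global intensity rescaling", {
  ph <- generate_phantom(small_spec(noise_sd = 0.04, seed = 6))
  r1 <- run_volumetrics(ph$image, ph$truth$brain_mask, ph$truth$icv_mask)
  scaled <- vol_image(ph$image$data * 0.013, ph$image$geometry)
  r2 <- run_volumetrics(scaled, ph$truth$brain_mask, ph$truth$icv_mask)
  expect_equal(r2$brain_volume_cc, r1$brain_volume_cc)
  expect_equal(r2$bpf, r1$bpf)
})

test_that("segmented volume is monotone non-increasing in the threshold", {
  ph <- generate_phantom(small_spec(noise_sd = 0.05, seed = 4))
  norm <- normalize_to_wm(ph$image, ph$truth$brain_mask)
  vols <- vapply(c(0, 0.2, 0.375, 0.6, 0.8),
                 function(th) mask_volume(segment_parenchyma(norm$image,
                                                             ph$truth$brain_mask, th)),
                 numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("inconsistent masks are rejected with the offending stage named", {
  ph <- generate_phantom(small_spec())
  expect_error(run_volumetrics(ph$image, ph$truth$brain_mask,
                               ph$truth$ventricle_mask), "bin_mask")
  # a brain mask poking outside the ICV mask is inconsistent
  expect_error(run_volumetrics(ph$image, ph$truth$icv_mask,
                               ph$truth$brain_mask), "not contained")
  e <- tryCatch(run_volumetrics(vol_image(ph$image$data * 0 - 1, ph$image$geometry),
                                ph$truth$brain_mask, ph$truth$icv_mask),
                error = conditionMessage)
  expect_match(e, "\\[bias-pass-1\\]")
})

test_that("volumetrics results export as a tidy one-row table", {
  ph <- generate_phantom(small_spec())
  res <- run_volumetrics(ph$image, ph$truth$brain_mask, ph$truth$icv_mask)
  row <- volumetrics_row(res, "phantom-01")
  expect_equal(row$bpf, row$brain_volume_cc / row$icv_cc, tolerance = 1e-9)
  expect_named(row, c("subject_id", "brain_volume_cc", "icv_cc", "bpf",
                      "logit_bpf", "wm_mode", "converged"))
})
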
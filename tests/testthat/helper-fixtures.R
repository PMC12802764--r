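# Small phantoms used across tests: same nested-ellipsoid anatomy as the
# default head phantom, scaled down so voxelization stays fast.

small_spec <- function(noise_sd = 0, bias_coeffs = NULL,
                       geometry = voxel_geometry(2, 2, 2), seed = 1L) {
  phantom_spec(icv_semiaxes = c(40, 32, 28), csf_rim_mm = 3, gm_rim_mm = 2.5,
               ventricle_semiaxes = c(15, 8, 8), noise_sd = noise_sd,
               bias_coeffs = bias_coeffs, geometry = geometry, seed = seed)
}

# cube image/mask pair on an isotropic grid
cube_image <- function(value, n = 20, vox = 1) {
  vol_image(array(value, dim = c(n, n, n)), voxel_geometry(vox, vox, vox))
}

full_mask <- function(image) {
  bin_mask(array(1L, dim = dim(image$data)), image$geometry)
}

# direct Bernoulli log-likelihood maximizer, independent of the IRLS path
logistic_oracle <- function(y, X, start = NULL) {
  if (is.null(start)) start <- rep(0, ncol(X))
  negll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  optim(start, negll, control = list(reltol = 1e-14, maxit = 20000))$par
}
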
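# Trivariate polynomial fields over the voxel grid, in coordinates normalized
# to [-1, 1] per axis. Shared by the phantom's simulated bias and the bias
# corrector's fitted field.

#' Exponent table of the trivariate polynomial basis
#'
#' Terms of total degree at most `degree`, ordered by total degree and then
#' lexicographically in (i, j, k) for x^i y^j z^k. The constant term comes
#' first; for `degree = 1` the order is 1, z, y, x.
#'
#' @param degree maximum total degree (non-negative integer).
#' @return integer matrix with columns `i`, `j`, `k`, one row per term.
#' @export
poly_exponents <- function(degree) {
  stopifnot(degree >= 0, degree == round(degree))
  g <- expand.grid(k = 0:degree, j = 0:degree, i = 0:degree)
  g <- g[g$i + g$j + g$k <= degree, c("i", "j", "k")]
  g <- g[order(g$i + g$j + g$k, g$i, g$j, g$k), ]
  m <- as.matrix(g)
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

n_poly_terms <- function(degree) choose(degree + 3, 3)

# coordinate vectors normalized to [-1, 1] along each grid axis
norm_coords <- function(n) {
  if (n == 1L) return(0)
  2 * (seq_len(n) - 1) / (n - 1) - 1
}

# basis matrix (length(idx) x terms) at linear voxel indices idx of a grid
poly_basis_at <- function(dims, idx, exponents) {
  nx <- dims[1]; ny <- dims[2]
  i0 <- (idx - 1L) %% nx
  j0 <- ((idx - 1L) %/% nx) %% ny
  k0 <- (idx - 1L) %/% (nx * ny)
  cx <- norm_coords(dims[1])[i0 + 1L]
  cy <- norm_coords(dims[2])[j0 + 1L]
  cz <- norm_coords(dims[3])[k0 + 1L]
  B <- matrix(1, nrow = length(idx), ncol = nrow(exponents))
  for (t in seq_len(nrow(exponents))) {
    e <- exponents[t, ]
    B[, t] <- cx^e[1] * cy^e[2] * cz^e[3]
  }
  B
}

# evaluate sum(coeffs * x^i y^j z^k) over the whole grid, term by term
eval_poly_field <- function(dims, coeffs, exponents) {
  stopifnot(length(coeffs) == nrow(exponents))
  cx <- norm_coords(dims[1]); cy <- norm_coords(dims[2]); cz <- norm_coords(dims[3])
  out <- array(0, dim = dims)
  for (t in seq_along(coeffs)) {
    if (coeffs[t] == 0) next
    e <- exponents[t, ]
    xy <- outer(cx^e[1], cy^e[2])
    out <- out + coeffs[t] * (as.vector(xy) * rep(cz^e[3], each = dims[1] * dims[2]))
  }
  out
}

# degree implied by a coefficient vector length, erroring on impossible lengths
degree_from_length <- function(n) {
  for (d in 0:10) if (n_poly_terms(d) == n) return(d)
  stop("coefficient vector length ", n,
       " does not match a complete trivariate basis", call. = FALSE)
}
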
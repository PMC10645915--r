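# Internal helpers: reproducible seed derivation and separable Gaussian
# convolution used by the PSF and scatter models.

# Derive a child seed < 2^31 - 1 from a parent seed plus mixed tags
# (integers or strings). Deterministic, no global RNG state touched.
derive_seed <- function(seed, ...) {
  tags <- list(...)
  x <- as.numeric(seed) %% 2147483647
  mix <- function(x, k) (x * 69069 + k + 1) %% 2147483647
  for (tag in tags) {
    if (is.character(tag)) {
      for (k in utf8ToInt(tag)) x <- mix(x, k)
    } else {
      x <- mix(x, as.numeric(tag))
    }
  }
  as.integer(x %% 2147483646) + 1L
}

# Truncated, normalized 1D Gaussian kernel; sigma in voxel units.
gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

# n x n dense band matrix applying the kernel with zero padding.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - r):(j + r)
    keep <- idx >= 1L & idx <= n
    K[idx[keep], j] <- kernel[keep]
  }
  K
}

# Convolve a 3D array along one axis with a 1D kernel (zero padding).
conv_along_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  if (n == 1L) return(arr)
  K <- conv_matrix(n, kernel)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  out <- K %*% m
  aperm(array(out, dim = d[perm]), order(perm))
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
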
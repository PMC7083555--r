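#' Convert a Gaussian FWHM to its standard deviation
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, the standard conversion used for
#' image smoothing kernels.
#'
#' @param fwhm full width at half maximum (any length unit).
#' @return standard deviation in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1D discrete Gaussian convolution matrix with reflecting boundaries.
# Rows sum to 1 (mean-preserving for constant fields).
conv_matrix_1d <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  w <- dnorm(seq(-r, r), sd = sigma_vox)
  w <- w / sum(w)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq(-r, r)) {
      j <- i + k
      # mirror about the half-sample boundary: ... 2 1 | 1 2 ... n-1 n | n n-1 ...
      while (j < 1L || j > n) {
        if (j < 1L) j <- 1L - j
        if (j > n) j <- 2L * n + 1L - j
      }
      M[i, j] <- M[i, j] + w[k + r + 1L]
    }
  }
  M
}

# Apply a matrix along one dimension of a 3D array.
apply_along <- function(arr, M, dim_index) {
  d <- dim(arr)
  perm <- switch(dim_index, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- M %*% matrix(a, nrow = da[1])
  dim(a) <- da
  aperm(a, order(perm))
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Discrete separable Gaussian with reflecting boundary handling;
#' `sigma = fwhm_to_sigma(fwhm) / voxel_size` voxels per axis.
#'
#' @param arr 3D numeric array.
#' @param fwhm smoothing FWHM in mm.
#' @param voxel_size voxel edge in mm.
#' @return smoothed array of the same dimension.
#' @export
gaussian_smooth <- function(arr, fwhm, voxel_size = 1) {
  stopifnot(length(dim(arr)) == 3)
  if (fwhm <= 0) return(arr)
  sigma_vox <- fwhm_to_sigma(fwhm) / voxel_size
  d <- dim(arr)
  for (ax in 1:3) arr <- apply_along(arr, conv_matrix_1d(d[ax], sigma_vox), ax)
  arr
}

# Per-voxel standard-deviation field of smoothed unit white noise:
# outer product of the row sums of squared 1D weights. Used to renormalise
# the smoothed noise so its marginal sd equals the configured value exactly.
smoothing_sd_field <- function(grid_shape, fwhm, voxel_size) {
  if (fwhm <= 0) return(array(1, dim = grid_shape))
  sigma_vox <- fwhm_to_sigma(fwhm) / voxel_size
  rs <- lapply(grid_shape, function(n) rowSums(conv_matrix_1d(n, sigma_vox)^2))
  sqrt(outer(outer(rs[[1]], rs[[2]]), rs[[3]]))
}
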
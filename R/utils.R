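#' @useDynLib tonodepth, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif fft sd quantile rmultinom qnorm pnorm
#' @importFrom utils write.csv read.csv
NULL

# Run code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Half-up rounding
#'
#' Report-display rounding: halves round away from zero toward the next
#' value up, unlike `round()`'s round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Voxel-center coordinates of a grid
#'
#' Physical positions of voxel centers for a regular isotropic grid, with
#' the convention that voxel `i` (1-based) is centered at `(i - 0.5) *
#' voxel_size` along each axis (x = right, y = anterior, z = superior).
#'
#' @param dim integer vector of grid extents (voxels per axis).
#' @param voxel_size isotropic voxel edge length in mm.
#' @return A 3-column matrix of voxel-center coordinates in mm, in array
#'   (column-major) order.
#' @export
voxel_centers <- function(dim, voxel_size) {
  stopifnot(length(dim) == 3)
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                   z = seq_len(dim[3]))
  (as.matrix(g) - 0.5) * voxel_size
}

# 1-D Gaussian convolution matrix with edge renormalization (rows sum to
# one, so constants are preserved).
gauss_band <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  h <- ceiling(4 * sigma_vox)
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma_vox^2))
  K[abs(outer(idx, idx, "-")) > h] <- 0
  K / rowSums(K)
}

#' Gaussian blur of a 3-D volume
#'
#' Separable Gaussian smoothing with an edge-renormalized kernel, used for
#' the spatial-smoothing control analysis and for the smoothed gain field
#' in homomorphic normalization.
#'
#' @param vol 3-D numeric array.
#' @param fwhm_mm kernel full width at half maximum, mm.
#' @param voxel_size voxel edge length, mm.
#' @return Blurred array of the same dimensions.
#' @export
gaussian_blur <- function(vol, fwhm_mm, voxel_size) {
  stopifnot(length(dim(vol)) == 3, fwhm_mm >= 0)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  out <- vol
  for (ax in 1:3) {
    K <- gauss_band(d[ax], sigma)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(out, perm), nrow = d[ax])
    m <- K %*% m
    out <- aperm(array(m, d[perm]), order(perm))
  }
  out
}

# Orthonormal DCT-II basis matrix (columns are basis vectors); component k
# (0-based) completes k/2 cycles over the window.
dct_basis <- function(n) {
  k <- 0:(n - 1)
  t <- 0:(n - 1)
  B <- cos(pi * outer(2 * t + 1, k) / (2 * n))
  B[, 1] <- B[, 1] / sqrt(2)
  B * sqrt(2 / n)
}
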
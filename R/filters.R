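## Separable Gaussian filtering with reflected borders, used by the phantom
## renderer (PSF emulation) and the unsharp sharpening mask.

.blur_cache <- new.env(parent = emptyenv())

# Dense n x n convolution matrix for a 1-D Gaussian (reflected borders).
gauss_blur_mat <- function(n, sigma) {
  key <- paste(n, signif(sigma, 10))
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g <- g / sum(g)
  M <- matrix(0, n, n)
  for (k in seq(-r, r)) {
    j <- seq_len(n) + k
    j[j < 1L] <- 2L - j[j < 1L]          # reflect
    j[j > n] <- 2L * n - j[j > n]
    j <- pmin(pmax(j, 1L), n)
    M[cbind(seq_len(n), j)] <- M[cbind(seq_len(n), j)] + g[k + r + 1L]
  }
  .blur_cache[[key]] <- M
  M
}

# 2-D Gaussian blur of a (y, x) matrix.
gauss_blur_2d <- function(m, sigma_y, sigma_x = sigma_y) {
  if (sigma_y > 0) m <- gauss_blur_mat(nrow(m), sigma_y) %*% m
  if (sigma_x > 0) m <- m %*% t(gauss_blur_mat(ncol(m), sigma_x))
  m
}

# Anisotropic Gaussian blur of a (z, y, x) volume; sigmas in voxel units.
gauss_blur_vol <- function(vol, sigma_z, sigma_y, sigma_x) {
  d <- dim(vol)
  if (sigma_z > 0) {
    M <- gauss_blur_mat(d[1], sigma_z)
    vol <- array(M %*% matrix(vol, d[1], d[2] * d[3]), dim = d)
  }
  if (sigma_y > 0 || sigma_x > 0) {
    for (z in seq_len(d[1])) {
      vol[z, , ] <- gauss_blur_2d(vol[z, , ], sigma_y, sigma_x)
    }
  }
  vol
}
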
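# Shared fixtures and independent oracles, generated in code at test time.

# Small random stack (z, y, x, c).
rand_stack <- function(z = 2, y = 12, x = 12, c = 2, seed = 1) {
  set.seed(seed)
  array(rnorm(z * y * x * c), dim = c(z, y, x, c))
}

# Brute-force windowed mean / population-sd oracle (clipped borders).
brute_local_stats <- function(stack, kernel) {
  d <- dim(stack)
  mu <- array(0, dim = d); sg <- mu
  rz <- (kernel[1] - 1) / 2; ry <- (kernel[2] - 1) / 2; rx <- (kernel[3] - 1) / 2
  for (ci in seq_len(d[4])) for (z in seq_len(d[1]))
    for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      w <- stack[max(1, z - rz):min(d[1], z + rz),
                 max(1, y - ry):min(d[2], y + ry),
                 max(1, x - rx):min(d[3], x + rx), ci]
      mu[z, y, x, ci] <- mean(w)
      sg[z, y, x, ci] <- sqrt(mean((w - mean(w))^2))
    }
  list(mu = mu, sigma = sg)
}

# Brute-force windowed SSIM oracle: explicit loops over every valid window.
brute_ssim_2d <- function(X, Y, C1 = 1e-4, C2 = 9e-4, win = 11, sigma = 1.5) {
  r <- (win - 1) / 2
  g1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  W <- outer(g1, g1)
  h <- nrow(X); w <- ncol(X)
  vals <- c()
  for (i in seq_len(h - win + 1)) for (j in seq_len(w - win + 1)) {
    px <- X[i:(i + win - 1), j:(j + win - 1)]
    py <- Y[i:(i + win - 1), j:(j + win - 1)]
    ux <- sum(W * px); uy <- sum(W * py)
    vx <- sum(W * px^2) - ux^2; vy <- sum(W * py^2) - uy^2
    cxy <- sum(W * px * py) - ux * uy
    vals <- c(vals, ((2 * ux * uy + C1) * (2 * cxy + C2)) /
                ((ux^2 + uy^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

# Draw a horizontal bar of given width (px) and length (px) into a canvas.
draw_bar <- function(size = 64, len = 50, width = 3, row = NULL, col0 = NULL) {
  img <- matrix(0, size, size)
  if (is.null(row)) row <- size %/% 2
  if (is.null(col0)) col0 <- (size - len) %/% 2 + 1
  half <- (width - 1) %/% 2
  img[(row - half):(row + half), col0:(col0 + len - 1)] <- 1
  img
}

# Phantom spec small and fast for unit tests.
tiny_phantom <- function(seed = 1, n_fibers = 8L, ...) {
  phantom_spec(shape = c(8L, 64L, 64L), n_fibers = n_fibers, seed = seed, ...)
}

# Z-score normalize with the reference sliding window.
norm_stack <- function(stack, kernel = c(1L, 31L, 31L)) {
  zscore_normalize(stack, local_stats(stack, kernel))
}
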
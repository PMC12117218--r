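## Hybrid training loss and evaluation metrics.
##
## The loss on a ground-truth/prediction pair is
##   L = (1/N) sum |y - yhat|  +  alpha * (1/N) sum |y - yhat|^3
##       + beta * (1 - SSIM(y, yhat)),
## with N the voxel count. The L1 term keeps gradients stable and errors
## sparse; the L3 term penalizes outliers early in training; the SSIM term
## adds windowed perceptual structure. SSIM is computed in 2D per z-slice
## (Gaussian 11x11 window, sigma 1.5, stabilizers C1=(0.01 L)^2,
## C2=(0.03 L)^2) and averaged across slices; inside the loss the pair is
## jointly min-max rescaled to [0,1] for the SSIM term only (the rescale is
## treated as constant under differentiation), while the Lp terms act on raw
## Z-scored values.

#' Loss hyperparameters
#'
#' @param alpha Weight of the cubic (`p = 3`) term; default `1e-1`.
#' @param beta Weight of the structural `1 - SSIM` term; default `1e-4`.
#' @param ssim_window Odd SSIM window size; default 11.
#' @param ssim_sigma Gaussian width of the window; default 1.5.
#' @param dynamic_range Dynamic range `L` entering the SSIM stabilizers
#'   (inputs to SSIM are `[0,1]`-scaled, so default 1).
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(alpha = 1e-1, beta = 1e-4, ssim_window = 11L,
                      ssim_sigma = 1.5, dynamic_range = 1) {
  stopifnot(alpha >= 0, beta >= 0, ssim_window %% 2L == 1L, ssim_sigma > 0,
            dynamic_range > 0)
  structure(list(alpha = alpha, beta = beta,
                 ssim_window = as.integer(ssim_window),
                 ssim_sigma = ssim_sigma, dynamic_range = dynamic_range,
                 C1 = (0.01 * dynamic_range)^2, C2 = (0.03 * dynamic_range)^2),
            class = "loss_spec")
}

#' Mean p-th power absolute error
#'
#' `(1/N) * sum(|y - yhat|^p)` over all voxels.
#'
#' @param y,yhat Equal-shaped numeric arrays.
#' @param p Norm order, `>= 1`.
#' @return Non-negative scalar.
#' @export
lp_term <- function(y, yhat, p) {
  if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat))
    stop("shape mismatch")
  stopifnot(p >= 1)
  mean(abs(y - yhat)^p)
}

gauss_window <- function(size, sigma) {
  r <- (size - 1L) %/% 2L
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g / sum(g)
}

# Valid-convolution banded filter matrix: (n - size + 1) x n.
filt_band <- function(n, g) {
  m <- length(g)
  if (n < m) stop("SSIM window larger than slice")
  out <- matrix(0, n - m + 1L, n)
  for (j in seq_along(g)) out[cbind(seq_len(n - m + 1L),
                                    seq_len(n - m + 1L) + j - 1L)] <- g[j]
  out
}

# SSIM of one 2D slice pair, optionally with the analytic gradient w.r.t. Y
# (the prediction). Gaussian-windowed local statistics, valid support.
ssim_slice <- function(X, Y, C1, C2, g, want_grad = FALSE) {
  Gy <- filt_band(nrow(X), g)
  Gx <- filt_band(ncol(X), g)
  f <- function(M) Gy %*% M %*% t(Gx)
  ux <- f(X); uy <- f(Y)
  fxx <- f(X * X); fyy <- f(Y * Y); fxy <- f(X * Y)
  sxx <- fxx - ux^2; syy <- fyy - uy^2; sxy <- fxy - ux * uy
  A1 <- 2 * ux * uy + C1; A2 <- 2 * sxy + C2
  B1 <- ux^2 + uy^2 + C1; B2 <- sxx + syy + C2
  S <- (A1 * A2) / (B1 * B2)
  val <- mean(S)
  if (!want_grad) return(list(value = val))
  N <- length(S)
  dS_dfxy <- 2 * A1 / (B1 * B2)
  dS_dfyy <- -(A1 * A2) / (B1 * B2^2)
  dS_duy <- 2 * ux * A2 / (B1 * B2) - 2 * uy * S / B1 -
    2 * uy * dS_dfyy - ux * dS_dfxy
  fb <- function(P) t(Gy) %*% P %*% Gx # adjoint of the valid filter
  grad <- (fb(dS_duy) + 2 * Y * fb(dS_dfyy) + X * fb(dS_dfxy)) / N
  list(value = val, grad = grad)
}

# Iterate (n, z) slices of volumes shaped (z,y,x), (z,y,x,1) or (n,z,y,x,1).
slice_list <- function(v) {
  d <- dim(v)
  if (length(d) == 2L) return(list(v))
  if (length(d) == 3L) return(lapply(seq_len(d[1]), function(z) v[z, , ]))
  if (length(d) == 4L) return(lapply(seq_len(d[1]), function(z) v[z, , , 1L]))
  out <- list()
  for (ni in seq_len(d[1])) for (z in seq_len(d[2]))
    out[[length(out) + 1L]] <- v[ni, z, , , 1L]
  out
}

#' Structural similarity index
#'
#' Standard Gaussian-windowed SSIM computed in 2D on each z-slice and averaged
#' over slices. Symmetric in its arguments; 1 exactly at equality. Inputs are
#' expected on the scale declared by `spec$dynamic_range` (rescale to `[0,1]`
#' for the default).
#'
#' @param y,yhat Equal-shaped volumes (`(y,x)`, `(z,y,x)`, `(z,y,x,1)` or
#'   `(n,z,y,x,1)`).
#' @param spec A [loss_spec()] (window/stabilizer parameters).
#' @return Scalar in `[-1, 1]`.
#' @export
ssim_index <- function(y, yhat, spec = loss_spec()) {
  if (!identical(dim(y), dim(yhat))) stop("shape mismatch")
  g <- gauss_window(spec$ssim_window, spec$ssim_sigma)
  sy <- slice_list(y); sh <- slice_list(yhat)
  mean(vapply(seq_along(sy), function(i)
    ssim_slice(sy[[i]], sh[[i]], spec$C1, spec$C2, g)$value, numeric(1)))
}

# Joint [0,1] min-max rescale of a pair; constant (or non-finite, so the
# Lp terms can surface the diagnostic) pairs map to zeros.
joint_minmax <- function(y, yhat) {
  lo <- min(y, yhat); hi <- max(y, yhat)
  rng <- hi - lo
  if (!is.finite(rng) || rng == 0) {
    list(y = y * 0, yhat = yhat * 0, scale = 0)
  } else {
    list(y = (y - lo) / rng, yhat = (yhat - lo) / rng, scale = 1 / rng)
  }
}

#' Hybrid L1 + alpha L3 + beta (1 - SSIM) loss
#'
#' @param y Ground-truth volume.
#' @param yhat Predicted volume, same shape.
#' @param spec A [loss_spec()].
#' @param want_grad If `TRUE`, also return the gradient w.r.t. `yhat`.
#' @return `list(value, grad?)`; `value >= 0`, exactly 0 at `y == yhat`.
#' @export
hybrid_loss <- function(y, yhat, spec = loss_spec(), want_grad = FALSE) {
  if (!identical(dim(y), dim(yhat))) stop("shape mismatch")
  diff <- yhat - y
  N <- length(y)
  l1 <- mean(abs(diff))
  l3 <- mean(abs(diff)^3)
  g <- gauss_window(spec$ssim_window, spec$ssim_sigma)
  sc <- joint_minmax(y, yhat)
  sy <- slice_list(sc$y); sh <- slice_list(sc$yhat)
  ns <- length(sy)
  vals <- numeric(ns)
  grads <- if (want_grad) vector("list", ns) else NULL
  for (i in seq_len(ns)) {
    r <- ssim_slice(sy[[i]], sh[[i]], spec$C1, spec$C2, g,
                    want_grad = want_grad)
    vals[i] <- r$value
    if (want_grad) grads[[i]] <- r$grad
  }
  ssim <- mean(vals)
  value <- l1 + spec$alpha * l3 + spec$beta * (1 - ssim)
  if (!want_grad) return(list(value = value))
  grad <- sign(diff) / N + spec$alpha * 3 * diff^2 * sign(diff) / N
  # scatter per-slice SSIM gradients back into the volume
  d <- dim(yhat)
  gvol <- array(0, dim = d)
  i <- 0L
  if (length(d) == 2L) {
    gvol <- grads[[1]]
  } else if (length(d) == 3L) {
    for (z in seq_len(d[1])) gvol[z, , ] <- grads[[z]]
  } else if (length(d) == 4L) {
    for (z in seq_len(d[1])) gvol[z, , , 1L] <- grads[[z]]
  } else {
    for (ni in seq_len(d[1])) for (z in seq_len(d[2])) {
      i <- i + 1L
      gvol[ni, z, , , 1L] <- grads[[i]]
    }
  }
  grad <- grad - spec$beta * gvol * sc$scale / ns
  list(value = value, grad = grad)
}

# Independent [0,1] min-max rescale; constant volumes map to zeros.
minmax01 <- function(v) {
  rng <- range(v)
  if (rng[2] == rng[1]) return(v * 0)
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Mean squared error on [0,1]-rescaled volumes
#'
#' Both volumes are independently min-max rescaled to `[0,1]` before the mean
#' squared difference, matching the evaluation convention of the image-quality
#' metrics ([psnr()], [ssim_index()], [spearman_rho()]).
#'
#' @param y,yhat Equal-shaped volumes.
#' @return Non-negative scalar.
#' @export
mse <- function(y, yhat) {
  if (!identical(dim(y), dim(yhat))) stop("shape mismatch")
  mean((minmax01(y) - minmax01(yhat))^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `-10 * log10(MSE)` for unit dynamic range; `+Inf` when the volumes agree
#' exactly.
#'
#' @inheritParams mse
#' @return Scalar in dB (possibly `Inf`).
#' @export
psnr <- function(y, yhat) {
  m <- mse(y, yhat)
  if (m == 0) Inf else -10 * log10(m)
}

#' Spearman rank correlation over all voxels
#'
#' Average-rank tie handling; invariant to monotone intensity maps. Returns
#' `NA` when either volume is constant (correlation undefined).
#'
#' @inheritParams mse
#' @return Scalar in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(y, yhat) {
  if (!identical(dim(y), dim(yhat))) stop("shape mismatch")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) return(NA_real_)
  stats::cor(as.vector(y), as.vector(yhat), method = "spearman")
}

metric_vector <- function(gy, gh, spec) {
  m <- mean((gy - gh)^2)
  c(mse = m,
    ssim = ssim_index(gy, gh, spec),
    psnr = if (m == 0) Inf else -10 * log10(m),
    spearman = if (stats::sd(gy) == 0 || stats::sd(gh) == 0) NA_real_ else
      stats::cor(as.vector(gy), as.vector(gh), method = "spearman"))
}

sd_or_zero <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  if (all(v == v[1])) return(0) # constant (incl. all-Inf) spread is zero
  stats::sd(v)
}

#' Bootstrap image-quality metrics over overlapping random patches
#'
#' Both volumes are min-max rescaled to `[0,1]` once, then `n_patches`
#' uniformly random patch origins are drawn with replacement (overlap
#' allowed) and MSE, SSIM, PSNR and Spearman's rho are computed per patch;
#' the report carries each metric's mean and standard deviation.
#'
#' @param gt,pred Equal-shaped `(z, y, x)` (or single-channel 4-D) volumes.
#' @param n_patches Number of bootstrap patches (the full-scale protocol uses
#'   10000; scale down for small volumes).
#' @param patch Patch extents `(z, y, x)`; default `c(15, 100, 100)`.
#' @param seed Integer seed; identical seeds give identical reports.
#' @param spec [loss_spec()] supplying the SSIM window.
#' @return A `metric_report`: data frame with columns `metric`, `mean`, `sd`,
#'   plus attributes `n_patches` and `patch`.
#' @export
bootstrap_metrics <- function(gt, pred, n_patches = 10000L,
                              patch = c(15L, 100L, 100L), seed = 1L,
                              spec = loss_spec()) {
  gt <- drop_to_3d(gt); pred <- drop_to_3d(pred)
  if (!identical(dim(gt), dim(pred))) stop("shape mismatch")
  d <- dim(gt); patch <- as.integer(patch)
  if (any(patch > d)) stop("patch larger than volume")
  gy <- minmax01(gt); gh <- minmax01(pred)
  set.seed(as.integer(seed))
  oz <- sample.int(d[1] - patch[1] + 1L, n_patches, replace = TRUE)
  oy <- sample.int(d[2] - patch[2] + 1L, n_patches, replace = TRUE)
  ox <- sample.int(d[3] - patch[3] + 1L, n_patches, replace = TRUE)
  vals <- matrix(NA_real_, n_patches, 4L,
                 dimnames = list(NULL, c("mse", "ssim", "psnr", "spearman")))
  for (i in seq_len(n_patches)) {
    pz <- oz[i]:(oz[i] + patch[1] - 1L)
    py <- oy[i]:(oy[i] + patch[2] - 1L)
    px <- ox[i]:(ox[i] + patch[3] - 1L)
    vals[i, ] <- metric_vector(gy[pz, py, px], gh[pz, py, px], spec)
  }
  rep <- data.frame(
    metric = colnames(vals),
    mean = apply(vals, 2L, function(v) mean(v[!is.na(v)])),
    sd = apply(vals, 2L, sd_or_zero),
    row.names = NULL)
  attr(rep, "n_patches") <- n_patches
  attr(rep, "patch") <- patch
  class(rep) <- c("metric_report", "data.frame")
  rep
}

drop_to_3d <- function(v) {
  d <- dim(v)
  if (length(d) == 4L && d[4] == 1L) dim(v) <- d[1:3]
  v
}
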
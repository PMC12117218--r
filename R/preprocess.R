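## Spatially localized Z-score normalization and patch/cohort assembly.
##
## Raw confocal stacks mix slowly varying illumination gradients (and the RCM
## central bright spot) with the fine fiber signal. A sliding-window Z-score
## removes the local mean and rescales by the local standard deviation, giving
## dimensionless, locally equalized intensities. Window statistics are taken
## over the centered window *clipped to the image* (no padding, so no
## fabricated intensities at borders), per channel and per slice.

# Clipped-window box sums of a (y, x) matrix via summed-area tables.
# Returns list(sum, count) matrices of the same shape.
box_sums_2d <- function(m, ky, kx) {
  h <- nrow(m); w <- ncol(m)
  ry <- (ky - 1L) %/% 2L; rx <- (kx - 1L) %/% 2L
  # SAT padded with a leading zero row/col
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  y0 <- pmax(seq_len(h) - ry, 1L); y1 <- pmin(seq_len(h) + ry, h)
  x0 <- pmax(seq_len(w) - rx, 1L); x1 <- pmin(seq_len(w) + rx, w)
  sums <- S[y1 + 1L, x1 + 1L] - S[y0, x1 + 1L] - S[y1 + 1L, x0] + S[y0, x0]
  counts <- outer(y1 - y0 + 1L, x1 - x0 + 1L)
  list(sum = sums, count = counts)
}

#' Sliding-window local mean and standard deviation maps
#'
#' At every voxel, the mean and population standard deviation of the raw
#' intensities inside a centered `(kz, ky, kx)` window, intersected with the
#' image bounds, per channel (the default window `(1, 101, 101)` is per-slice).
#' These maps drive [zscore_normalize()].
#'
#' @param stack Numeric `(z, y, x, c)` array.
#' @param kernel Integer window extents `(kz, ky, kx)`, all odd and positive.
#'   Default `c(1, 101, 101)`.
#' @param stride Integer strides `(z, y, x)`. With the default `(1, 1, 1)` the
#'   maps have the shape of the input; larger strides subsample the evaluation
#'   grid (such maps cannot feed [zscore_normalize()] directly).
#' @return `list(mu, sigma)` arrays; `sigma >= 0` everywhere.
#' @export
local_stats <- function(stack, kernel = c(1L, 101L, 101L),
                        stride = c(1L, 1L, 1L)) {
  stack <- as_stack(stack)
  kernel <- as.integer(kernel); stride <- as.integer(stride)
  stopifnot(length(kernel) == 3L, length(stride) == 3L, all(stride >= 1L))
  if (any(kernel <= 0L) || any(kernel %% 2L == 0L))
    stop("kernel dims must be odd and positive")
  d <- dim(stack)
  if (any(kernel > d[1:3]))
    stop("kernel exceeds image extent in at least one dimension")
  if (all(kernel == 1L) && all(stride == 1L)) {
    # degenerate single-voxel windows: exact, no round-off
    return(list(mu = stack, sigma = array(0, dim = d)))
  }

  zs <- seq(1L, d[1], by = stride[1])
  ys <- seq(1L, d[2], by = stride[2])
  xs <- seq(1L, d[3], by = stride[3])
  mu <- array(0, dim = c(length(zs), length(ys), length(xs), d[4]))
  sg <- mu
  rz <- (kernel[1] - 1L) %/% 2L
  for (ci in seq_len(d[4])) {
    # per-slice 2-D box sums, then a clipped running sum across z
    s1 <- lapply(seq_len(d[1]), function(zi)
      box_sums_2d(stack[zi, , , ci], kernel[2], kernel[3]))
    s2 <- lapply(seq_len(d[1]), function(zi)
      box_sums_2d(stack[zi, , , ci]^2, kernel[2], kernel[3]))
    for (oi in seq_along(zs)) {
      zi <- zs[oi]
      zwin <- max(1L, zi - rz):min(d[1], zi + rz)
      ssum <- Reduce(`+`, lapply(zwin, function(z) s1[[z]]$sum))
      qsum <- Reduce(`+`, lapply(zwin, function(z) s2[[z]]$sum))
      cnt <- s1[[zi]]$count * length(zwin)
      m <- ssum / cnt
      v <- pmax(qsum / cnt - m^2, 0) # guard tiny negative round-off
      mu[oi, , , ci] <- m[ys, xs]
      sg[oi, , , ci] <- sqrt(v)[ys, xs]
    }
  }
  list(mu = mu, sigma = sg)
}

#' Z-score normalization against local statistics
#'
#' Computes `N = (R - mu) / max(sigma, sigma_floor)` voxel-wise. The floor
#' keeps the output finite in zero-variance windows, where constant regions
#' map to exactly 0. The transform is invariant to affine intensity changes
#' `a * R + b` (a > 0) wherever `sigma` dominates the floor.
#'
#' @param stack Numeric `(z, y, x, c)` array of raw intensities.
#' @param stats `list(mu, sigma)` from [local_stats()] at stride `(1, 1, 1)`.
#' @param sigma_floor Positive scalar; default `1e-6` times the global
#'   intensity range of `stack` (or `1e-6` for a constant stack).
#' @return Normalized `(z, y, x, c)` array of dimensionless Z-scores.
#' @export
zscore_normalize <- function(stack, stats, sigma_floor = NULL) {
  stack <- as_stack(stack)
  if (!identical(dim(stack), dim(stats$mu)) ||
      !identical(dim(stack), dim(stats$sigma)))
    stop("stats shape does not match stack")
  if (is.null(sigma_floor)) {
    rng <- diff(range(stack))
    sigma_floor <- if (rng > 0) 1e-6 * rng else 1e-6
  }
  stopifnot(sigma_floor > 0)
  n <- (stack - stats$mu) / pmax(stats$sigma, sigma_floor)
  if (!all(is.finite(n))) stop("normalization produced non-finite values")
  n
}

# Truncated, normalized 2-D Gaussian kernel of odd size `size`.
gaussian_kernel_2d <- function(sigma, size = 5L) {
  stopifnot(sigma > 0, size %% 2L == 1L)
  r <- (size - 1L) %/% 2L
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Same-size 2-D convolution with reflected borders.
conv2d_reflect <- function(m, k) {
  r <- (nrow(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  iy <- c(rev(seq_len(r) + 1L), seq_len(h), h - seq_len(r))
  ix <- c(rev(seq_len(r) + 1L), seq_len(w), w - seq_len(r))
  mp <- m[iy, ix]
  out <- matrix(0, h, w)
  for (dy in seq_len(nrow(k))) for (dx in seq_len(ncol(k))) {
    out <- out + k[dy, dx] * mp[dy + seq_len(h) - 1L, dx + seq_len(w) - 1L]
  }
  out
}

#' Blur the transmission channel
#'
#' Convolves the transmission channel, slice by slice, with a normalized
#' truncated `size x size` Gaussian kernel; all other channels are returned
#' unchanged. Emulates the resolution loss of thick or dense scaffolds and
#' feeds the blur-ablation experiments (`sigma` of 1, 3 or 5).
#'
#' @param stack Numeric `(z, y, x, c)` array.
#' @param meta [stack_meta()]; a channel named `"Tra"` must exist.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param kernel_size Odd kernel extent; default 5.
#' @return The stack with a blurred transmission channel.
#' @export
blur_transmission <- function(stack, meta, sigma, kernel_size = 5L) {
  stack <- as_stack(stack)
  stopifnot(sigma > 0)
  ti <- channel_index(meta, "Tra")
  k <- gaussian_kernel_2d(sigma, kernel_size)
  for (zi in seq_len(dim(stack)[1])) {
    stack[zi, , , ti] <- conv2d_reflect(stack[zi, , , ti], k)
  }
  stack
}

#' Tile a stack into full-depth training patches
#'
#' Non-overlapping `(tile_y, tile_x)` tiling of the `(y, x)` plane; the full z
#' extent (and all channels) of the source is preserved in every patch so
#' axially oriented features survive. Remainder rows/columns that do not fill
#' a whole tile are dropped.
#'
#' @param stack Numeric `(z, y, x, c)` array (typically normalized).
#' @param tile Integer `(tile_y, tile_x)`; default `c(256, 256)`.
#' @param source_id Label of the originating sample (cohort bookkeeping).
#' @return An object of class `patch_set`: list with `patches` (list of
#'   `(z, ty, tx, c)` arrays), `origins` (matrix of 1-based `(y, x)` corners)
#'   and `source_id`.
#' @export
tile_stack <- function(stack, tile = c(256L, 256L), source_id = "sample1") {
  stack <- as_stack(stack)
  tile <- as.integer(tile)
  d <- dim(stack)
  if (any(tile > d[2:3])) stop("tile larger than image")
  ny <- d[2] %/% tile[1]; nx <- d[3] %/% tile[2]
  patches <- vector("list", ny * nx)
  origins <- matrix(0L, ny * nx, 2L, dimnames = list(NULL, c("y", "x")))
  k <- 0L
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    k <- k + 1L
    oy <- (iy - 1L) * tile[1] + 1L; ox <- (ix - 1L) * tile[2] + 1L
    patches[[k]] <- stack[, oy:(oy + tile[1] - 1L), ox:(ox + tile[2] - 1L), ,
                          drop = FALSE]
    origins[k, ] <- c(oy, ox)
  }
  structure(list(patches = patches, origins = origins, source_id = source_id,
                 tile = tile),
            class = "patch_set")
}

#' Reassemble a tiling produced by [tile_stack()]
#'
#' Exact inverse of [tile_stack()] for inputs whose extents divide the tile
#' size (dropped remainders cannot be recovered).
#'
#' @param ps A `patch_set`.
#' @return The `(z, y, x, c)` array covered by the tiles.
#' @export
stitch_tiles <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  tile <- ps$tile
  ymax <- max(ps$origins[, "y"]) + tile[1] - 1L
  xmax <- max(ps$origins[, "x"]) + tile[2] - 1L
  d <- dim(ps$patches[[1]])
  out <- array(0, dim = c(d[1], ymax, xmax, d[4]))
  for (k in seq_along(ps$patches)) {
    oy <- ps$origins[k, "y"]; ox <- ps$origins[k, "x"]
    out[, oy:(oy + tile[1] - 1L), ox:(ox + tile[2] - 1L), ] <- ps$patches[[k]]
  }
  out
}

#' Assemble sample-disjoint training cohorts
#'
#' Assigns whole samples (never individual patches) to cohorts, so no patch
#' of any sample can appear in more than one of train/val/test. Mirrors the
#' acquisition design: distinct fibrin scaffold samples for training, an
#' independent sample for validation, and a further independent one for test.
#'
#' @param patchsets List of `patch_set` objects with unique `source_id`s.
#' @param assignment Named character vector mapping each `source_id` to one of
#'   `"train"`, `"val"`, `"test"`.
#' @return `list(train, val, test)`, each a list of patches (possibly empty).
#' @export
split_cohorts <- function(patchsets, assignment) {
  ids <- vapply(patchsets, function(p) p$source_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate source ids")
  if (!all(ids %in% names(assignment)))
    stop("assignment does not cover every source sample")
  cohorts <- assignment[ids]
  if (!all(cohorts %in% c("train", "val", "test")))
    stop("cohort labels must be train/val/test")
  if (anyDuplicated(names(assignment)))
    stop("a sample is assigned to two cohorts")
  out <- list(train = list(), val = list(), test = list())
  for (i in seq_along(patchsets)) {
    out[[cohorts[i]]] <- c(out[[cohorts[i]]], patchsets[[i]]$patches)
  }
  out
}
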
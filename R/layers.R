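## Differentiable layer primitives for the 3D encoder-decoder.
##
## Tensors are numeric arrays with axis order (n, z, y, x, c); because R is
## column-major and c is the slowest axis, a tensor reshapes to an
## (n*z*y*x) x c matrix for free, which every layer exploits. Convolutions are
## evaluated as im2col gathers followed by one matrix product; backward passes
## are the exact adjoints (scatter-add through the same index tables). All
## strides have z-component 1: depth is never downsampled, preserving axial
## fiber context.

# Promote a (z, y, x, c) patch to a batch of one.
as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) {
    dim(x) <- c(1L, d)
  } else if (length(d) != 5L) stop("expected (z,y,x,c) or (n,z,y,x,c)")
  x
}

# 3D convolution, kernel (kz,ky,kx), stride (1,sy,sx), zero padding (k-1)/2.
# W: (E*cin) x cout with rows grouped kernel-offset-major (cin rows per
# offset, offsets enumerated dz fastest); b: length cout. Hot loops live in
# src/conv3d.cpp.
conv3d_fwd <- function(x, W, b, kernel, stride, keep_xcol = FALSE) {
  d <- dim(x)
  r <- conv3d_forward_cpp(x, as.integer(d), W, b, as.integer(kernel),
                          as.integer(stride), keep_xcol)
  list(out = r$out, cache = list(x = x, Xcol = r$Xcol, in_dims = d,
                                 kernel = kernel, stride = stride, W = W))
}

conv3d_bwd <- function(cache, dout) {
  conv3d_backward_cpp(cache$x, as.integer(cache$in_dims), cache$W, dout,
                      as.integer(cache$kernel), as.integer(cache$stride),
                      cache$Xcol)
}

# Transposed convolution, kernel = stride = (1,2,2): each input voxel fans out
# to a 2x2 output block. W: cin x (4*cout), blocks ordered (dy,dx) in
# (0,0),(1,0),(0,1),(1,1); b: length cout.
convT_fwd <- function(x, W, b) {
  d <- dim(x)
  cin <- d[5]; cout <- ncol(W) %/% 4L
  Xmat <- matrix(x, prod(d[1:4]), cin)
  out <- array(0, dim = c(d[1], d[2], 2L * d[3], 2L * d[4], cout))
  for (k in 1:4) {
    dy_ <- c(0L, 1L, 0L, 1L)[k]; dx_ <- c(0L, 0L, 1L, 1L)[k]
    Yk <- Xmat %*% W[, (k - 1L) * cout + seq_len(cout), drop = FALSE]
    out[, , seq(1L + dy_, 2L * d[3], by = 2L),
        seq(1L + dx_, 2L * d[4], by = 2L), ] <-
      array(Yk, dim = c(d[1:4], cout))
  }
  out <- out + rep(b, each = prod(d[1:4]) * 4L)
  list(out = out, cache = list(Xmat = Xmat, in_dims = d, W = W))
}

convT_bwd <- function(cache, dout) {
  d <- cache$in_dims; W <- cache$W
  cin <- d[5]; cout <- ncol(W) %/% 4L
  Rr <- prod(d[1:4])
  dW <- matrix(0, cin, 4L * cout)
  dX <- matrix(0, Rr, cin)
  for (k in 1:4) {
    dy_ <- c(0L, 1L, 0L, 1L)[k]; dx_ <- c(0L, 0L, 1L, 1L)[k]
    dk <- dout[, , seq(1L + dy_, 2L * d[3], by = 2L),
               seq(1L + dx_, 2L * d[4], by = 2L), , drop = FALSE]
    dkm <- matrix(dk, Rr, cout)
    dW[, (k - 1L) * cout + seq_len(cout)] <- crossprod(cache$Xmat, dkm)
    dX <- dX + dkm %*% t(W[, (k - 1L) * cout + seq_len(cout), drop = FALSE])
  }
  db <- colSums(matrix(dout, length(dout) %/% cout, cout))
  dx <- dX
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# Nonstrided (1,2,2) average pooling, same extent; windows clipped at the
# right/bottom edge are count-normalized. Smooths zero-filled upsampling
# artifacts after transposed convolutions.
avgpool_fwd <- function(x) {
  d <- dim(x)
  y <- d[3]; xd <- d[4]
  xp <- array(0, dim = c(d[1], d[2], y + 1L, xd + 1L, d[5]))
  xp[, , seq_len(y), seq_len(xd), ] <- x
  cnt <- outer(c(rep(2L, y - 1L), 1L), c(rep(2L, xd - 1L), 1L))
  cnt_full <- rep(as.vector(cnt), each = d[1] * d[2])
  out <- (xp[, , seq_len(y), seq_len(xd), , drop = FALSE] +
          xp[, , seq_len(y) + 1L, seq_len(xd), , drop = FALSE] +
          xp[, , seq_len(y), seq_len(xd) + 1L, , drop = FALSE] +
          xp[, , seq_len(y) + 1L, seq_len(xd) + 1L, , drop = FALSE])
  out <- out / cnt_full
  list(out = out, cache = list(dims = d, cnt_full = cnt_full))
}

avgpool_bwd <- function(cache, dout) {
  d <- cache$dims
  y <- d[3]; xd <- d[4]
  dnorm <- dout / cache$cnt_full
  dp <- array(0, dim = c(d[1], d[2], y + 1L, xd + 1L, d[5]))
  dp[, , seq_len(y) + 1L, seq_len(xd) + 1L, ] <- dnorm
  dx <- dp[, , seq_len(y) + 1L, seq_len(xd) + 1L, , drop = FALSE] +
        dp[, , seq_len(y), seq_len(xd) + 1L, , drop = FALSE] +
        dp[, , seq_len(y) + 1L, seq_len(xd), , drop = FALSE] +
        dp[, , seq_len(y), seq_len(xd), , drop = FALSE]
  dim(dx) <- d
  list(dx = dx)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Batch normalization over (n,z,y,x) per feature channel.
bn_fwd <- function(x, gamma, beta, rmean, rvar, train) {
  d <- dim(x)
  M <- prod(d[1:4]); C <- d[5]
  xm <- matrix(x, M, C)
  if (train) {
    m <- colMeans(xm)
    v <- colMeans(xm^2) - m^2
    v <- pmax(v, 0)
    rmean <- (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * m
    rvar <- (1 - BN_MOMENTUM) * rvar + BN_MOMENTUM * v
  } else {
    m <- rmean; v <- rvar
  }
  s <- sqrt(v + BN_EPS)
  xhat <- (xm - rep(m, each = M)) / rep(s, each = M)
  out <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, s = s, gamma = gamma, dims = d, train = train),
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(cache, dout) {
  d <- cache$dims
  M <- prod(d[1:4]); C <- d[5]
  dym <- matrix(dout, M, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  if (cache$train) {
    t1 <- colMeans(dym)
    t2 <- colMeans(dym * cache$xhat)
    dx <- (dym - rep(t1, each = M) - cache$xhat * rep(t2, each = M)) *
      rep(cache$gamma / cache$s, each = M)
  } else {
    dx <- dym * rep(cache$gamma / cache$s, each = M)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask)
}

relu_bwd <- function(mask, dout) {
  dout[!mask] <- 0
  list(dx = dout)
}

attention_fwd <- function(x, w) {
  d <- dim(x)
  if (length(w) != d[5]) stop("one attention weight per channel required")
  M <- prod(d[1:4])
  out <- x * rep(w, each = M)
  list(out = out, cache = list(x = x, w = w, M = M, C = d[5]))
}

attention_bwd <- function(cache, dout) {
  dw <- colSums(matrix(dout * cache$x, cache$M, cache$C))
  dx <- dout * rep(cache$w, each = cache$M)
  list(dx = dx, dw = dw)
}

# Channel concatenation: free because c is the slowest axis.
concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:4] == db[1:4]))
  array(c(a, b), dim = c(da[1:4], da[5] + db[5]))
}

split_c <- function(x, c1) {
  d <- dim(x)
  list(a = x[, , , , seq_len(c1), drop = FALSE],
       b = x[, , , , c1 + seq_len(d[5] - c1), drop = FALSE])
}
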
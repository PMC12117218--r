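## The fully convolutional 3D encoder-decoder with per-channel attention.
##
## Architecture: a learnable scalar gate per input channel, then `levels`
## encoder pairs of (nonstrided block, strided (1,2,2) downsampling block),
## then a symmetric decoder of (transposed (1,2,2) convolution, nonstrided
## (1,2,2) average-pooling smoothing, batch norm, ReLU) stages with
## concatenated skip connections and a nonstrided block each, and a final
## linear 1x1x1 projection. A block is conv -> batch norm -> ReLU. Feature
## depth doubles per downsampling stage from the input channel count up to
## `max_channels`; spatial (y, x) dims halve per stage while z is preserved.

#' Architecture hyperparameters
#'
#' @param in_channels Number of input channels (default 4: three RCM
#'   wavelengths plus transmission).
#' @param out_channels Number of predicted channels (default 1: fluorescence).
#' @param levels Number of down/upsampling stages (default 4); `(y, x)` input
#'   dims must be divisible by `2^levels`.
#' @param max_channels Feature-depth cap (default 64).
#' @param conv_kernel Convolution kernel `(z, y, x)`, default `c(3, 3, 3)` —
#'   3D kernels supply the axial context that fiber recovery relies on.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(in_channels = 4L, out_channels = 1L, levels = 4L,
                       max_channels = 64L, conv_kernel = c(3L, 3L, 3L)) {
  stopifnot(in_channels >= 1L, out_channels >= 1L, levels >= 0L,
            max_channels >= in_channels,
            length(conv_kernel) == 3L, all(conv_kernel %% 2L == 1L))
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 levels = as.integer(levels),
                 max_channels = as.integer(max_channels),
                 conv_kernel = as.integer(conv_kernel)),
            class = "model_spec")
}

# Feature depth after k doubling stages.
channel_progression <- function(spec) {
  k <- seq_len(max(spec$levels, 1L))
  pmin(spec$in_channels * 2^k, spec$max_channels)
}

#' Scale each input channel by its attention weight
#'
#' Channel `c` of the output is `w[c]` times channel `c` of the input. During
#' training the weights receive gradients, so their converged values read out
#' the relative importance of each input modality.
#'
#' @param x Array `(z, y, x, c)` or `(n, z, y, x, c)`.
#' @param w Numeric vector, one weight per channel of `x`.
#' @return Scaled array, same shape as `x`.
#' @export
apply_channel_attention <- function(x, w) {
  squeeze <- length(dim(x)) == 4L
  xb <- as_batch(x)
  out <- attention_fwd(xb, w)$out
  if (squeeze) dim(out) <- dim(out)[-1]
  out
}

init_conv <- function(E_cin, cout, gain = 2) {
  matrix(stats::rnorm(E_cin * cout, 0, sqrt(gain / E_cin)), E_cin, cout)
}

#' Build a model with seeded parameter initialization
#'
#' @param spec A [model_spec()].
#' @param seed Integer RNG seed for weight initialization.
#' @return An object of class `fib_model` holding `spec`, `params` (named flat
#'   list of weight arrays, attention weights initialized to 1) and `state`
#'   (batch-norm running statistics).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(as.integer(seed))
  E <- prod(spec$conv_kernel)
  params <- list()
  state <- list()
  add_block <- function(name, cin, cout) {
    params[[paste0(name, ".W")]] <<- init_conv(E * cin, cout)
    params[[paste0(name, ".b")]] <<- numeric(cout)
    params[[paste0(name, ".g")]] <<- rep(1, cout)
    params[[paste0(name, ".be")]] <<- numeric(cout)
    state[[paste0(name, ".rm")]] <<- numeric(cout)
    state[[paste0(name, ".rv")]] <<- rep(1, cout)
  }
  params[["att.w"]] <- rep(1, spec$in_channels)
  prog <- channel_progression(spec)
  if (spec$levels == 0L) {
    add_block("mid", spec$in_channels, prog[1])
    top <- prog[1]
  } else {
    cin <- spec$in_channels
    for (k in seq_len(spec$levels)) {
      add_block(paste0("enc", k, "a"), cin, prog[k])
      add_block(paste0("enc", k, "b"), prog[k], prog[k])
      cin <- prog[k]
    }
    ccur <- prog[spec$levels]
    for (k in rev(seq_len(spec$levels))) {
      nm <- paste0("dec", k, "t")
      params[[paste0(nm, ".W")]] <- matrix(
        stats::rnorm(ccur * 4L * ccur, 0, sqrt(2 / ccur)), ccur, 4L * ccur)
      params[[paste0(nm, ".b")]] <- numeric(ccur)
      params[[paste0(nm, ".g")]] <- rep(1, ccur)
      params[[paste0(nm, ".be")]] <- numeric(ccur)
      state[[paste0(nm, ".rm")]] <- numeric(ccur)
      state[[paste0(nm, ".rv")]] <- rep(1, ccur)
      add_block(paste0("dec", k, "a"), ccur + prog[k], prog[k])
      ccur <- prog[k]
    }
    top <- ccur
  }
  params[["final.W"]] <- init_conv(top, spec$out_channels, gain = 1)
  params[["final.b"]] <- numeric(spec$out_channels)
  structure(list(spec = spec, params = params, state = state,
                 seed = as.integer(seed)),
            class = "fib_model")
}

#' @export
print.fib_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(paste0("<fib_model> %d -> %d channels, %d levels, ",
                     "max depth %d, %d parameters\n"),
              x$spec$in_channels, x$spec$out_channels, x$spec$levels,
              x$spec$max_channels, np))
  invisible(x)
}

# Conv -> BN -> ReLU block. Returns out, caches, updated running stats.
block_fwd <- function(x, model, name, stride, train) {
  p <- model$params; s <- model$state
  cv <- conv3d_fwd(x, p[[paste0(name, ".W")]], p[[paste0(name, ".b")]],
                   model$spec$conv_kernel, stride)
  bn <- bn_fwd(cv$out, p[[paste0(name, ".g")]], p[[paste0(name, ".be")]],
               s[[paste0(name, ".rm")]], s[[paste0(name, ".rv")]], train)
  rl <- relu_fwd(bn$out)
  list(out = rl$out,
       cache = list(conv = cv$cache, bn = bn$cache, relu = rl$cache),
       rm = bn$rmean, rv = bn$rvar)
}

block_bwd <- function(cache, dout, name, grads) {
  rl <- relu_bwd(cache$relu, dout)
  bn <- bn_bwd(cache$bn, rl$dx)
  cv <- conv3d_bwd(cache$conv, bn$dx)
  grads[[paste0(name, ".W")]] <- cv$dW
  grads[[paste0(name, ".b")]] <- cv$db
  grads[[paste0(name, ".g")]] <- bn$dgamma
  grads[[paste0(name, ".be")]] <- bn$dbeta
  list(dx = cv$dx, grads = grads)
}

# Full forward pass. Returns out, layer caches (for backward), and updated
# batch-norm running statistics.
forward_net <- function(model, x, train = FALSE) {
  x <- as_batch(x)
  if (!all(is.finite(x))) stop("non-finite input")
  spec <- model$spec
  d <- dim(x)
  if (d[5] != spec$in_channels)
    stop(sprintf("input has %d channels, model expects %d", d[5],
                 spec$in_channels))
  if (spec$levels > 0L && any(d[3:4] %% 2L^spec$levels != 0L))
    stop(sprintf("(y, x) dims must be divisible by 2^levels = %d",
                 2L^spec$levels))
  caches <- list()
  att <- attention_fwd(x, model$params[["att.w"]])
  caches$att <- att$cache
  h <- att$out
  skips <- list()
  if (spec$levels == 0L) {
    bl <- block_fwd(h, model, "mid", c(1L, 1L, 1L), train)
    model$state[["mid.rm"]] <- bl$rm; model$state[["mid.rv"]] <- bl$rv
    caches$mid <- bl$cache
    h <- bl$out
  } else {
    for (k in seq_len(spec$levels)) {
      a <- block_fwd(h, model, paste0("enc", k, "a"), c(1L, 1L, 1L), train)
      model$state[[paste0("enc", k, "a.rm")]] <- a$rm
      model$state[[paste0("enc", k, "a.rv")]] <- a$rv
      caches[[paste0("enc", k, "a")]] <- a$cache
      skips[[k]] <- a$out
      b <- block_fwd(a$out, model, paste0("enc", k, "b"), c(1L, 2L, 2L), train)
      model$state[[paste0("enc", k, "b.rm")]] <- b$rm
      model$state[[paste0("enc", k, "b.rv")]] <- b$rv
      caches[[paste0("enc", k, "b")]] <- b$cache
      h <- b$out
    }
    for (k in rev(seq_len(spec$levels))) {
      nm <- paste0("dec", k, "t")
      tc <- convT_fwd(h, model$params[[paste0(nm, ".W")]],
                      model$params[[paste0(nm, ".b")]])
      pl <- avgpool_fwd(tc$out)
      bn <- bn_fwd(pl$out, model$params[[paste0(nm, ".g")]],
                   model$params[[paste0(nm, ".be")]],
                   model$state[[paste0(nm, ".rm")]],
                   model$state[[paste0(nm, ".rv")]], train)
      model$state[[paste0(nm, ".rm")]] <- bn$rmean
      model$state[[paste0(nm, ".rv")]] <- bn$rvar
      rl <- relu_fwd(bn$out)
      caches[[nm]] <- list(convT = tc$cache, pool = pl$cache, bn = bn$cache,
                           relu = rl$cache)
      skc <- dim(skips[[k]])[5]
      h2 <- concat_c(rl$out, skips[[k]])
      a <- block_fwd(h2, model, paste0("dec", k, "a"), c(1L, 1L, 1L), train)
      model$state[[paste0("dec", k, "a.rm")]] <- a$rm
      model$state[[paste0("dec", k, "a.rv")]] <- a$rv
      caches[[paste0("dec", k, "a")]] <- a$cache
      caches[[paste0("dec", k, "split")]] <- dim(rl$out)[5]
      h <- a$out
    }
  }
  fin <- conv3d_fwd(h, model$params[["final.W"]], model$params[["final.b"]],
                    c(1L, 1L, 1L), c(1L, 1L, 1L))
  caches$final <- fin$cache
  list(out = fin$out, caches = caches, state = model$state)
}

# Full backward pass: gradients of a scalar loss w.r.t. every parameter.
backward_net <- function(model, caches, dout) {
  spec <- model$spec
  grads <- list()
  fin <- conv3d_bwd(caches$final, dout)
  grads[["final.W"]] <- fin$dW; grads[["final.b"]] <- fin$db
  dh <- fin$dx
  if (spec$levels == 0L) {
    r <- block_bwd(caches$mid, dh, "mid", grads)
    grads <- r$grads; dh <- r$dx
  } else {
    dskips <- vector("list", spec$levels)
    for (k in seq_len(spec$levels)) {
      r <- block_bwd(caches[[paste0("dec", k, "a")]], dh,
                     paste0("dec", k, "a"), grads)
      grads <- r$grads
      sp <- split_c(r$dx, caches[[paste0("dec", k, "split")]])
      dskips[[k]] <- sp$b
      nm <- paste0("dec", k, "t")
      cc <- caches[[nm]]
      rl <- relu_bwd(cc$relu, sp$a)
      bn <- bn_bwd(cc$bn, rl$dx)
      grads[[paste0(nm, ".g")]] <- bn$dgamma
      grads[[paste0(nm, ".be")]] <- bn$dbeta
      pl <- avgpool_bwd(cc$pool, bn$dx)
      tc <- convT_bwd(cc$convT, pl$dx)
      grads[[paste0(nm, ".W")]] <- tc$dW
      grads[[paste0(nm, ".b")]] <- tc$db
      dh <- tc$dx
    }
    for (k in rev(seq_len(spec$levels))) {
      r <- block_bwd(caches[[paste0("enc", k, "b")]], dh,
                     paste0("enc", k, "b"), grads)
      grads <- r$grads
      dh <- r$dx + dskips[[k]]
      r <- block_bwd(caches[[paste0("enc", k, "a")]], dh,
                     paste0("enc", k, "a"), grads)
      grads <- r$grads
      dh <- r$dx
    }
  }
  at <- attention_bwd(caches$att, dh)
  grads[["att.w"]] <- at$dw
  grads
}

#' Run the model on a patch (inference mode)
#'
#' Batch normalization uses accumulated running statistics, so repeated calls
#' on the same input are bit-identical.
#'
#' @param model A `fib_model`.
#' @param patch Array `(z, y, x, c)` or batch `(n, z, y, x, c)` with finite
#'   values; `(y, x)` divisible by `2^levels`.
#' @return Predicted array with `out_channels` channels, same spatial dims.
#' @export
forward <- function(model, patch) {
  squeeze <- length(dim(patch)) == 4L
  out <- forward_net(model, patch, train = FALSE)$out
  if (squeeze) dim(out) <- dim(out)[-1]
  out
}

#' Predict a full volume by tiled inference with overlap blending
#'
#' The volume is covered with overlapping `(tile_y, tile_x)` tiles; each
#' tile's prediction is cropped by `overlap` pixels on interior borders before
#' placement, so every output voxel comes from a single tile evaluated with
#' adequate spatial context and seams carry no blending artifacts.
#'
#' @param model A `fib_model`.
#' @param stack Normalized `(z, y, x, c)` array; `y`, `x` at least `tile`.
#' @param tile `(tile_y, tile_x)`, divisible by `2^levels`.
#' @param overlap Margin in pixels, `>= 0` and less than half the tile.
#' @return Predicted `(z, y, x, out_channels)` array.
#' @export
predict_volume <- function(model, stack, tile = c(256L, 256L), overlap = 16L) {
  stack <- as_stack(stack)
  tile <- as.integer(tile); overlap <- as.integer(overlap)
  d <- dim(stack)
  lv <- model$spec$levels
  if (lv > 0L && any(tile %% 2L^lv != 0L))
    stop("tile must be divisible by 2^levels")
  if (any(tile > d[2:3])) stop("stack smaller than tile")
  if (any(2L * overlap >= tile)) stop("overlap too large for tile")
  core <- tile - 2L * overlap
  starts <- function(extent, tl, cr) {
    s <- unique(pmin(seq(1L, extent, by = cr), extent - tl + 1L))
    s[s >= 1L]
  }
  oy <- starts(d[2], tile[1], core[1])
  ox <- starts(d[3], tile[2], core[2])
  out <- array(0, dim = c(d[1], d[2], d[3], model$spec$out_channels))
  for (sy in oy) for (sx in ox) {
    patch <- stack[, sy:(sy + tile[1] - 1L), sx:(sx + tile[2] - 1L), ,
                   drop = FALSE]
    pred <- forward(model, patch)
    y0 <- if (sy == 1L) 1L else overlap + 1L
    y1 <- if (sy + tile[1] - 1L == d[2]) tile[1] else tile[1] - overlap
    x0 <- if (sx == 1L) 1L else overlap + 1L
    x1 <- if (sx + tile[2] - 1L == d[3]) tile[2] else tile[2] - overlap
    out[, sy + (y0:y1) - 1L, sx + (x0:x1) - 1L, ] <-
      pred[, y0:y1, x0:x1, , drop = FALSE]
  }
  out
}
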
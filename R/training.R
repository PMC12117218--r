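## Optimization loop and ablation harness.
##
## Models are trained with Adam on the hybrid L1/L3/SSIM loss at the
## reference hyperparameters (learning rate 1e-4, batch size 5, Adam moments
## 0.9/0.999); the checkpoint with the best validation loss is retained.
## Ablation variants restrict the input channel subset (and optionally blur
## the transmission channel) before training, so channel contributions can be
## compared under identical seeds.

#' Training hyperparameters
#'
#' @param learning_rate Adam step size; default `1e-4`.
#' @param batch_size Patches per optimization step; default 5.
#' @param epochs Hard epoch cap.
#' @param patience Early-stop patience on validation loss (epochs without
#'   improvement); `Inf` disables early stopping.
#' @param seed Integer seed governing initialization order, shuffling and any
#'   stochastic preprocessing.
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 1e-4, batch_size = 5L, epochs = 50L,
                       patience = 10L, seed = 1L, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-7) {
  stopifnot(learning_rate >= 0, batch_size >= 1L, epochs >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience,
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 eps = eps),
            class = "train_spec")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, spec) {
  st$t <- st$t + 1L
  corr1 <- 1 - spec$beta1^st$t
  corr2 <- 1 - spec$beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- spec$beta1 * st$m[[nm]] + (1 - spec$beta1) * g
    st$v[[nm]] <- spec$beta2 * st$v[[nm]] + (1 - spec$beta2) * g^2
    mh <- st$m[[nm]] / corr1
    vh <- st$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - spec$learning_rate * mh / (sqrt(vh) + spec$eps)
  }
  list(params = params, state = st)
}

# Stack a list of (z,y,x,c) patches into an (n,z,y,x,c) batch.
stack_batch <- function(patches) {
  d <- dim(patches[[1]])
  n <- length(patches)
  out <- array(0, dim = c(n, d))
  for (i in seq_len(n)) out[i, , , , ] <- patches[[i]]
  out
}

# Mean hybrid loss of a model over a patch list (inference mode).
eval_loss <- function(model, xs, ys, lspec) {
  mean(vapply(seq_along(xs), function(i) {
    pred <- forward_net(model, xs[[i]], train = FALSE)$out
    yb <- ys[[i]]; dim(yb) <- c(1L, dim(yb))
    hybrid_loss(yb, pred, lspec)$value
  }, numeric(1)))
}

split_xy <- function(patches, in_channels) {
  xs <- lapply(patches, function(p) p[, , , seq_len(in_channels), drop = FALSE])
  ys <- lapply(patches, function(p) p[, , , dim(p)[4], drop = FALSE])
  list(xs = xs, ys = ys)
}

#' Train a model on paired patches
#'
#' Each training patch carries the input channels first and the fluorescence
#' target as its last channel. Parameters are updated by Adam on the hybrid
#' loss; per-epoch training/validation losses and attention-weight
#' trajectories are logged, and the parameters with the best validation loss
#' are restored before returning. Runs are reproducible: all shuffling
#' derives from `spec$seed`.
#'
#' @param model A `fib_model` whose `in_channels` equals the patch channel
#'   count minus one.
#' @param train_patches,val_patches Lists of `(z, y, x, c_in + 1)` arrays
#'   (`val_patches` may be empty, in which case training loss drives
#'   checkpoint selection).
#' @param spec A [train_spec()].
#' @param lspec A [loss_spec()].
#' @param steps_per_epoch Optimization steps per epoch; defaults to one pass
#'   over the training patches.
#' @return `list(model, history)`; `history` is a data frame with columns
#'   `epoch`, `train_loss`, `val_loss` and one `w_*` column per input channel.
#' @export
train_model <- function(model, train_patches, val_patches = list(),
                        spec = train_spec(), lspec = loss_spec(),
                        steps_per_epoch = NULL) {
  stopifnot(inherits(model, "fib_model"), length(train_patches) >= 1L)
  cin <- model$spec$in_channels
  if (dim(train_patches[[1]])[4] != cin + 1L)
    stop("patches must have in_channels input channels plus one target")
  tr <- split_xy(train_patches, cin)
  va <- if (length(val_patches)) split_xy(val_patches, cin) else NULL
  if (is.null(steps_per_epoch))
    steps_per_epoch <- max(1L, ceiling(length(tr$xs) / spec$batch_size))

  set.seed(spec$seed)
  opt <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, state = model$state)
  hist <- list()
  stale <- 0L
  for (ep in seq_len(spec$epochs)) {
    ep_losses <- numeric(steps_per_epoch)
    for (st in seq_len(steps_per_epoch)) {
      take <- sample.int(length(tr$xs), min(spec$batch_size, length(tr$xs)),
                         replace = length(tr$xs) < spec$batch_size)
      xb <- stack_batch(tr$xs[take])
      yb <- stack_batch(tr$ys[take])
      fw <- forward_net(model, xb, train = TRUE)
      model$state <- fw$state
      hl <- hybrid_loss(yb, fw$out, lspec, want_grad = TRUE)
      if (!is.finite(hl$value))
        stop(sprintf("non-finite loss at epoch %d step %d (batch %s)",
                     ep, st, paste(take, collapse = ",")))
      ep_losses[st] <- hl$value
      grads <- backward_net(model, fw$caches, hl$grad)
      if (spec$learning_rate > 0) {
        up <- adam_step(model$params, grads, opt, spec)
        model$params <- up$params
        opt <- up$state
      }
    }
    train_loss <- mean(ep_losses)
    val_loss <- if (!is.null(va)) eval_loss(model, va$xs, va$ys, lspec)
                else train_loss
    w <- model$params[["att.w"]]
    hist[[ep]] <- c(epoch = ep, train_loss = train_loss, val_loss = val_loss,
                    stats::setNames(w, paste0("w_", seq_along(w))))
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = model$params,
                   state = model$state)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= spec$patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  history <- as.data.frame(do.call(rbind, hist))
  list(model = model, history = history)
}

ABLATION_VARIANTS <- list(
  "Tra+Ref" = list(channels = c("Ref405", "Ref488", "Ref561", "Tra"),
                   blur = NULL),
  "Tra" = list(channels = "Tra", blur = NULL),
  "Ref" = list(channels = c("Ref405", "Ref488", "Ref561"), blur = NULL),
  "Tra+Ref405" = list(channels = c("Ref405", "Tra"), blur = NULL),
  "Tra+Ref488" = list(channels = c("Ref488", "Tra"), blur = NULL),
  "Tra+Ref561" = list(channels = c("Ref561", "Tra"), blur = NULL),
  "Tra(s=1)" = list(channels = c("Ref405", "Ref488", "Ref561", "Tra"),
                    blur = 1),
  "Tra(s=3)" = list(channels = c("Ref405", "Ref488", "Ref561", "Tra"),
                    blur = 3),
  "Tra(s=5)" = list(channels = c("Ref405", "Ref488", "Ref561", "Tra"),
                    blur = 5))

#' Ablation variant labels
#'
#' The nine input permutations: the full model, transmission-only, RCM-only,
#' single-RCM-wavelength pairs, and the transmission-blur family (blurred
#' transmission combined with the three intact RCM channels).
#'
#' @return Character vector of labels accepted by [make_ablation_inputs()].
#' @export
ablation_variants <- function() names(ABLATION_VARIANTS)

#' Restrict a stack to an ablation variant's inputs
#'
#' Returns the stack reduced to the variant's channel subset (order
#' preserved), with the transmission channel Gaussian-blurred for the
#' `Tra(s=...)` family. A trailing `GT` channel, if present, is carried
#' through unchanged.
#'
#' @param stack `(z, y, x, c)` array.
#' @param meta [stack_meta()] naming the channels.
#' @param variant One of [ablation_variants()].
#' @return `list(stack, meta)` for the variant.
#' @export
make_ablation_inputs <- function(stack, meta, variant) {
  v <- ABLATION_VARIANTS[[variant]]
  if (is.null(v)) stop("unknown ablation variant: ", variant)
  stack <- as_stack(stack)
  if (!is.null(v$blur)) stack <- blur_transmission(stack, meta, v$blur)
  keep <- v$channels
  if ("GT" %in% meta$channel_names) keep <- c(keep, "GT")
  select_channels(stack, meta, keep)
}

#' Train and evaluate every requested ablation variant
#'
#' For each variant the stacks are reduced with [make_ablation_inputs()],
#' tiled, split by the sample assignment, and a fresh model (input width
#' equal to the variant's channel count) is trained with identical seeds, so
#' variants are paired for comparison. Held-out test stacks are predicted and
#' scored with [bootstrap_metrics()].
#'
#' @param stacks Named list of `(z, y, x, c)` arrays including a `GT`
#'   channel.
#' @param meta [stack_meta()] shared by the stacks.
#' @param assignment Named cohort map (`"train"`/`"val"`/`"test"`) covering
#'   `names(stacks)`.
#' @param variants Character vector of [ablation_variants()] labels.
#' @param tile Patch tile `(y, x)`.
#' @param tspec A [train_spec()].
#' @param lspec A [loss_spec()].
#' @param mspec_fn Function `(in_channels) -> model_spec` so reduced-width
#'   architectures can be swapped in.
#' @param n_boot,boot_patch Bootstrap evaluation parameters.
#' @param norm_kernel Sliding-window kernel for Z-score normalization applied
#'   after the variant's blur/subset (blur acts on raw intensities, as in the
#'   acquisition protocol); `NULL` skips normalization.
#' @return Data frame: one row per variant x metric with mean and sd, plus a
#'   `models` attribute holding the trained models.
#' @export
run_ablation_suite <- function(stacks, meta, assignment,
                               variants = c("Tra+Ref", "Tra", "Ref"),
                               tile = c(64L, 64L), tspec = train_spec(),
                               lspec = loss_spec(),
                               mspec_fn = function(cin)
                                 model_spec(in_channels = cin),
                               n_boot = 50L, boot_patch = c(8L, 32L, 32L),
                               norm_kernel = c(1L, 101L, 101L)) {
  rows <- list()
  models <- list()
  for (vl in variants) {
    cohorts <- list(train = list(), val = list(), test = list())
    test_pairs <- list()
    for (sid in names(stacks)) {
      ab <- make_ablation_inputs(stacks[[sid]], meta, vl)
      if (!is.null(norm_kernel)) {
        ab$stack <- zscore_normalize(ab$stack,
                                     local_stats(ab$stack, norm_kernel))
      }
      ps <- tile_stack(ab$stack, tile, source_id = sid)
      ch <- assignment[[sid]]
      cohorts[[ch]] <- c(cohorts[[ch]], ps$patches)
      if (ch == "test") test_pairs[[sid]] <- ab
    }
    cin <- length(ABLATION_VARIANTS[[vl]]$channels)
    model <- build_model(mspec_fn(cin), seed = tspec$seed)
    fit <- train_model(model, cohorts$train, cohorts$val, tspec, lspec)
    models[[vl]] <- fit
    for (sid in names(test_pairs)) {
      ab <- test_pairs[[sid]]
      x <- ab$stack[, , , seq_len(cin), drop = FALSE]
      gt <- ab$stack[, , , dim(ab$stack)[4], drop = FALSE]
      pred <- predict_volume(fit$model, x, tile = tile, overlap = 0L)
      rep <- bootstrap_metrics(gt, pred, n_patches = n_boot,
                               patch = boot_patch, seed = tspec$seed)
      rep$variant <- vl
      rep$sample <- sid
      rows[[paste(vl, sid)]] <- rep
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}

#' Read the learned per-channel attention weights
#'
#' @param model A `fib_model`.
#' @param channel_names Optional labels for the weights.
#' @return Named numeric vector, one scalar per input channel.
#' @export
read_attention <- function(model, channel_names = NULL) {
  w <- model$params[["att.w"]]
  if (!is.null(channel_names)) {
    stopifnot(length(channel_names) == length(w))
    names(w) <- channel_names
  } else if (is.null(names(w))) {
    names(w) <- paste0("w", seq_along(w))
  }
  w
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries the architecture spec, all parameters (including
#' attention weights), batch-norm running statistics and the initialization
#' seed, and reloads bit-exactly.
#'
#' @param model A `fib_model`.
#' @param path Checkpoint file path (RDS).
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fib_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fib_model")) stop("not a model checkpoint")
  model
}
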
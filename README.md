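# fibrestain

Virtual staining of fibrin fiber networks: predict fluorescently labeled
confocal optical sections from label-free inputs — reflection confocal
microscopy (RCM) at 405/488/561 nm plus a laser-transmission channel.

## The problem

Fluorescent dyes photobleach and can perturb cells, which limits
longitudinal confocal imaging of extracellular-matrix scaffolds. The two
label-free alternatives each fail differently: RCM sections optically but
misses fibers tilted toward the optical axis, while transmission imaging
sees every fiber through a thick focal volume (no depth assignment, and a
spatially varying 400–700 nm focal offset relative to the confocal planes).
`fibrestain` learns the mapping from the four label-free channels to the
fluorescence channel, so the dye channel can be freed for molecular labels.

## What is inside

* **Preprocessing** — spatially localized Z-score normalization
  `N = (R − μ)/max(σ, σ_min)` with a sliding `(1, 101, 101)` window (clipped
  at borders, population σ), transmission blurring for ablation studies,
  non-overlapping 256×256 tiling with full z extent, and sample-disjoint
  cohort assembly.
* **Network** — a fully convolutional 3D encoder–decoder
  (conv → batch norm → ReLU blocks, `(1,2,2)` strides so z is never
  downsampled, feature depth doubling to a cap of 64, concatenated skips,
  transposed-convolution upsampling smoothed by `(1,2,2)` average pooling)
  with one trainable attention scalar per input channel. Layers and
  backpropagation are implemented in the package (im2col + BLAS hot loops
  in `src/conv3d.cpp`) and verified against finite differences.
* **Objectives** — the hybrid training loss
  `L = L1 + α·L3 + β·(1 − SSIM)` with defaults `α = 1e-1`, `β = 1e-4`
  (analytic SSIM gradient included), and evaluation metrics MSE, SSIM,
  PSNR and Spearman ρ with overlapping-patch bootstrap variance.
* **Training** — Adam (reference learning rate `1e-4`, batch 5), early
  stopping on validation loss, bit-reproducible runs, and the ablation
  harness over channel subsets (`Tra+Ref`, `Tra`, `Ref`, single-wavelength
  pairs) and the transmission-blur family `σ ∈ {1, 3, 5}`.
* **Fiber quantification** — a skeleton-based tracer (threshold → thinning
  → spur pruning → branch splitting → collinear re-linking) reporting
  per-slice counts, lengths and medial-axis widths in µm, depth-binned
  counts (`[1,4), [4,8), [8,12), [12,16)` µm), paired t tests, signed error
  maps and an unsharp-mask width correction (radius 4 px, weight 0.6).
* **Phantom generator** — paired synthetic stacks on the acquisition grid
  (77.69 nm pixels, 100 nm z-steps): fluorescence GT, three RCM channels
  with `cos^k` orientation response, wavelength-dependent blur, central
  bright-spot and interference-ring artifacts, and a thick-focal-volume
  transmission channel with a smooth 400–700 nm focal-offset field.
* **I/O and CLI** — lossless float32 multi-page TIFF with embedded JSON
  metadata, CSV/JSON reports, and `simulate | normalize | patchify | train |
  predict | evaluate | fibers` subcommands (`inst/cli/fibrestain`).

## Worked example

```r
library(fibrestain)

# 1. Simulate a paired phantom: 4 label-free channels + fluorescence GT
spec <- phantom_spec(shape = c(16L, 128L, 128L), seed = 42)
ds <- make_paired_dataset(spec, n_stacks = 2, seed = 42)
meta <- ds[[1]]$meta

# 2. Sliding-window Z-score normalization (kernel 1 x 101 x 101)
norm <- lapply(ds, function(d)
  zscore_normalize(d$stack, local_stats(d$stack, c(1L, 101L, 101L))))

# 3. Train a reduced-width model on 16x16 full-depth patches
patches <- tile_stack(norm[[1]], c(16L, 16L))$patches
sdv <- sapply(patches, function(p) sd(p[, , , 5]))
train_set <- patches[order(-sdv)[1:12]]
model <- build_model(model_spec(in_channels = 4, levels = 2,
                                max_channels = 8), seed = 42)
fit <- train_model(model, train_set,
                   spec = train_spec(learning_rate = 1e-3, batch_size = 3,
                                     epochs = 4, patience = Inf, seed = 42),
                   steps_per_epoch = 20)

# 4. Predict the held-out phantom and evaluate
x_test <- norm[[2]][, , , 1:4, drop = FALSE]
gt_test <- norm[[2]][, , , 5, drop = FALSE]
pred <- predict_volume(fit$model, x_test, tile = c(16L, 16L), overlap = 0L)
bootstrap_metrics(gt_test, pred, n_patches = 100,
                  patch = c(8L, 64L, 64L), seed = 42)
#>     metric     mean       sd
#> 1      mse  0.00299 0.000344
#> 2     ssim  0.55754 0.034502
#> 3     psnr 25.27074 0.482794
#> 4 spearman  0.39027 0.149329

# 5. Which input channels did the model rely on?
round(read_attention(fit$model, meta$channel_names[1:4]), 3)
#> Ref405 Ref488 Ref561    Tra
#>  0.991  0.971  0.990  1.024

# 6. Fiber morphometry of GT vs prediction on a mid-depth slice
tp <- trace_params()
seg_gt <- trace_fibers(gt_test[8, , , 1], tp, meta$pixel_size_xy)
seg_pr <- trace_fibers(pred[8, , , 1], tp, meta$pixel_size_xy)
#> slice 8: 6 GT fibers vs 5 predicted; mean width 0.229 vs 0.197 um
```

After 80 Adam steps on one CPU the reduced model reaches a per-voxel MSE of
~3×10⁻³ on `[0,1]`-rescaled held-out data (PSNR ≈ 25 dB), and the learned
attention already ranks the transmission channel above the three RCM
channels — the direction expected from the information content of the
modalities. Fiber counts and widths of the prediction track ground truth on
mid-depth slices.

## Command line

```sh
Rscript inst/cli/fibrestain simulate  --config sim.yaml
Rscript inst/cli/fibrestain normalize --config norm.yaml
Rscript inst/cli/fibrestain train     --config train.yaml
Rscript inst/cli/fibrestain evaluate  --config eval.yaml
Rscript inst/cli/fibrestain fibers    --config fibers.yaml
```

Each stage logs its parameters and seed; identical configs and seeds give
identical outputs.

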
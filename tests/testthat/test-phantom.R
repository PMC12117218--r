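test_that("fiber sampling is seeded, bounded, and matches its distribution", {
  spec <- phantom_spec(n_fibers = 0L)
  expect_length(sample_fibers(spec), 0)
  spec2 <- tiny_phantom(seed = 81)
  expect_identical(sample_fibers(spec2), sample_fibers(spec2))
  spec3 <- phantom_spec(n_fibers = 500L, seed = 82)
  fb <- sample_fibers(spec3)
  lens <- vapply(fb, function(f) f$length_um, numeric(1))
  expect_true(all(lens >= 2 & lens <= 30))
  # sample moments vs the truncated log-normal (Monte Carlo reference)
  set.seed(99)
  ref <- stats::rlnorm(2e5, spec3$length_meanlog, spec3$length_sdlog)
  ref <- ref[ref >= 2 & ref <= 30]
  se <- stats::sd(ref) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - mean(ref)), 3 * se)
})

test_that("degenerate volumes are rejected", {
  expect_error(phantom_spec(shape = c(1L, 64L, 64L)), "degenerate")
})

test_that("fluorescence render peaks on the centerline and decays transversally", {
  spec <- phantom_spec(shape = c(8L, 64L, 64L), n_fibers = 0L, seed = 83,
                       background = 0.1)
  # empty scene: background plus noise only
  empty <- render_fluorescence(sample_fibers(spec), spec)
  expect_lt(abs(mean(empty) - 0.1), 0.02)
  # single in-plane fiber through the volume center
  ext <- fibrestain:::vol_extent_um(spec)
  f <- list(p0 = c(ext[1] / 2, ext[2] / 2, 0.2),
            p1 = c(ext[1] / 2, ext[2] / 2, ext[3] - 0.2),
            radius_um = 0.12, intensity = 1, tilt_deg = 0, length_um = 4)
  gt <- render_fluorescence(list(f), spec, noise = FALSE)
  zc <- round(ext[1] / 2 / (spec$meta$z_step / 1000) + 0.5)
  prof <- gt[zc, , 32]
  expect_equal(which.max(prof), 32, tolerance = 1) # centered response
  expect_true(all(diff(prof[32:45]) <= 1e-9)) # monotone transverse decay
  # apparent width >= true width after PSF widening
  seg <- trace_fibers(gt[zc, , ], trace_params(), spec$meta$pixel_size_xy)
  expect_gte(seg[[1]]$width_um, 2 * f$radius_um - 0.0777)
})

test_that("RCM response is monotone non-increasing in fiber tilt", {
  spec <- phantom_spec(shape = c(8L, 64L, 64L), n_fibers = 0L, seed = 84,
                       background = 0)
  ext <- fibrestain:::vol_extent_um(spec)
  response <- sapply(seq(0, 80, by = 10), function(tilt) {
    th <- tilt * pi / 180
    len <- 2
    u <- c(sin(th), cos(th), 0) # (z, y, x) direction
    ctr <- ext / 2
    f <- list(p0 = ctr - u * len / 2, p1 = ctr + u * len / 2,
              radius_um = 0.12, intensity = 1, tilt_deg = tilt,
              length_um = len)
    sum(render_rcm(list(f), 488, spec, artifacts = FALSE, noise = FALSE))
  })
  expect_true(all(diff(response) <= 1e-6))
  # axial fiber nearly vanishes relative to in-plane
  expect_lt(response[length(response)] / response[1], 0.05)
})

test_that("wavelengths share geometry but differ in blur, unknown ones error", {
  spec <- tiny_phantom(seed = 85)
  fb <- sample_fibers(spec)
  a <- render_rcm(fb, 405, spec, artifacts = FALSE, noise = FALSE)
  b <- render_rcm(fb, 561, spec, artifacts = FALSE, noise = FALSE)
  expect_gt(stats::cor(as.vector(a), as.vector(b)), 0.9)
  expect_gt(stats::sd(a), stats::sd(b)) # longer wavelength, wider PSF
  expect_error(render_rcm(fb, 650, spec), "wavelength")
})

test_that("artifacts differ from the clean render only inside their masks", {
  spec <- phantom_spec(shape = c(8L, 64L, 64L), seed = 86, n_fibers = 6L)
  fb <- sample_fibers(spec)
  clean <- render_rcm(fb, 488, spec, artifacts = FALSE, noise = FALSE)
  art <- render_rcm(fb, 488, spec, artifacts = TRUE, noise = FALSE)
  d <- art - clean
  expect_true(all(d >= -1e-12)) # additive artifacts
  # the difference is exactly the configured spot + ring overlay: largest at
  # the field center, decaying with depth for the ring component
  center <- mean(d[, 30:35, 30:35])
  corner <- mean(d[, 1:6, 1:6])
  expect_gt(center, corner)
  expect_gt(mean(d[1, , ]), mean(d[8, , ])) # rings fade with depth
})

test_that("transmission co-localizes with GT in the thin, offset-free limit", {
  spec <- phantom_spec(shape = c(8L, 64L, 64L), seed = 87, n_fibers = 6L,
                       tra_half_depth_um = 0, poisson_scale = 0,
                       read_noise_sd = 0, axial_fraction = 0)
  fb <- sample_fibers(spec)
  gt <- render_fluorescence(fb, spec, noise = FALSE)
  tra <- render_transmission(fb, spec, delta_nm = 0, noise = FALSE)
  z <- 4
  gm <- gt[z, , ] > stats::quantile(gt[z, , ], 0.9)
  tm <- (-tra[z, , ]) > stats::quantile(-tra[z, , ], 0.9)
  expect_gt(stats::cor(as.vector(gm * 1), as.vector(tm * 1)), 0.6)
})

test_that("a programmed 500 nm offset is recovered by slice correlation", {
  spec <- phantom_spec(seed = 88, tra_half_depth_um = 0.15,
                       poisson_scale = 0, read_noise_sd = 0.002,
                       spot_amplitude = 0, ring_amplitude = 0,
                       axial_fraction = 0.1)
  fb <- sample_fibers(spec)
  gt <- render_fluorescence(fb, spec, noise = FALSE)
  tra <- render_transmission(fb, spec, delta_nm = 500, noise = FALSE)
  lags <- 0:10
  cors <- sapply(lags, function(s) {
    z1 <- 1:(dim(gt)[1] - s)
    stats::cor(as.vector(-tra[z1, , ]), as.vector(gt[z1 + s, , ]))
  })
  best <- lags[which.max(cors)]
  expect_lte(abs(best - 5), 1) # 500 nm / 100 nm z-step, within one step
})

test_that("thick-focal-volume transmission detects more fibers per slice", {
  spec <- phantom_spec(seed = 89, tra_half_depth_um = 1.5, n_fibers = 25L)
  fb <- sample_fibers(spec)
  gt <- render_fluorescence(fb, spec, noise = FALSE)
  tra <- render_transmission(fb, spec, delta_nm = 0, noise = FALSE)
  zmid <- seq(8, 24, by = 4)
  n_gt <- sum(sapply(zmid, function(z)
    length(trace_fibers(gt[z, , ], trace_params(), 77.69))))
  n_tra <- sum(sapply(zmid, function(z)
    length(trace_fibers(max(tra) - tra[z, , ], trace_params(), 77.69))))
  expect_gt(n_tra, n_gt)
})

test_that("paired dataset assembles consistent channels per seed", {
  spec <- tiny_phantom(seed = 90)
  ds <- make_paired_dataset(spec, 2, seed = 90)
  expect_length(ds, 2)
  expect_identical(ds[[1]]$meta$channel_names,
                   c("Ref405", "Ref488", "Ref561", "Tra", "GT"))
  expect_false(identical(ds[[1]]$stack, ds[[2]]$stack))
  ds2 <- make_paired_dataset(spec, 2, seed = 90)
  expect_identical(ds[[1]]$stack, ds2[[1]]$stack) # reproducible per seed
  # channels agree on fiber geometry: GT vs in-plane RCM mask overlap
  spec_clean <- tiny_phantom(seed = 91, axial_fraction = 0, poisson_scale = 0,
                             read_noise_sd = 0, spot_amplitude = 0,
                             ring_amplitude = 0, background = 0)
  fb <- sample_fibers(spec_clean)
  gt <- render_fluorescence(fb, spec_clean, noise = FALSE)
  rcm <- render_rcm(fb, 488, spec_clean, artifacts = FALSE, noise = FALSE)
  gm <- gt > 0.2 * max(gt)
  rm <- rcm > 0.2 * max(rcm)
  iou <- sum(gm & rm) / sum(gm | rm)
  expect_gt(iou, 0.5)
})

test_that("steeply tilted fibers are invisible to RCM but present in GT", {
  spec <- phantom_spec(shape = c(16L, 64L, 64L), seed = 92, n_fibers = 12L,
                       axial_fraction = 1, poisson_scale = 0,
                       read_noise_sd = 0, spot_amplitude = 0,
                       ring_amplitude = 0, background = 0)
  fb <- sample_fibers(spec)
  gt <- render_fluorescence(fb, spec, noise = FALSE)
  rcm <- render_rcm(fb, 488, spec, artifacts = FALSE, noise = FALSE)
  gm <- gt > 0.2 * max(gt)
  expect_gt(sum(gm), 0) # fibers exist in the scene
  # a per-voxel regressor on RCM cannot reach them: RCM carries almost no
  # signal where GT has fibers
  expect_lt(max(rcm[gm]) / max(gt[gm]), 0.2)
})

test_that("focal offset field is smooth and inside the configured range", {
  spec <- phantom_spec(seed = 93)
  f <- focal_offset_field(spec)
  expect_identical(dim(f), c(128L, 128L))
  expect_true(all(f >= 400 & f <= 700))
  expect_lt(max(abs(diff(f))), 10) # low-frequency: small pixel-to-pixel step
})
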
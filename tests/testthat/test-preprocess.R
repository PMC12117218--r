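test_that("windowed stats equal the brute-force oracle on random stacks", {
  st <- rand_stack(1, 16, 16, 1, seed = 21)
  got <- local_stats(st, c(1L, 5L, 5L))
  want <- brute_local_stats(st, c(1, 5, 5))
  expect_equal(got$mu, want$mu, tolerance = 1e-6)
  expect_equal(got$sigma, want$sigma, tolerance = 1e-6)
  # multi-channel, multi-slice, z-extent > 1
  st2 <- rand_stack(3, 10, 10, 2, seed = 22)
  got2 <- local_stats(st2, c(3L, 5L, 5L))
  want2 <- brute_local_stats(st2, c(3, 5, 5))
  expect_equal(got2$mu, want2$mu, tolerance = 1e-6)
  expect_equal(got2$sigma, want2$sigma, tolerance = 1e-6)
})

test_that("constant stack gives mu = value, sigma = 0, normalized 0", {
  st <- array(5, dim = c(2, 8, 8, 1))
  s <- local_stats(st, c(1L, 3L, 3L))
  expect_true(all(s$mu == 5))
  expect_true(all(s$sigma == 0))
  expect_true(all(zscore_normalize(st, s) == 0))
})

test_that("center of a 3x3 window equals the mean of all nine values", {
  st <- rand_stack(1, 3, 3, 1, seed = 5)
  s <- local_stats(st, c(1L, 3L, 3L))
  expect_equal(s$mu[1, 2, 2, 1], mean(st))
})

test_that("default kernel maps keep the input shape", {
  st <- rand_stack(2, 128, 110, 2, seed = 6)
  s <- local_stats(st, c(1L, 101L, 101L))
  expect_identical(dim(s$mu), dim(st))
  expect_identical(dim(s$sigma), dim(st))
  expect_true(all(s$sigma >= 0))
})

test_that("kernel validation rejects even or oversized kernels", {
  st <- rand_stack(1, 8, 8, 1)
  expect_error(local_stats(st, c(1L, 4L, 5L)), "odd")
  expect_error(local_stats(st, c(1L, 9L, 9L)), "exceeds")
})

test_that("Z-score normalization is affine invariant", {
  st <- rand_stack(2, 20, 20, 2, seed = 7)
  n1 <- zscore_normalize(st, local_stats(st, c(1L, 5L, 5L)))
  st2 <- 2.5 * st + 7
  n2 <- zscore_normalize(st2, local_stats(st2, c(1L, 5L, 5L)))
  expect_equal(n1, n2, tolerance = 1e-6)
})

test_that("windowed residuals have zero mean over interior windows", {
  st <- rand_stack(1, 15, 15, 1, seed = 8)
  s <- local_stats(st, c(1L, 5L, 5L))
  resid <- st - s$mu
  # interior voxel: window fully inside -> mean of raw values equals mu there
  w <- st[1, 6:10, 6:10, 1]
  expect_equal(mean(w), s$mu[1, 8, 8, 1], tolerance = 1e-10)
  expect_equal(mean(w - s$mu[1, 8, 8, 1]), 0, tolerance = 1e-10)
  expect_true(is.array(resid))
})

test_that("(1,1,1) kernel collapses to mu = R, sigma = 0, all-zero output", {
  st <- rand_stack(2, 6, 6, 1, seed = 9)
  s <- local_stats(st, c(1L, 1L, 1L))
  expect_equal(s$mu, st)
  expect_true(all(s$sigma == 0))
  expect_true(all(zscore_normalize(st, s) == 0))
})

test_that("a bright central plateau is flattened by normalization", {
  # emulate the RCM central bright spot: strong smooth bump over texture
  set.seed(10)
  y <- x <- seq(-1, 1, length.out = 64)
  bump <- 4 * exp(-outer(y^2, x^2, `+`) / 0.1)
  tex <- matrix(rnorm(64 * 64, 0, 0.3), 64)
  st <- array(bump + tex + 1, dim = c(1, 64, 64, 1))
  n <- zscore_normalize(st, local_stats(st, c(1L, 21L, 21L)))
  center_mag <- mean(abs(n[1, 28:36, 28:36, 1]))
  edge_mag <- mean(abs(n[1, 1:9, 1:9, 1]))
  raw_ratio <- mean(st[1, 28:36, 28:36, 1]) / mean(st[1, 1:9, 1:9, 1])
  norm_ratio <- center_mag / edge_mag
  expect_gt(raw_ratio, 3) # the raw plateau dominates
  expect_lt(norm_ratio, raw_ratio / 2) # the saturation drop is suppressed
})

test_that("Z-scoring removes a uniform brightness plateau entirely", {
  # pure plateau with matched texture everywhere: normalization leaves no
  # trace of the bump at all
  set.seed(11)
  y <- x <- seq(-1, 1, length.out = 64)
  bump <- 4 * exp(-outer(y^2, x^2, `+`) / 0.1)
  tex <- matrix(rnorm(64 * 64, 0, 0.3), 64)
  a <- array(bump + tex, dim = c(1, 64, 64, 1))
  b <- array(tex, dim = c(1, 64, 64, 1))
  na <- zscore_normalize(a, local_stats(a, c(1L, 21L, 21L)))
  nb <- zscore_normalize(b, local_stats(b, c(1L, 21L, 21L)))
  # away from the bump's steep flank the two normalizations agree closely
  expect_lt(mean(abs(na[1, 1:12, 1:12, 1] - nb[1, 1:12, 1:12, 1])), 0.05)
})

test_that("transmission blur matches the impulse-response kernel", {
  meta <- stack_meta(channel_names = c("Ref405", "Tra"))
  st <- array(0, dim = c(1, 11, 11, 2))
  st[1, 6, 6, 2] <- 1
  out <- blur_transmission(st, meta, sigma = 1.2)
  r <- 2
  g <- exp(-(seq(-r, r))^2 / (2 * 1.2^2))
  k <- outer(g, g); k <- k / sum(k)
  expect_equal(out[1, 4:8, 4:8, 2], k, tolerance = 1e-12)
  expect_identical(out[, , , 1], st[, , , 1]) # RCM untouched
})

test_that("blur approaches identity as sigma shrinks", {
  meta <- stack_meta(channel_names = "Tra")
  st <- rand_stack(1, 16, 16, 1, seed = 12)
  out <- blur_transmission(st, meta, sigma = 0.05)
  expect_equal(out, st, tolerance = 1e-6)
})

test_that("blur sigma family produces three distinct ablation inputs", {
  meta <- stack_meta(channel_names = "Tra")
  st <- rand_stack(2, 16, 16, 1, seed = 13)
  outs <- lapply(c(1, 3, 5), function(s) blur_transmission(st, meta, s))
  v <- sapply(outs, function(o) stats::sd(o))
  expect_true(all(diff(v) < 0)) # stronger blur, less variance
})

test_that("blurring requires a transmission channel", {
  meta <- stack_meta(channel_names = c("Ref405"))
  expect_error(blur_transmission(rand_stack(c = 1), meta, 1), "Tra")
})

test_that("tiling partitions the plane and stitches back exactly", {
  st <- rand_stack(2, 64, 96, 2, seed = 14)
  ps <- tile_stack(st, c(32L, 32L))
  expect_equal(length(ps$patches), 2 * 3)
  expect_false(anyDuplicated(ps$origins) > 0)
  for (p in ps$patches) expect_equal(dim(p), c(2, 32, 32, 2))
  expect_equal(stitch_tiles(ps), st)
  # every retained voxel appears exactly once: total voxel conservation
  expect_equal(sum(sapply(ps$patches, length)), length(st))
})

test_that("a 256x256 plane yields exactly one identical patch", {
  st <- rand_stack(1, 256, 256, 1, seed = 15)
  ps <- tile_stack(st, c(256L, 256L))
  expect_equal(length(ps$patches), 1)
  expect_equal(ps$patches[[1]], st)
})

test_that("remainder rows/columns are dropped", {
  st <- rand_stack(1, 70, 70, 1, seed = 16)
  ps <- tile_stack(st, c(32L, 32L))
  expect_equal(length(ps$patches), 4)
  expect_error(tile_stack(st, c(128L, 32L)), "larger")
})

test_that("cohort split is sample-disjoint and conserves patches", {
  sets <- lapply(1:4, function(i)
    tile_stack(rand_stack(1, 64, 64, 1, seed = i), c(32L, 32L),
               source_id = paste0("s", i)))
  assign <- c(s1 = "train", s2 = "train", s3 = "val", s4 = "test")
  co <- split_cohorts(sets, assign)
  expect_equal(length(co$train), 8)
  expect_equal(length(co$val), 4)
  expect_equal(length(co$test), 4)
  expect_equal(length(co$train) + length(co$val) + length(co$test),
               sum(sapply(sets, function(p) length(p$patches))))
  expect_error(split_cohorts(sets, assign[-1]), "cover")
  expect_error(split_cohorts(sets[c(1, 1)], assign), "duplicate")
})
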
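## Synthetic paired-data generator.
##
## Scenes are straight cylindrical fibers in a (z, y, x) volume on the
## confocal acquisition grid (77.69 nm lateral, 100 nm axial by default).
## Each scene is rendered through four label-free modalities plus the
## fluorescence ground truth:
##   * fluorescence (GT): orientation-independent, anisotropic confocal PSF
##     (sigma_z > sigma_xy), bright fibers;
##   * RCM at 405/488/561 nm: reflectance scaled by cos^k of the fiber's
##     tilt out of the transverse plane (steep fibers vanish), PSF width
##     scaling with wavelength, optional central bright-spot and
##     near-coverslip interference-ring artifacts;
##   * transmission: absorbance integrated over a thick focal volume
##     displaced axially by a smooth spatially varying focal-offset field
##     (400-700 nm), rendered dark-on-bright;
## all with Poisson-Gaussian noise. Every render is reproducible per seed.

#' Phantom scene and rendering parameters
#'
#' Lengths are micrometers unless suffixed `_nm`. Defaults give a
#' `(32, 128, 128)` voxel test-scale volume (about 3.2 x 9.9 x 9.9 um) that
#' full pipelines can traverse in minutes on one CPU.
#'
#' @param shape Volume extents `(z, y, x)` in voxels.
#' @param meta A [stack_meta()] fixing the voxel grid.
#' @param n_fibers Number of fibers drawn per scene.
#' @param length_range_um Support of fiber lengths; default `c(2, 30)` (long
#'   fibers are clipped at the volume bounds when rendered).
#' @param length_meanlog,length_sdlog Log-normal length parameters (rejection
#'   sampled into `length_range_um`).
#' @param radius_um_mean,radius_um_sd Fiber radius distribution (truncated
#'   normal, floor 0.04 um).
#' @param axial_fraction Fraction of fibers drawn steeply tilted (polar
#'   angle within 30 degrees of the optical axis); the rest are uniform on
#'   the sphere. Guarantees fibers that RCM cannot see.
#' @param rcm_k Exponent of the `cos^k(tilt)` RCM orientation response.
#' @param background Mean background level.
#' @param read_noise_sd Gaussian read-noise standard deviation.
#' @param poisson_scale Photon scale of Poisson shot noise (0 disables).
#' @param fl_sigma_xy_um,fl_sigma_z_um Fluorescence PSF widths.
#' @param rcm_sigma_xy_um RCM lateral PSF width at 488 nm (scaled by
#'   `lambda / 488` per wavelength).
#' @param rcm_sigma_z_um RCM axial PSF width.
#' @param spot_amplitude,spot_sigma_frac Central bright-spot artifact height
#'   and Gaussian width (fraction of field extent).
#' @param ring_amplitude,ring_period_um,ring_decay_um Interference-ring
#'   artifact: amplitude near `z = 0`, radial period, exponential decay depth.
#' @param tra_half_depth_um Transmission integration half-depth `h` (thick
#'   focal volume).
#' @param tra_offset_range_nm Focal-offset field range; default
#'   `c(400, 700)`.
#' @param tra_offset_cells Control-grid resolution of the smooth offset field.
#' @param tra_sigma_xy_um Transmission lateral blur.
#' @param tra_absorb Absorption coefficient (fibers dark on bright field).
#' @param seed Scene seed; all randomness derives from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 128L, 128L), meta = stack_meta(),
                         n_fibers = 30L,
                         length_range_um = c(2, 30),
                         length_meanlog = log(8), length_sdlog = 0.6,
                         radius_um_mean = 0.10, radius_um_sd = 0.02,
                         axial_fraction = 0.25,
                         rcm_k = 4,
                         background = 0.05, read_noise_sd = 0.01,
                         poisson_scale = 500,
                         fl_sigma_xy_um = 0.10, fl_sigma_z_um = 0.30,
                         rcm_sigma_xy_um = 0.09, rcm_sigma_z_um = 0.25,
                         spot_amplitude = 0.5, spot_sigma_frac = 0.08,
                         ring_amplitude = 0.3, ring_period_um = 0.8,
                         ring_decay_um = 1.0,
                         tra_half_depth_um = 1.0,
                         tra_offset_range_nm = c(400, 700),
                         tra_offset_cells = 4L,
                         tra_sigma_xy_um = 0.12,
                         tra_absorb = 0.8,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape < 2L)) stop("degenerate volume: every dim must be >= 2")
  stopifnot(n_fibers >= 0L, length_range_um[1] > 0,
            length_range_um[2] > length_range_um[1],
            radius_um_mean > 0, axial_fraction >= 0, axial_fraction <= 1,
            rcm_k >= 0, tra_half_depth_um >= 0,
            tra_offset_range_nm[1] >= 0,
            tra_offset_range_nm[2] >= tra_offset_range_nm[1],
            tra_offset_range_nm[2] < shape[1] * meta$z_step)
  spec <- as.list(environment())
  structure(spec, class = "phantom_spec")
}

# Volume extents in micrometers (z, y, x).
vol_extent_um <- function(spec) {
  c(spec$shape[1] * spec$meta$z_step,
    spec$shape[2] * spec$meta$pixel_size_xy,
    spec$shape[3] * spec$meta$pixel_size_xy) / 1000
}

#' Sample a fiber scene
#'
#' Draws straight fibers with log-normal lengths (truncated to the declared
#' support), truncated-normal radii, and orientations that are uniform on the
#' sphere except for a configured fraction forced steeply out-of-plane.
#' Centers are uniform in the volume; renderers clip to bounds.
#'
#' @param spec A [phantom_spec()].
#' @return List of fiber primitives `list(p0, p1, radius_um, intensity,
#'   tilt_deg, length_um)`; coordinates are `(z, y, x)` micrometers.
#' @export
sample_fibers <- function(spec) {
  set.seed(spec$seed)
  ext <- vol_extent_um(spec)
  fibers <- vector("list", spec$n_fibers)
  if (spec$n_fibers == 0L) return(fibers)
  for (i in seq_len(spec$n_fibers)) {
    repeat {
      len <- stats::rlnorm(1, spec$length_meanlog, spec$length_sdlog)
      if (len >= spec$length_range_um[1] && len <= spec$length_range_um[2])
        break
    }
    r <- max(stats::rnorm(1, spec$radius_um_mean, spec$radius_um_sd), 0.04)
    if (stats::runif(1) < spec$axial_fraction) {
      theta <- acos(stats::runif(1, cos(30 * pi / 180), 1)) # near axis
    } else {
      theta <- acos(stats::runif(1, -1, 1))
    }
    phi <- stats::runif(1, 0, 2 * pi)
    u <- c(cos(theta), sin(theta) * sin(phi), sin(theta) * cos(phi)) # (z,y,x)
    ctr <- stats::runif(3, 0, ext)
    p0 <- ctr - u * len / 2
    p1 <- ctr + u * len / 2
    tilt <- asin(min(abs(u[1]), 1)) * 180 / pi # out-of-plane angle
    fibers[[i]] <- list(p0 = p0, p1 = p1, radius_um = r,
                        intensity = stats::rlnorm(1, 0, 0.15),
                        tilt_deg = tilt, length_um = len)
  }
  fibers
}

# Rasterize fibers into a (z,y,x) density volume; per-fiber weights scale
# intensity. Antialiased solid rods: density ramps over `edge_um` at radius.
rasterize_fibers <- function(fibers, spec, weights = NULL, edge_um = 0.08) {
  d <- spec$shape
  vol <- array(0, dim = d)
  if (length(fibers) == 0L) return(vol)
  if (is.null(weights)) weights <- rep(1, length(fibers))
  vz <- spec$meta$z_step / 1000
  vxy <- spec$meta$pixel_size_xy / 1000
  zc <- (seq_len(d[1]) - 0.5) * vz
  yc <- (seq_len(d[2]) - 0.5) * vxy
  xc <- (seq_len(d[3]) - 0.5) * vxy
  for (i in seq_along(fibers)) {
    f <- fibers[[i]]
    if (weights[i] <= 0) next
    pad <- f$radius_um + edge_um + 2 * vxy
    lo <- pmin(f$p0, f$p1) - pad
    hi <- pmax(f$p0, f$p1) + pad
    zi <- which(zc >= lo[1] - vz & zc <= hi[1] + vz)
    yi <- which(yc >= lo[2] & yc <= hi[2])
    xi <- which(xc >= lo[3] & xc <= hi[3])
    if (!length(zi) || !length(yi) || !length(xi)) next
    nz <- length(zi); ny <- length(yi); nx <- length(xi)
    Pz <- rep(zc[zi], times = ny * nx)
    Py <- rep(rep(yc[yi], each = nz), times = nx)
    Px <- rep(xc[xi], each = nz * ny)
    u <- f$p1 - f$p0
    L2 <- sum(u^2)
    t <- ((Pz - f$p0[1]) * u[1] + (Py - f$p0[2]) * u[2] +
          (Px - f$p0[3]) * u[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    dz <- Pz - (f$p0[1] + t * u[1])
    dy <- Py - (f$p0[2] + t * u[2])
    dx <- Px - (f$p0[3] + t * u[3])
    dist <- sqrt(dz^2 + dy^2 + dx^2)
    dens <- pmin(pmax((f$radius_um + edge_um - dist) / edge_um, 0), 1)
    if (all(dens == 0)) next
    add <- array(dens * f$intensity * weights[i], dim = c(nz, ny, nx))
    vol[zi, yi, xi] <- vol[zi, yi, xi] + add
  }
  vol
}

add_noise <- function(vol, spec, seed_offset) {
  set.seed(spec$seed + seed_offset)
  if (spec$poisson_scale > 0) {
    vol <- array(stats::rpois(length(vol), pmax(vol, 0) * spec$poisson_scale) /
                   spec$poisson_scale, dim = dim(vol))
  }
  if (spec$read_noise_sd > 0) {
    vol <- vol + array(stats::rnorm(length(vol), 0, spec$read_noise_sd),
                       dim = dim(vol))
  }
  vol
}

#' Render the fluorescence ground-truth channel
#'
#' Fibers rasterized at full intensity regardless of orientation, convolved
#' with an anisotropic confocal PSF (`sigma_z > sigma_xy`), plus background
#' and Poisson-Gaussian noise.
#'
#' @param fibers Scene from [sample_fibers()].
#' @param spec The [phantom_spec()].
#' @param noise Disable to obtain the clean render.
#' @return `(z, y, x)` volume.
#' @export
render_fluorescence <- function(fibers, spec, noise = TRUE) {
  vxy <- spec$meta$pixel_size_xy / 1000
  vz <- spec$meta$z_step / 1000
  vol <- rasterize_fibers(fibers, spec)
  vol <- gauss_blur_vol(vol, spec$fl_sigma_z_um / vz,
                        spec$fl_sigma_xy_um / vxy, spec$fl_sigma_xy_um / vxy)
  vol <- vol + spec$background
  if (noise) vol <- add_noise(vol, spec, 15L) else vol
}

rcm_lambdas <- c("405" = 405, "488" = 488, "561" = 561)

#' Render one reflection-confocal channel
#'
#' Each fiber's reflectance is scaled by `cos^k` of its tilt out of the
#' transverse plane, so fibers oriented along the optical axis disappear.
#' The lateral PSF width scales with wavelength. Optional artifacts: an
#' additive central bright spot on every slice and concentric interference
#' rings decaying exponentially with depth from the coverslip (`z = 0`).
#'
#' @param fibers Scene from [sample_fibers()].
#' @param wavelength One of 405, 488, 561 (nm).
#' @param spec The [phantom_spec()].
#' @param artifacts,noise Toggles for artifact overlays and noise.
#' @return `(z, y, x)` volume.
#' @export
render_rcm <- function(fibers, wavelength, spec, artifacts = TRUE,
                       noise = TRUE) {
  wl <- as.character(wavelength)
  if (!wl %in% names(rcm_lambdas)) stop("unknown wavelength: ", wavelength)
  lambda <- rcm_lambdas[[wl]]
  w <- vapply(fibers, function(f) cos(f$tilt_deg * pi / 180)^spec$rcm_k,
              numeric(1))
  vol <- rasterize_fibers(fibers, spec, weights = if (length(w)) w else NULL)
  vxy <- spec$meta$pixel_size_xy / 1000
  vz <- spec$meta$z_step / 1000
  sxy <- spec$rcm_sigma_xy_um * lambda / 488 / vxy
  vol <- gauss_blur_vol(vol, spec$rcm_sigma_z_um / vz, sxy, sxy)
  vol <- vol + spec$background
  if (artifacts) {
    d <- spec$shape
    ext <- vol_extent_um(spec)
    yy <- (seq_len(d[2]) - 0.5) * vxy - ext[2] / 2
    xx <- (seq_len(d[3]) - 0.5) * vxy - ext[3] / 2
    rho <- sqrt(outer(yy^2, xx^2, `+`))
    sig <- spec$spot_sigma_frac * ext[2]
    spot <- spec$spot_amplitude * exp(-rho^2 / (2 * sig^2))
    ring_env <- exp(-rho^2 / (2 * (0.3 * ext[2])^2))
    ring <- spec$ring_amplitude * 0.5 *
      (1 + cos(2 * pi * rho / spec$ring_period_um)) * ring_env
    for (z in seq_len(d[1])) {
      depth <- (z - 0.5) * vz
      vol[z, , ] <- vol[z, , ] + spot +
        ring * exp(-depth / spec$ring_decay_um)
    }
  }
  if (noise) {
    offs <- c("405" = 11L, "488" = 12L, "561" = 13L)[[wl]]
    vol <- add_noise(vol, spec, offs)
  }
  vol
}

#' Smooth focal-offset field for the transmission channel
#'
#' A low-frequency random field in nm, bilinearly interpolated from a coarse
#' control grid of uniform draws in `tra_offset_range_nm`; the offset varies
#' across the field of view without a systematic trend.
#'
#' @param spec The [phantom_spec()].
#' @return `(y, x)` matrix of offsets in nm.
#' @export
focal_offset_field <- function(spec) {
  set.seed(spec$seed + 20L)
  g <- spec$tra_offset_cells
  ctrl <- matrix(stats::runif(g * g, spec$tra_offset_range_nm[1],
                              spec$tra_offset_range_nm[2]), g, g)
  d <- spec$shape
  up <- function(n) {
    if (g == 1L) return(rep(1, n))
    seq(1, g, length.out = n)
  }
  gy <- up(d[2]); gx <- up(d[3])
  y0 <- pmin(floor(gy), g - 1L); x0 <- pmin(floor(gx), g - 1L)
  fy <- gy - y0; fx <- gx - x0
  if (g == 1L) return(matrix(ctrl[1, 1], d[2], d[3]))
  A <- ctrl[cbind(rep(y0, d[3]), rep(x0, each = d[2]))]
  B <- ctrl[cbind(rep(y0 + 1L, d[3]), rep(x0, each = d[2]))]
  C <- ctrl[cbind(rep(y0, d[3]), rep(x0 + 1L, each = d[2]))]
  D <- ctrl[cbind(rep(y0 + 1L, d[3]), rep(x0 + 1L, each = d[2]))]
  FY <- rep(fy, d[3]); FX <- rep(fx, each = d[2])
  matrix(A * (1 - FY) * (1 - FX) + B * FY * (1 - FX) +
         C * (1 - FY) * FX + D * FY * FX, d[2], d[3])
}

#' Render the laser-transmission channel
#'
#' For each output slice `z`, fiber absorbance is averaged over the axial
#' window `[z + delta(y,x) - h, z + delta(y,x) + h]`, where `h` is the
#' integration half-depth (thick focal volume: depth cannot be assigned) and
#' `delta` the smooth focal-offset field. The result is rendered as
#' attenuation of a bright field (`exp(-absorb)`), laterally blurred, with
#' noise. Windows pushed past the volume are clipped.
#'
#' @param fibers Scene from [sample_fibers()].
#' @param spec The [phantom_spec()].
#' @param delta_nm Optional `(y, x)` offset field; defaults to
#'   [focal_offset_field()] of the spec.
#' @param noise Toggle.
#' @return `(z, y, x)` volume (fibers dark on bright background).
#' @export
render_transmission <- function(fibers, spec, delta_nm = NULL, noise = TRUE) {
  d <- spec$shape
  vol <- rasterize_fibers(fibers, spec)
  if (is.null(delta_nm)) delta_nm <- focal_offset_field(spec)
  if (!identical(dim(delta_nm), d[2:3])) {
    if (length(delta_nm) == 1L) {
      delta_nm <- matrix(delta_nm, d[2], d[3])
    } else stop("delta_nm must be scalar or (y, x)")
  }
  shift <- round(delta_nm / spec$meta$z_step)
  hs <- round(spec$tra_half_depth_um * 1000 / spec$meta$z_step)
  # cumulative absorbance along z with a leading zero plane
  C <- array(0, dim = c(d[1] + 1L, d[2], d[3]))
  C[-1L, , ] <- apply(vol, c(2L, 3L), cumsum)
  plane <- d[2] * d[3]
  yx_lin <- seq_len(plane) - 1L # 0-based (y,x) plane offsets
  out <- array(0, dim = d)
  for (z in seq_len(d[1])) {
    hi <- pmin(pmax(z + shift + hs, 1L), d[1])
    lo <- pmin(pmax(z + shift - hs, 1L), d[1])
    sums <- C[1L + hi + (d[1] + 1L) * yx_lin] - C[lo + (d[1] + 1L) * yx_lin]
    cnt <- hi - lo + 1L
    out[z, , ] <- matrix(sums / cnt, d[2], d[3])
  }
  vxy <- spec$meta$pixel_size_xy / 1000
  bright <- 1
  out <- bright * exp(-spec$tra_absorb * out)
  for (z in seq_len(d[1])) {
    out[z, , ] <- gauss_blur_2d(out[z, , ], spec$tra_sigma_xy_um / vxy)
  }
  if (noise) out <- add_noise(out, spec, 14L) else out
}

#' Generate paired label-free / fluorescence stacks
#'
#' Draws `n_stacks` independent scenes (sub-seeded from `seed`) and renders
#' each through all four input modalities plus ground truth, assembling
#' channels `[Ref405, Ref488, Ref561, Tra, GT]`.
#'
#' @param spec A [phantom_spec()]; its `seed` is overridden per stack.
#' @param n_stacks Number of stacks.
#' @param seed Base seed; stack `i` uses `seed + i - 1`.
#' @param artifacts,noise Rendering toggles passed through.
#' @return List of `list(stack, meta, fibers, delta_nm)`; `meta` names the
#'   five channels.
#' @export
make_paired_dataset <- function(spec, n_stacks = 1L, seed = spec$seed,
                                artifacts = TRUE, noise = TRUE) {
  out <- vector("list", n_stacks)
  for (i in seq_len(n_stacks)) {
    sp <- spec
    sp$seed <- as.integer(seed + i - 1L)
    fibers <- sample_fibers(sp)
    delta <- focal_offset_field(sp)
    d <- sp$shape
    stack <- array(0, dim = c(d, 5L))
    stack[, , , 1] <- render_rcm(fibers, 405, sp, artifacts, noise)
    stack[, , , 2] <- render_rcm(fibers, 488, sp, artifacts, noise)
    stack[, , , 3] <- render_rcm(fibers, 561, sp, artifacts, noise)
    stack[, , , 4] <- render_transmission(fibers, sp, delta, noise)
    stack[, , , 5] <- render_fluorescence(fibers, sp, noise)
    meta <- stack_meta(sp$meta$pixel_size_xy, sp$meta$z_step,
                       c("Ref405", "Ref488", "Ref561", "Tra", "GT"))
    out[[i]] <- list(stack = stack, meta = meta, fibers = fibers,
                     delta_nm = delta)
  }
  out
}
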
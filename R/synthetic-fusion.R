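#' Generate a synthetic droplet-fusion image series
#'
#' Renders a time series of 3-D frames in which two spheres (radii `r1`,
#' `r2`) merge into a single prolate spheroid whose aspect ratio relaxes
#' exponentially to 1 with time constant `tau_c = eta_over_gamma * ell`,
#' where `ell = (r1 + r2) / 2` is the characteristic length (mean pre-fusion
#' radius). The spheroid volume equals the summed sphere volumes exactly
#' (before voxelization and noise), so the equivalent final radius is
#' `(r1^3 + r2^3)^(1/3)`. The initial aspect ratio is that of the touching
#' sphere pair, `(r1 + r2) / max(r1, r2)`.
#'
#' The rendering is a geometric morph, not a hydrodynamic solve: only the
#' exponential relaxation law and volume conservation are physical claims.
#'
#' @param r1,r2 pre-fusion droplet radii (um), > 0.
#' @param eta_over_gamma inverse capillary velocity (s/um) setting
#'   `tau_c = eta_over_gamma * ell`.
#' @param frame_interval s between frames.
#' @param n_frames total frames (>= 3); the first `n_pre` show the separated
#'   sphere pair, the rest the relaxing spheroid at times `0, dt, 2 dt, ...`.
#' @param n_pre number of pre-contact frames (>= 1).
#' @param pixel_size,z_step calibration (um).
#' @param background_level,partition_ratio scene intensity model as in
#'   [gen_droplet_stack()].
#' @param psf_sigma_xy,psf_sigma_z PSF sigmas (um); 0 disables.
#' @param poisson,read_noise_sd noise model; set `poisson = FALSE,
#'   read_noise_sd = 0` for noiseless series.
#' @param seed integer seed.
#' @return An [image_stack] (single channel, `n_frames` time points) carrying
#'   a [ground_truth] that includes the exact `tau_c_s`, `ell_um` and the
#'   conserved volumes `V1_um3`, `V2_um3`, `V3_um3`.
#' @seealso [coalescence_relaxation()], [gen_fusion_events()]
#' @export
gen_fusion_series <- function(r1 = 2, r2 = 2, eta_over_gamma = 0.382,
                              frame_interval = 0.25, n_frames = 14L,
                              n_pre = 2L, pixel_size = 0.08, z_step = 0.2,
                              background_level = 20, partition_ratio = 15,
                              psf_sigma_xy = 0, psf_sigma_z = 0,
                              poisson = FALSE, read_noise_sd = 0,
                              seed = 1L) {
  if (r1 <= 0 || r2 <= 0) .stopf("radii must be > 0")
  if (n_frames < 3L) .stopf("need n_frames >= 3 to fit the relaxation")
  if (n_pre < 1L || n_frames - n_pre < 3L)
    .stopf("need at least 3 post-contact frames")
  ell <- (r1 + r2) / 2
  tau_c <- eta_over_gamma * ell
  rf <- (r1^3 + r2^3)^(1 / 3)
  ar0 <- (r1 + r2) / max(r1, r2)
  gap <- 3 * pixel_size                    # pre-contact separation
  # field sized to hold the separated pair and the relaxed sphere
  margin <- 1
  lx <- 2 * (r1 + r2) + gap + 2 * margin
  ly <- 2 * max(r1, r2, rf) + 2 * margin
  lz <- ly
  nx <- as.integer(ceiling(lx / pixel_size)) + 1L
  ny <- as.integer(ceiling(ly / pixel_size)) + 1L
  nz <- as.integer(ceiling(lz / z_step)) + 1L
  xs <- (seq_len(nx) - 1) * pixel_size
  ys <- (seq_len(ny) - 1) * pixel_size
  zs <- (seq_len(nz) - 1) * z_step
  cx <- max(xs) / 2; cy <- max(ys) / 2; cz <- max(zs) / 2

  ellipsoid <- function(a, b) {
    # prolate spheroid, long axis along x, semi-axes (a, b, b)
    ind <- array(FALSE, c(nx, ny, nz))
    dzb2 <- ((zs - cz) / b)^2
    for (k in which(dzb2 <= 1)) {
      rem <- 1 - dzb2[k]
      ind[, , k] <- outer(((xs - cx) / a)^2, ((ys - cy) / b)^2, `+`) <= rem
    }
    ind
  }
  arr <- array(0, c(nx, ny, nz, 1L, n_frames))
  pair <- .sphere_indicator(c(nx, ny, nz), pixel_size, z_step,
                            c(r1, r2),
                            rbind(c(cx - (r2 + gap / 2), cy, cz),
                                  c(cx + (r1 + gap / 2), cy, cz)))
  for (f in seq_len(n_frames)) {
    if (f <= n_pre) {
      ind <- pair
    } else {
      t <- (f - n_pre - 1L) * frame_interval
      ar <- 1 + (ar0 - 1) * exp(-t / tau_c)
      a <- rf * ar^(2 / 3)
      b <- rf / ar^(1 / 3)
      ind <- ellipsoid(a, b)
    }
    vol <- array(background_level, c(nx, ny, nz))
    vol[ind] <- background_level * partition_ratio
    vol <- .gauss_blur3(vol, psf_sigma_xy / pixel_size, psf_sigma_z / z_step)
    arr[, , , 1L, f] <- vol
  }
  if (poisson || read_noise_sd > 0)
    arr <- .with_seed(seed, array(.apply_noise(arr, poisson, read_noise_sd),
                                  dim(arr)))
  v1 <- 4 / 3 * pi * r1^3; v2 <- 4 / 3 * pi * r2^3
  gt <- ground_truth("fusion_series", list(
    r1_um = r1, r2_um = r2, eta_over_gamma_s_per_um = eta_over_gamma,
    tau_c_s = tau_c, ell_um = ell, ar0 = ar0,
    V1_um3 = v1, V2_um3 = v2, V3_um3 = v1 + v2,
    frame_interval_s = frame_interval, n_frames = n_frames, n_pre = n_pre,
    pixel_size_um = pixel_size, z_step_um = z_step,
    background_level = background_level, partition_ratio = partition_ratio,
    poisson = poisson, read_noise_sd = read_noise_sd), seed)
  image_stack(arr, pixel_size = pixel_size, z_step = z_step,
              frame_interval = frame_interval, channels = "droplet",
              ground_truth = gt)
}

#' Generate a table of synthetic fusion events
#'
#' Draws pre-fusion radius pairs uniformly from `r_range`, sets
#' `V3 = V1 + V2` (optionally perturbed by fractional Gaussian volume noise)
#' and `tau_c = eta_over_gamma * ell` (optionally perturbed likewise). With
#' zero noise, volume conservation and the capillary relaxation law hold
#' exactly by construction.
#'
#' @param n number of events.
#' @param r_range range of pre-fusion radii (um).
#' @param eta_over_gamma inverse capillary velocity (s/um).
#' @param volume_noise fractional sd of Gaussian noise on V3 (0 = exact).
#' @param tau_noise fractional sd of Gaussian noise on tau_c.
#' @param seed integer seed.
#' @return A [fusion_events] data.frame with a [ground_truth] attribute.
#' @export
gen_fusion_events <- function(n = 31L, r_range = c(0.5, 2.5),
                              eta_over_gamma = 0.382,
                              volume_noise = 0, tau_noise = 0, seed = 1L) {
  ev <- .with_seed(seed, {
    r1 <- runif(n, r_range[1], r_range[2])
    r2 <- runif(n, r_range[1], r_range[2])
    v1 <- 4 / 3 * pi * r1^3
    v2 <- 4 / 3 * pi * r2^3
    ell <- (r1 + r2) / 2
    v3 <- (v1 + v2) * (1 + if (volume_noise > 0) rnorm(n, sd = volume_noise) else 0)
    tc <- eta_over_gamma * ell * (1 + if (tau_noise > 0) rnorm(n, sd = tau_noise) else 0)
    fusion_events(V1 = v1, V2 = v2, V3 = v3, tau_c = tc, ell = ell)
  })
  attr(ev, "ground_truth") <- ground_truth("fusion_events", list(
    n = n, r_range_um = r_range, eta_over_gamma_s_per_um = eta_over_gamma,
    volume_noise = volume_noise, tau_noise = tau_noise), seed)
  ev
}

#' Generate a synthetic microtubule-aster image
#'
#' Renders a bright central droplet disk with `n_arms` tapered radial ridges
#' (microtubule-bundle projections) at jittered equal angular spacing, plus
#' Poisson/read noise. Ground truth records the exact arm angles. Arms whose
#' jittered spacing falls below the resolvability limit of the counting
#' annulus raise an error advising fewer arms or a larger droplet.
#'
#' @param droplet_diameter droplet diameter (um).
#' @param n_arms number of projections (>= 0).
#' @param arm_length radial arm length beyond the droplet surface (um).
#' @param arm_taper fractional width reduction from arm base to tip, in
#'   \[0, 1).
#' @param angular_jitter_deg arms are displaced from equal spacing by
#'   independent uniform jitter in `[-angular_jitter_deg, +angular_jitter_deg]`.
#' @param arm_width base Gaussian ridge sigma (um).
#' @param min_separation_deg smallest allowed angular gap between arms.
#' @param pixel_size um per pixel.
#' @param background_level background counts.
#' @param droplet_ratio droplet interior : background intensity ratio.
#' @param arm_amp arm ridge peak amplitude : background ratio.
#' @param poisson,read_noise_sd noise model.
#' @param seed integer seed.
#' @return A single-plane [image_stack] carrying a [ground_truth] with the
#'   exact `arm_angles_deg`.
#' @seealso [count_projections()]
#' @export
gen_aster_image <- function(droplet_diameter = 3.08, n_arms = 28L,
                            arm_length = 2.5, arm_taper = 0.6,
                            angular_jitter_deg = 3, arm_width = 0.08,
                            min_separation_deg = 6,
                            pixel_size = 0.04, background_level = 20,
                            droplet_ratio = 10, arm_amp = 4,
                            poisson = TRUE, read_noise_sd = 2, seed = 1L) {
  if (n_arms < 0) .stopf("n_arms must be >= 0")
  R <- droplet_diameter / 2
  angles <- numeric(0)
  if (n_arms > 0) {
    base <- (seq_len(n_arms) - 1) * 360 / n_arms
    jit <- .with_seed(seed, runif(n_arms, -angular_jitter_deg,
                                  angular_jitter_deg))
    angles <- (base + jit) %% 360
    if (n_arms > 1) {
      gaps <- diff(sort(angles))
      gaps <- c(gaps, 360 - sum(gaps))
      if (min(gaps) < min_separation_deg)
        .stopf(paste("arm separation %.2f deg is below the %.1f deg",
                     "resolvability threshold at the counting annulus;",
                     "use fewer arms or a larger droplet"),
               min(gaps), min_separation_deg)
    }
  }
  extent <- 2 * (R + arm_length + 0.5)
  n <- as.integer(ceiling(extent / pixel_size)) + 1L
  xs <- (seq_len(n) - 1) * pixel_size
  c0 <- max(xs) / 2
  dx <- outer(xs - c0, rep(1, n))
  dy <- outer(rep(1, n), xs - c0)
  r <- sqrt(dx^2 + dy^2)
  img <- matrix(background_level, n, n)
  img[r <= R] <- background_level * droplet_ratio
  phi <- atan2(dy, dx) * 180 / pi          # (-180, 180]
  for (a in angles) {
    dphi <- (phi - a + 180) %% 360 - 180   # signed angular offset, deg
    along <- r                              # radial coordinate
    sel <- abs(dphi) < 30 & along >= 0.7 * R & along <= R + arm_length
    if (!any(sel)) next
    s <- along[sel]
    w <- arm_width * (1 - arm_taper * pmin(pmax((s - R) / arm_length, 0), 1))
    perp <- s * sin(dphi[sel] * pi / 180)  # perpendicular distance to ray
    img[sel] <- img[sel] +
      background_level * arm_amp * exp(-perp^2 / (2 * w^2))
  }
  if (poisson || read_noise_sd > 0)
    img <- .with_seed(seed + 1L,
                      .apply_noise(array(img, c(n, n, 1L)), poisson,
                                   read_noise_sd)[, , 1])
  gt <- ground_truth("aster_image", list(
    droplet_diameter_um = droplet_diameter, n_arms = n_arms,
    arm_angles_deg = angles, arm_length_um = arm_length,
    arm_taper = arm_taper, angular_jitter_deg = angular_jitter_deg,
    arm_width_um = arm_width, pixel_size_um = pixel_size,
    background_level = background_level, droplet_ratio = droplet_ratio,
    arm_amp = arm_amp, center_px = c(c0 / pixel_size + 1, c0 / pixel_size + 1),
    poisson = poisson, read_noise_sd = read_noise_sd), seed)
  image_stack(array(img, c(n, n, 1L, 1L, 1L)), pixel_size = pixel_size,
              z_step = pixel_size, channels = "tubulin", ground_truth = gt)
}
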
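#' Generate a synthetic confocal droplet z-stack
#'
#' Renders spherical condensates of given radii and centres on a uniform
#' background, with an interior:exterior intensity ratio per channel (the
#' generating partition coefficient), blurs with a separable anisotropic
#' Gaussian PSF, and applies Poisson shot noise plus Gaussian read noise.
#' With `psf_sigma_xy = 0` and noise disabled the interior/exterior mean
#' intensity ratio equals `partition_ratio` exactly.
#'
#' An optional bright shell (thickness `shell_thickness_um`, intensity ratio
#' `shell_ratio`) can be placed at the droplet surface, emulating tubulin
#' accumulating at the rim of gel-like condensates while the core sits at the
#' lower `partition_ratio`.
#'
#' @param radii numeric vector of droplet radii in micrometres (> 0).
#' @param centers matrix with one row per droplet and columns (x, y, z) in
#'   micrometres; a single droplet may be given as a length-3 vector.
#' @param partition_ratio interior:exterior intensity ratio, one value per
#'   channel (recycled); must be >= 1.
#' @param background_level background intensity in counts.
#' @param dim_px integer (nx, ny, nz) stack size in pixels/planes.
#' @param pixel_size,z_step,frame_interval calibration (um, um, s).
#' @param psf_sigma_xy,psf_sigma_z PSF standard deviations in micrometres; 0
#'   disables blurring along that axis.
#' @param poisson apply Poisson shot noise?
#' @param read_noise_sd Gaussian read-noise standard deviation in counts
#'   (default 2); 0 disables.
#' @param shell_ratio optional per-channel surface-shell intensity ratio
#'   (`NA` for no shell on that channel).
#' @param shell_thickness_um shell thickness in micrometres.
#' @param channels channel labels.
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   stacks.
#' @return An [image_stack] carrying a [ground_truth]; the voxel-level
#'   sphere indicator (pre-PSF, pre-noise) is not stored — use
#'   [droplet_indicator()] to recompute it from the ground truth.
#' @seealso [droplet_indicator()], [segment_droplets()],
#'   [partition_coefficient()]
#' @export
gen_droplet_stack <- function(radii, centers,
                              partition_ratio = 20.5,
                              background_level = 100,
                              dim_px = c(64L, 64L, 9L),
                              pixel_size = 0.1, z_step = 0.5,
                              frame_interval = 1,
                              psf_sigma_xy = 0.1, psf_sigma_z = 0.3,
                              poisson = TRUE, read_noise_sd = 2,
                              shell_ratio = NA_real_,
                              shell_thickness_um = 0.3,
                              channels = NULL, seed = 1L) {
  if (is.numeric(centers) && is.null(dim(centers)))
    centers <- matrix(centers, ncol = 3, byrow = TRUE)
  centers <- as.matrix(centers)
  n <- length(radii)
  if (n != nrow(centers)) .stopf("need one centre per radius")
  if (n > 0 && any(radii <= 0)) .stopf("radii must be > 0")
  if (!isTRUE(pixel_size > 0) || !isTRUE(z_step > 0))
    .stopf("calibrations must be > 0")
  nc <- max(length(partition_ratio), length(shell_ratio), 1L)
  partition_ratio <- rep_len(partition_ratio, nc)
  shell_ratio <- rep_len(shell_ratio, nc)
  if (any(partition_ratio < 1)) .stopf("partition_ratio must be >= 1")
  ext <- c((dim_px[1] - 1) * pixel_size, (dim_px[2] - 1) * pixel_size,
           (dim_px[3] - 1) * z_step)
  for (i in seq_len(n)) {
    lo <- centers[i, ] - radii[i]; hi <- centers[i, ] + radii[i]
    inz <- if (dim_px[3] == 1L) TRUE else (lo[3] >= 0 && hi[3] <= ext[3])
    if (lo[1] < 0 || lo[2] < 0 || hi[1] > ext[1] || hi[2] > ext[2] || !inz)
      .stopf("droplet %d (r = %.3g um at %.3g, %.3g, %.3g) extends beyond the field",
             i, radii[i], centers[i, 1], centers[i, 2], centers[i, 3])
  }

  core <- .sphere_indicator(dim_px, pixel_size, z_step, radii, centers)
  shell <- NULL
  if (any(!is.na(shell_ratio)) && n > 0) {
    inner_r <- pmax(radii - shell_thickness_um, 0)
    inner <- .sphere_indicator(dim_px, pixel_size, z_step, inner_r, centers)
    shell <- core & !inner
    core_only <- inner
  } else core_only <- core

  arr <- array(0, c(dim_px, nc, 1L))
  for (ch in seq_len(nc)) {
    vol <- array(background_level, dim_px)
    if (n > 0) {
      if (!is.na(shell_ratio[ch])) {
        vol[core_only] <- background_level * partition_ratio[ch]
        vol[shell] <- background_level * shell_ratio[ch]
      } else {
        vol[core] <- background_level * partition_ratio[ch]
      }
    }
    vol <- .gauss_blur3(vol, psf_sigma_xy / pixel_size, psf_sigma_z / z_step)
    arr[, , , ch, 1L] <- vol
  }
  if (poisson || read_noise_sd > 0)
    arr <- .with_seed(seed, array(.apply_noise(arr, poisson, read_noise_sd),
                                  dim(arr)))
  gt <- ground_truth("droplet_stack", list(
    radii_um = radii, centers_um = centers,
    partition_ratio = partition_ratio, shell_ratio = shell_ratio,
    shell_thickness_um = shell_thickness_um,
    background_level = background_level, dim_px = dim_px,
    pixel_size_um = pixel_size, z_step_um = z_step,
    psf_sigma_xy_um = psf_sigma_xy, psf_sigma_z_um = psf_sigma_z,
    poisson = poisson, read_noise_sd = read_noise_sd), seed)
  image_stack(arr, pixel_size = pixel_size, z_step = z_step,
              frame_interval = frame_interval, channels = channels,
              ground_truth = gt)
}

# logical (x, y, z) array marking voxels whose centre lies inside any sphere
.sphere_indicator <- function(dim_px, pixel_size, z_step, radii, centers) {
  xs <- (seq_len(dim_px[1]) - 1) * pixel_size
  ys <- (seq_len(dim_px[2]) - 1) * pixel_size
  zs <- (seq_len(dim_px[3]) - 1) * z_step
  ind <- array(FALSE, dim_px)
  for (i in seq_along(radii)) {
    if (radii[i] <= 0) next
    dz2 <- (zs - centers[i, 3])^2
    for (k in which(dz2 <= radii[i]^2)) {
      rk2 <- radii[i]^2 - dz2[k]
      dx2 <- (xs - centers[i, 1])^2
      dy2 <- (ys - centers[i, 2])^2
      ind[, , k] <- ind[, , k] | (outer(dx2, dy2, `+`) <= rk2)
    }
  }
  ind
}

#' Recompute the exact sphere indicator of a synthetic droplet stack
#'
#' @param stack an [image_stack] produced by [gen_droplet_stack()].
#' @return Logical (x, y, z) array: voxels inside any generating sphere.
#' @export
droplet_indicator <- function(stack) {
  gt <- stack$ground_truth
  if (is.null(gt) || gt$scenario != "droplet_stack")
    .stopf("stack has no droplet_stack ground truth")
  p <- gt$params
  .sphere_indicator(p$dim_px, p$pixel_size_um, p$z_step_um, p$radii_um,
                    matrix(p$centers_um, ncol = 3))
}

#' Sample droplet diameters following a shifted power law in concentration
#'
#' The median diameter at concentration x is `a * x^b + c` micrometres;
#' individual diameters are drawn from a normal distribution of that mean and
#' standard deviation `spread_sd`, truncated at zero by redrawing.
#'
#' @param concentrations protein concentrations in micromolar (> 0).
#' @param a,b,c shifted-power-law parameters (y um, x uM); a negative `c`
#'   gives a positive critical concentration `(-c/a)^(1/b)` below which the
#'   median would vanish.
#' @param spread_sd within-condition standard deviation (um).
#' @param n_per_conc samples per concentration.
#' @param seed integer seed.
#' @return A `data.frame` with columns `concentration_uM` and `diameter_um`,
#'   and a [ground_truth] in attribute `"ground_truth"`.
#' @export
gen_diameter_samples <- function(concentrations, a = 1, b = 0.5, c = -0.22,
                                 spread_sd = 0.3, n_per_conc = 100L,
                                 seed = 1L) {
  if (any(concentrations <= 0)) .stopf("concentrations must be > 0")
  med <- a * concentrations^b + c
  bad <- which(med <= 0)
  if (length(bad))
    .stopf("median diameter non-positive at concentration %.4g uM",
           concentrations[bad[1]])
  df <- .with_seed(seed, {
    out <- lapply(seq_along(concentrations), function(i) {
      d <- rnorm(n_per_conc, med[i], spread_sd)
      while (any(d <= 0)) {           # truncate at zero by redraw
        j <- d <= 0
        d[j] <- rnorm(sum(j), med[i], spread_sd)
      }
      data.frame(concentration_uM = concentrations[i], diameter_um = d)
    })
    do.call(rbind, out)
  })
  attr(df, "ground_truth") <- ground_truth("diameter_samples", list(
    concentrations_uM = concentrations, a = a, b = b, c = c,
    medians_um = med, spread_sd_um = spread_sd, n_per_conc = n_per_conc),
    seed)
  df
}

#' Generate a synthetic X-Z image of a surface droplet (spherical cap)
#'
#' Renders the cross-section of a droplet resting on a substrate with a
#' prescribed contact angle: the droplet is the part of a sphere of radius
#' `radius_um` above the substrate plane, with its centre at height
#' `-radius_um * cos(theta)` so that the interior angle between substrate and
#' surface tangent at the contact line equals `theta_deg` (90 deg =
#' hemisphere; < 90 wetting; > 90 dewetting).
#'
#' @param theta_deg generating contact angle in degrees, in (0, 180).
#' @param radius_um sphere radius (um).
#' @param partition_ratio interior:exterior intensity ratio.
#' @param background_level background counts.
#' @param pixel_size pixel size used for both x and z (um).
#' @param psf_sigma PSF sigma (um); 0 disables.
#' @param poisson,read_noise_sd noise model as in [gen_droplet_stack()].
#' @param seed integer seed.
#' @return An [image_stack] whose y axis is the optical (z) axis, substrate
#'   at index 1, carrying a [ground_truth].
#' @export
gen_contact_cap <- function(theta_deg, radius_um = 2,
                            partition_ratio = 10, background_level = 50,
                            pixel_size = 0.05, psf_sigma = 0.05,
                            poisson = TRUE, read_noise_sd = 2, seed = 1L) {
  if (!(theta_deg > 0 && theta_deg < 180)) .stopf("theta must be in (0, 180)")
  th <- theta_deg * pi / 180
  zc <- -radius_um * cos(th)              # sphere centre height above substrate
  base_half <- radius_um * sin(th)        # contact radius
  width <- 2 * max(base_half, radius_um) + 2
  height <- zc + radius_um + 1
  nx <- as.integer(ceiling(width / pixel_size))
  nz <- as.integer(ceiling(height / pixel_size))
  xs <- (seq_len(nx) - 1) * pixel_size
  zs <- (seq_len(nz) - 1) * pixel_size    # z = 0 at substrate
  x0 <- width / 2
  mask <- outer((xs - x0)^2, (zs - zc)^2, `+`) <= radius_um^2
  img <- array(background_level * (1 + (partition_ratio - 1) * mask),
               c(nx, nz, 1L))
  img <- .gauss_blur3(img, psf_sigma / pixel_size, 0)
  if (poisson || read_noise_sd > 0)
    img <- .with_seed(seed, .apply_noise(img, poisson, read_noise_sd))
  gt <- ground_truth("contact_cap", list(
    theta_deg = theta_deg, radius_um = radius_um,
    partition_ratio = partition_ratio, background_level = background_level,
    pixel_size_um = pixel_size, psf_sigma_um = psf_sigma,
    poisson = poisson, read_noise_sd = read_noise_sd), seed)
  image_stack(array(img, c(nx, nz, 1L, 1L, 1L)), pixel_size = pixel_size,
              z_step = pixel_size, ground_truth = gt)
}
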
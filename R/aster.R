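#' Count microtubule-bundle projections around a condensate
#'
#' Takes the maximum-intensity projection over z, samples the intensity on a
#' circle of radius `annulus_factor` times the droplet radius in
#' `angular_bin_deg` bins (bilinear interpolation), smooths the periodic
#' profile, and counts arms as circular local maxima whose topographic
#' prominence exceeds `prominence_k` times the robust noise level of the
#' smoothed profile (estimated from the median absolute sampling residual).
#' Peaks closer than `merge_deg` are counted as one arm (split bundles),
#' with the circular wrap handled. A profile whose total modulation does not
#' clear the noise floor yields zero arms. The count is invariant to image
#' rotation up to the angular relabelling of the arms.
#'
#' @param stack an [image_stack] (e.g. from [gen_aster_image()]).
#' @param droplet either a one-row `droplet_records` table for the central
#'   condensate, or a list/vector with named entries `x_um`, `y_um`,
#'   `diameter_um` (e.g. built from generator ground truth).
#' @param annulus_factor counting-circle radius as a multiple of the droplet
#'   radius (> 1, default 1.3).
#' @param angular_bin_deg angular sampling bin (degrees, default 1).
#' @param prominence_k arms must rise `prominence_k` median absolute
#'   deviations above the median profile (default 3).
#' @param smooth_deg width of the circular smoothing window (degrees).
#' @param merge_deg peaks closer than this are one arm (degrees, default 5).
#' @param channel,time channel and frame index.
#' @return An object of class `aster_record`: list with `n` (projection
#'   count), `angles_deg` (peak angles, in \[0, 360)), `diameter_um`,
#'   `annulus_radius_um`, `profile` (data.frame angle_deg, intensity).
#' @export
count_projections <- function(stack, droplet, annulus_factor = 1.3,
                              angular_bin_deg = 1, prominence_k = 3,
                              smooth_deg = 3, merge_deg = 5,
                              channel = 1L, time = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (annulus_factor <= 1) .stopf("annulus_factor must be > 1")
  if (is.data.frame(droplet)) droplet <- as.list(droplet[1, ])
  px <- stack$pixel_size
  R <- droplet$diameter_um / 2
  if (R < 3 * px) .stopf("droplet too small to count (radius below 3 px)")
  vol <- stack_volume(stack, time = time, channel = channel)
  mip <- apply(vol, c(1, 2), max)
  a_r <- annulus_factor * R
  cx <- droplet$x_um / px + 1; cy <- droplet$y_um / px + 1
  ang <- seq(0, 360 - angular_bin_deg, by = angular_bin_deg)
  rad <- ang * pi / 180
  xi <- cx + (a_r / px) * cos(rad)
  yi <- cy + (a_r / px) * sin(rad)
  if (any(xi < 1 | xi > nrow(mip) | yi < 1 | yi > ncol(mip)))
    .stopf("counting annulus exits the image")
  raw <- .bilinear(mip, xi, yi)
  smooth_bins <- max(1, smooth_deg / angular_bin_deg)
  prof <- .circ_smooth(raw, smooth_bins)
  n_bins <- length(prof)
  # pixel noise from the image corners (arm-free background), scaled to the
  # annulus intensity assuming shot-noise statistics; the 1-degree samples
  # are sub-pixel and therefore correlated, so the profile's own residual
  # cannot estimate the noise
  cs <- max(4L, round(min(dim(mip)) * 0.06))
  corners <- c(mip[1:cs, 1:cs], mip[1:cs, ncol(mip) - 1:cs + 1L],
               mip[nrow(mip) - 1:cs + 1L, 1:cs],
               mip[nrow(mip) - 1:cs + 1L, ncol(mip) - 1:cs + 1L])
  sigma_bg <- max(mad(corners), 1e-9)
  mu_bg <- max(median(corners), 1e-9)
  sigma_ann <- sigma_bg * sqrt(max(median(prof), mu_bg) / mu_bg)
  record <- function(n, angles) structure(
    list(n = n, angles_deg = sort(angles %% 360), diameter_um = 2 * R,
         annulus_radius_um = a_r,
         profile = data.frame(angle_deg = ang, intensity = prof)),
    class = "aster_record")
  peaks <- .circular_peaks(prof)
  if (!length(peaks)) return(record(0L, numeric(0)))
  prom <- .circular_prominence(prof, peaks)
  # bare droplet: even the most prominent wiggle is noise-sized
  if (max(prom) < (prominence_k + 2) * sigma_ann)
    return(record(0L, numeric(0)))
  # arms: prominent both absolutely (vs noise) and relative to the strongest
  keep <- prom >= pmax(prominence_k * sigma_ann, 0.25 * max(prom))
  peaks <- peaks[keep]
  if (!length(peaks)) return(record(0L, numeric(0)))
  # merge peaks closer than merge_deg on the circle, keeping the higher
  merge_bins <- merge_deg / angular_bin_deg
  o <- order(peaks)
  peaks <- peaks[o]
  repeat {
    if (length(peaks) < 2L) break
    gaps <- diff(c(peaks, peaks[1] + n_bins))
    j <- which.min(gaps)
    if (gaps[j] >= merge_bins) break
    a_i <- j; b_i <- if (j == length(peaks)) 1L else j + 1L
    drop_i <- if (prof[peaks[a_i]] >= prof[peaks[b_i]]) b_i else a_i
    peaks <- peaks[-drop_i]
  }
  record(length(peaks), ang[peaks])
}

# circular local maxima: strictly above both neighbours (plateaus take the
# first index)
.circular_peaks <- function(v) {
  n <- length(v)
  left <- v[c(n, seq_len(n - 1L))]
  right <- v[c(seq(2L, n), 1L)]
  which(v > left & v >= right)
}

# topographic prominence of each peak on a circular profile: height minus the
# higher of the two saddle minima encountered walking each way to the nearest
# higher ground; the global maximum keys off the global minimum
.circular_prominence <- function(v, peaks) {
  n <- length(v)
  vapply(peaks, function(p) {
    h <- v[p]
    if (h >= max(v)) return(h - min(v))
    saddle <- function(step) {
      i <- p; lo <- h
      repeat {
        i <- ((i - 1L + step) %% n) + 1L
        if (v[i] > h) return(lo)
        if (v[i] < lo) lo <- v[i]
      }
    }
    h - max(saddle(1L), saddle(-1L))
  }, numeric(1))
}

#' @export
print.aster_record <- function(x, ...) {
  cat(sprintf("<aster_record> %d projections (droplet %.3g um, annulus %.3g um)\n",
              x$n, x$diameter_um, x$annulus_radius_um))
  invisible(x)
}

#' Quadratic scaling of projection number with droplet diameter
#'
#' Weighted least-squares parabola `N = alpha d^2 + beta d + delta` through
#' (diameter, projection count) medians. The quadratic form reflects arms
#' scaling with droplet surface area. With exactly three points the fit
#' interpolates them exactly.
#'
#' @param diameters droplet diameters (um), >= 3 points.
#' @param counts projection counts.
#' @param sems optional standard errors of the counts (weights `1/sem^2`).
#' @return An object of class `projection_scaling_fit`: list with `alpha`,
#'   `beta`, `delta`, `vcov`, `fitted`.
#' @export
fit_projection_scaling <- function(diameters, counts, sems = NULL) {
  d <- as.numeric(diameters); n <- as.numeric(counts)
  if (length(d) < 3L) .stopf("need at least 3 (diameter, count) points")
  w <- if (!is.null(sems)) 1 / sems^2 else rep(1, length(d))
  fit <- lm(n ~ I(d^2) + d, weights = w)
  co <- coef(fit)
  structure(list(alpha = unname(co["I(d^2)"]), beta = unname(co["d"]),
                 delta = unname(co["(Intercept)"]),
                 # three points interpolate exactly; the perfect-fit summary
                 # caveat is expected, not actionable
                 vcov = suppressWarnings(vcov(fit)),
                 fitted = as.numeric(predict(fit))),
            class = "projection_scaling_fit")
}

#' @export
print.projection_scaling_fit <- function(x, ...) {
  cat(sprintf("<projection_scaling_fit> N = %.4g d^2 + %.4g d + %.4g\n",
              x$alpha, x$beta, x$delta))
  invisible(x)
}
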
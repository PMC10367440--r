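#' Partition coefficient of droplets, p = Iin / Iout
#'
#' For each droplet, the interior mean intensity `Iin` is taken over its
#' equatorial-plane mask eroded by `erode_px` pixels (excluding the
#' PSF-blurred boundary), and the exterior mean `Iout` over an annulus from
#' `annulus_px[1]` to `annulus_px[2]` pixels beyond the boundary with every
#' droplet mask excluded. Per-droplet ratios `p_i = Iin_i / Iout_i` are
#' aggregated as mean and standard error. Being a ratio, the result is
#' invariant to multiplying the whole image by a positive constant.
#'
#' Droplets whose annulus is fully occluded by neighbours are skipped with a
#' message; an exactly zero exterior intensity is an error.
#'
#' @param stack the [image_stack] the droplets were segmented from.
#' @param droplets a `droplet_records` table from [segment_droplets()]
#'   (carries the label masks).
#' @param channel channel to measure (may differ from the segmentation
#'   channel, e.g. tubulin partitioning into MAP65-segmented droplets).
#' @param time frame index.
#' @param erode_px interior mask erosion in pixels.
#' @param annulus_px length-2 inner/outer annulus distances in pixels.
#' @return An object of class `partition_result`: list with `p`, `sem`,
#'   `Iin`, `Iout`, `n`, and the per-droplet table `per_droplet`.
#' @export
partition_coefficient <- function(stack, droplets, channel = NULL,
                                  time = NULL, erode_px = 2L,
                                  annulus_px = c(3L, 6L)) {
  stopifnot(inherits(stack, "image_stack"), inherits(droplets, "droplet_records"))
  if (nrow(droplets) == 0L) .stopf("need at least one droplet")
  if (is.null(channel)) channel <- attr(droplets, "channel")
  if (is.null(time)) time <- attr(droplets, "time")
  labels <- attr(droplets, "labels")
  vol <- stack_volume(stack, time = time, channel = channel)
  brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
  res <- lapply(seq_len(nrow(droplets)), function(i) {
    id <- droplets$label[i]; z <- droplets$eq_z[i]
    plane <- vol[, , z]
    lab2 <- labels[, , z]
    mask <- lab2 == id
    inner <- if (erode_px > 0)
      EBImage::erode(EBImage::Image(mask * 1), brush(erode_px)) > 0 else mask
    if (!any(inner)) {
      message(sprintf("droplet %d: eroded mask empty, skipped", id))
      return(NULL)
    }
    outer1 <- EBImage::dilate(EBImage::Image(mask * 1), brush(annulus_px[1])) > 0
    outer2 <- EBImage::dilate(EBImage::Image(mask * 1), brush(annulus_px[2])) > 0
    ann <- outer2 & !outer1 & lab2 == 0L
    if (!any(ann)) {
      message(sprintf("droplet %d: annulus fully occluded, skipped", id))
      return(NULL)
    }
    iin <- mean(plane[inner]); iout <- mean(plane[ann])
    if (iout == 0) .stopf("zero exterior intensity for droplet %d", id)
    data.frame(label = id, Iin = iin, Iout = iout, p = iin / iout)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) .stopf("no droplet had a usable annulus")
  p <- mean(res$p)
  sem <- if (nrow(res) > 1) sd(res$p) / sqrt(nrow(res)) else NA_real_
  structure(list(p = p, sem = sem, Iin = mean(res$Iin), Iout = mean(res$Iout),
                 n = nrow(res), per_droplet = res),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> p = %.3g +/- %.2g (SEM), n = %d droplets\n",
              x$p, x$sem, x$n))
  invisible(x)
}

#' Normalized intensity line profile through a droplet centre
#'
#' Extracts the intensity along the x line through the droplet centroid at
#' its equatorial plane, and normalizes it so that the flanking background
#' windows (outside the droplet and its blurred rim) average exactly 1.
#' Reports the profile's peak value and its value at the droplet centre
#' separately, which distinguishes surface-shell accumulation (peak well
#' above centre) from uniformly filled droplets.
#'
#' @inheritParams partition_coefficient
#' @param droplet_index row of `droplets` to profile.
#' @param margin_px pixels beyond the mask excluded from the background
#'   window.
#' @return An object of class `profile_scan`: list with `positions` (um,
#'   along x), `intensity` (background == 1), `peak`, `center`.
#' @export
shell_profile <- function(stack, droplets, droplet_index = 1L,
                          channel = NULL, time = NULL, margin_px = 3L) {
  stopifnot(inherits(stack, "image_stack"), inherits(droplets, "droplet_records"))
  if (is.null(channel)) channel <- attr(droplets, "channel")
  if (is.null(time)) time <- attr(droplets, "time")
  d <- droplets[droplet_index, ]
  labels <- attr(droplets, "labels")
  px <- stack$pixel_size
  plane <- stack_volume(stack, time = time, channel = channel)[, , d$eq_z]
  lab2 <- labels[, , d$eq_z]
  yi <- round(d$y_um / px) + 1L
  if (yi < 1L || yi > ncol(plane)) .stopf("profile exits the image")
  line <- plane[, yi]
  online <- lab2[, yi] == d$label
  if (!any(online)) .stopf("droplet mask does not intersect the profile line")
  ext <- range(which(online))
  idx <- seq_along(line)
  bgidx <- which((idx < ext[1] - margin_px | idx > ext[2] + margin_px) &
                   lab2[, yi] == 0L)
  if (length(bgidx) < 3L) .stopf("profile exits the image: no background window")
  norm <- line / mean(line[bgidx])
  inside <- seq(ext[1], ext[2])
  ci <- round(d$x_um / px) + 1L
  center_idx <- intersect(seq(ci - 1L, ci + 1L), inside)
  structure(list(positions = (seq_along(line) - 1) * px,
                 intensity = norm,
                 peak = max(norm[inside]),
                 center = mean(norm[center_idx]),
                 droplet = d$label),
            class = "profile_scan")
}

#' @export
print.profile_scan <- function(x, ...) {
  cat(sprintf("<profile_scan> %d points, peak %.3g, center %.3g\n",
              length(x$positions), x$peak, x$center))
  invisible(x)
}

#' Radially averaged intensity profile
#'
#' Bins pixel intensities of a plane by distance from a centre, giving the
#' radial profile used for whole-droplet FRAP diffusion fits.
#'
#' @param plane numeric matrix (x, y).
#' @param center (x, y) centre in micrometres.
#' @param pixel_size um per pixel.
#' @param bin_width radial bin width (um); default one pixel.
#' @param max_radius largest radius to keep (um).
#' @return A `profile_scan`-like list with `positions` (bin centres, um) and
#'   `intensity` (mean per bin).
#' @export
radial_profile <- function(plane, center, pixel_size, bin_width = pixel_size,
                           max_radius = NULL) {
  xs <- (seq_len(nrow(plane)) - 1) * pixel_size
  ys <- (seq_len(ncol(plane)) - 1) * pixel_size
  r <- sqrt(outer((xs - center[1])^2, (ys - center[2])^2, `+`))
  if (is.null(max_radius)) max_radius <- max(r)
  sel <- r <= max_radius
  bins <- floor(r[sel] / bin_width)
  mean_i <- tapply(plane[sel], bins, mean)
  structure(list(positions = (as.numeric(names(mean_i)) + 0.5) * bin_width,
                 intensity = as.numeric(mean_i)),
            class = "profile_scan")
}

#' Interior concentration implied by a partition coefficient
#'
#' The mean concentration of a partitioned species inside a condensate is the
#' partition coefficient times the (dilute-phase) concentration outside:
#' e.g. tubulin partitioning at p = 4.8 into a shell from 3.75 uM added gives
#' 18 uM in the shell.
#'
#' @param p partition coefficient (dimensionless, > 0).
#' @param outside_uM concentration of the dilute phase (uM).
#' @return Interior concentration in uM.
#' @export
interior_concentration <- function(p, outside_uM) {
  if (any(p <= 0) || any(outside_uM < 0)) .stopf("inputs must be positive")
  p * outside_uM
}
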
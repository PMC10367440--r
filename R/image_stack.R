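#' Calibrated multi-dimensional image stack
#'
#' The common currency of all image operations in the package: an intensity
#' array with axes (x, y, z, channel, time), any of which may be singleton,
#' together with its spatial and temporal calibration. Intensities are in
#' arbitrary camera counts and must be non-negative; pixel coordinates are
#' 0-based at pixel centres, so pixel index `i` (1-based in R) sits at
#' physical position `(i - 1) * pixel_size` micrometres.
#'
#' @param data numeric array with 2 to 5 dimensions, interpreted as
#'   (x, y\[, z\[, channel\[, time\]\]\]); missing trailing axes are added as
#'   singletons.
#' @param pixel_size lateral pixel size in micrometres (> 0).
#' @param z_step axial step between z planes in micrometres (> 0).
#' @param frame_interval time between frames in seconds (> 0).
#' @param channels character vector of channel labels, one per channel axis
#'   entry (default `"ch1"`, `"ch2"`, ...).
#' @param ground_truth optional `ground_truth` object attached by the
#'   synthetic generators.
#'
#' @return An object of class `image_stack`: a list with elements `data`
#'   (5-D array), `pixel_size`, `z_step`, `frame_interval`, `channels` and
#'   optionally `ground_truth`.
#' @examples
#' s <- image_stack(array(1, c(8, 8)), pixel_size = 0.1)
#' dim(s$data)
#' @export
image_stack <- function(data, pixel_size, z_step = pixel_size,
                        frame_interval = 1, channels = NULL,
                        ground_truth = NULL) {
  if (!is.array(data) && !is.matrix(data)) .stopf("`data` must be an array")
  d <- dim(data)
  if (length(d) < 2L || length(d) > 5L)
    .stopf("`data` must have 2 to 5 dimensions, got %d", length(d))
  dim(data) <- c(d, rep(1L, 5L - length(d)))
  if (any(data < 0)) .stopf("intensities must be non-negative")
  if (!isTRUE(pixel_size > 0) || !isTRUE(z_step > 0) || !isTRUE(frame_interval > 0))
    .stopf("calibrations (pixel_size, z_step, frame_interval) must be > 0")
  nc <- dim(data)[4]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc)
    .stopf("%d channel labels supplied for %d channels", length(channels), nc)
  structure(list(data = data, pixel_size = pixel_size, z_step = z_step,
                 frame_interval = frame_interval, channels = channels,
                 ground_truth = ground_truth),
            class = "image_stack")
}

#' Extract one (x, y, z) volume or a single plane from a stack
#'
#' @param stack an [image_stack].
#' @param time,channel 1-based frame and channel index (a channel label is
#'   also accepted).
#' @return `stack_volume()` returns a 3-D (x, y, z) array; `stack_plane()` a
#'   2-D (x, y) matrix at plane `z`.
#' @export
stack_volume <- function(stack, time = 1L, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) channel <- match(channel, stack$channels)
  d <- dim(stack$data)
  if (is.na(channel) || channel < 1L || channel > d[4]) .stopf("no such channel")
  if (time < 1L || time > d[5]) .stopf("no such frame")
  array(stack$data[, , , channel, time], d[1:3])
}

#' @param z 1-based z-plane index.
#' @rdname stack_volume
#' @export
stack_plane <- function(stack, z = 1L, time = 1L, channel = 1L) {
  v <- stack_volume(stack, time = time, channel = channel)
  if (z < 1L || z > dim(v)[3]) .stopf("no such z plane")
  v[, , z]
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d px, %d z, %d channel(s) [%s], %d frame(s)\n",
    d[1], d[2], d[3], d[4], paste(x$channels, collapse = ", "), d[5]))
  cat(sprintf("  pixel %.4g um, z-step %.4g um, frame interval %.4g s\n",
              x$pixel_size, x$z_step, x$frame_interval))
  if (!is.null(x$ground_truth))
    cat(sprintf("  ground truth: %s\n", x$ground_truth$scenario))
  invisible(x)
}

#' Ground-truth record attached to synthetic artifacts
#'
#' Every synthetic generator attaches exactly one of these to its output. It
#' stores the scenario label, the full generating parameter map (with units in
#' the names where meaningful) and the seed, so that the identical artifact
#' can be regenerated from the serialized record.
#'
#' @param scenario short scenario label, e.g. `"droplet_stack"`.
#' @param params named list of generating parameters.
#' @param seed integer seed used for all randomness in the artifact.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(scenario, params, seed) {
  structure(list(scenario = scenario, params = params, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s (seed %s)\n", x$scenario,
              format(x$seed)))
  str(x$params, no.list = TRUE, give.attr = FALSE)
  invisible(x)
}

#' Serialize / restore a ground-truth record as JSON
#'
#' @param gt a [ground_truth] object.
#' @param path file path for the JSON record.
#' @return `read_ground_truth()` returns the restored `ground_truth`.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(x$scenario, x$params, x$seed)
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are written time-major with z inner and channels interleaved within
#' each (time, z) pair; the calibration (and any ground truth) goes into a
#' JSON sidecar `<path>.json`. Intensities are stored as 32-bit float after
#' scaling into \[0, 1\] by the recorded `intensity_max`.
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `read_stack_tiff()` returns the restored [image_stack].
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  mx <- max(stack$data, 1)
  pages <- list()
  for (t in seq_len(d[5])) for (z in seq_len(d[3])) for (ch in seq_len(d[4]))
    # tiff expects row-major (y, x) matrices
    pages[[length(pages) + 1L]] <- t(stack$data[, , z, ch, t]) / mx
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- list(pixel_size_um = stack$pixel_size, z_step_um = stack$z_step,
               frame_interval_s = stack$frame_interval,
               channels = stack$channels, n_z = d[3], n_time = d[5],
               intensity_max = mx,
               ground_truth = if (!is.null(stack$ground_truth))
                 unclass(stack$ground_truth))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- side$n_z; nt <- side$n_time
  nc <- length(pages) / (nz * nt)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(nx, ny, nz, nc, nt))
  i <- 1L
  for (t in seq_len(nt)) for (z in seq_len(nz)) for (ch in seq_len(nc)) {
    arr[, , z, ch, t] <- t(pages[[i]]) * side$intensity_max
    i <- i + 1L
  }
  gt <- if (!is.null(side$ground_truth))
    ground_truth(side$ground_truth$scenario, side$ground_truth$params,
                 side$ground_truth$seed)
  image_stack(arr, pixel_size = side$pixel_size_um, z_step = side$z_step_um,
              frame_interval = side$frame_interval_s, channels = side$channels,
              ground_truth = gt)
}
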
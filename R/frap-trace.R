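#' FRAP time-intensity trace
#'
#' A region-of-interest photobleaching record: times, ROI mean intensities,
#' optional unbleached reference-ROI intensities (for photofade correction)
#' and optional background intensities, plus the prebleach frame count and
#' the bleach-spot radius.
#'
#' @param time strictly increasing times in seconds.
#' @param roi ROI mean intensities.
#' @param reference optional reference-ROI intensities (same length).
#' @param background optional background intensities (same length).
#' @param prebleach_frames number of frames acquired before the bleach.
#' @param bleach_index 1-based index of the bleach frame; `NULL` to
#'   auto-detect (global minimum within 3 frames after the largest
#'   single-frame drop).
#' @param roi_radius bleach-spot radius in micrometres (default 0.55).
#' @param normalized has the trace already been normalized?
#' @param ground_truth optional [ground_truth].
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(time, roi, reference = NULL, background = NULL,
                       prebleach_frames = NULL, bleach_index = NULL,
                       roi_radius = 0.55, normalized = FALSE,
                       ground_truth = NULL) {
  if (any(diff(time) <= 0)) .stopf("times must be strictly increasing")
  if (length(roi) != length(time)) .stopf("roi and time lengths differ")
  if (!is.null(reference) && length(reference) != length(time))
    .stopf("reference length differs from time")
  if (!is.null(background) && length(background) != length(time))
    .stopf("background length differs from time")
  if (!isTRUE(roi_radius > 0)) .stopf("roi_radius must be > 0")
  if (is.null(bleach_index)) {
    drops <- diff(roi)
    j <- which.min(drops)                 # largest single-frame drop
    cand <- seq(j + 1L, min(j + 3L, length(roi)))
    bleach_index <- cand[which.min(roi[cand])]
  }
  if (bleach_index <= 1L) .stopf("bleach index must be > 1")
  if (is.null(prebleach_frames)) prebleach_frames <- bleach_index - 1L
  structure(list(time = as.numeric(time), roi = as.numeric(roi),
                 reference = reference, background = background,
                 prebleach_frames = as.integer(prebleach_frames),
                 bleach_index = as.integer(bleach_index),
                 roi_radius = roi_radius, normalized = isTRUE(normalized),
                 ground_truth = ground_truth),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d frames, bleach at frame %d (t = %.3g s)%s\n",
              length(x$time), x$bleach_index, x$time[x$bleach_index],
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize a FRAP trace
#'
#' Applies, in order: background subtraction (if a background series is
#' present), point-wise division by the reference ROI (photofade correction,
#' if present), then the affine rescaling that sets the prebleach mean to 1
#' and the bleach-frame value to 0. Time is re-zeroed at the bleach frame.
#' The result is idempotent and invariant to any positive affine transform of
#' the input intensities.
#'
#' @param trace a [frap_trace].
#' @return A normalized [frap_trace] (reference/background consumed).
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  v <- trace$roi
  if (!is.null(trace$background)) v <- v - trace$background
  if (!is.null(trace$reference)) {
    ref <- trace$reference
    if (!is.null(trace$background)) ref <- ref - trace$background
    pre <- seq_len(trace$bleach_index - 1L)
    v <- v / (ref / mean(ref[pre]))       # unit gain prebleach
  }
  pre <- seq_len(trace$bleach_index - 1L)
  i0 <- mean(v[pre])
  ib <- v[trace$bleach_index]
  if (i0 <= ib) .stopf("no bleach detected: prebleach mean <= bleach value")
  vn <- (v - ib) / (i0 - ib)
  frap_trace(time = trace$time - trace$time[trace$bleach_index],
             roi = vn,
             prebleach_frames = trace$prebleach_frames,
             bleach_index = trace$bleach_index,
             roi_radius = trace$roi_radius, normalized = TRUE,
             ground_truth = trace$ground_truth)
}

#' Read / write FRAP traces as CSV
#'
#' The CSV has columns `time_s`, `roi` and optionally `reference`,
#' `background`, with a header row.
#'
#' @param trace a [frap_trace].
#' @param path CSV path.
#' @param ... passed to [frap_trace()] on reading (e.g. `bleach_index`,
#'   `roi_radius`).
#' @return `read_frap_trace()` returns a [frap_trace].
#' @export
write_frap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  df <- data.frame(time_s = trace$time, roi = trace$roi)
  if (!is.null(trace$reference)) df$reference <- trace$reference
  if (!is.null(trace$background)) df$background <- trace$background
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_trace
#' @export
read_frap_trace <- function(path, ...) {
  df <- read.csv(path)
  frap_trace(df$time_s, df$roi, reference = df$reference,
             background = df$background, ...)
}
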
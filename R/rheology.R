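#' Stokes-Einstein viscosity from a diffusion coefficient
#'
#' `eta = kB T / (6 pi D R_h)` with `kB = 1.380649e-23 J/K`, converting from
#' the microscopy-native units (D in um^2/s, hydrodynamic radius in nm) to
#' Pa s. The default hydrodynamic radius 4.2 nm and temperature 295 K (22 C
#' room temperature) are those appropriate to MAP65-scale proteins.
#'
#' @param D diffusion coefficient (um^2/s, > 0).
#' @param R_h hydrodynamic radius (nm, > 0).
#' @param T_K absolute temperature (K, > 0).
#' @return Viscosity in Pa s.
#' @examples
#' stokes_einstein_viscosity(0.0054, 4.2, 295)  # ~9.5 Pa s
#' @export
stokes_einstein_viscosity <- function(D, R_h = 4.2, T_K = 295) {
  if (any(D <= 0) || any(R_h <= 0) || any(T_K <= 0))
    .stopf("D, R_h and T_K must all be > 0")
  kB <- 1.380649e-23
  kB * T_K / (6 * pi * (D * 1e-12) * (R_h * 1e-9))
}

#' @rdname stokes_einstein_viscosity
#' @param eta viscosity (Pa s, > 0); `stokes_einstein_diffusion()` inverts
#'   the relation, returning D in um^2/s.
#' @export
stokes_einstein_diffusion <- function(eta, R_h = 4.2, T_K = 295) {
  if (any(eta <= 0) || any(R_h <= 0) || any(T_K <= 0))
    .stopf("eta, R_h and T_K must all be > 0")
  kB <- 1.380649e-23
  kB * T_K / (6 * pi * eta * (R_h * 1e-9)) * 1e12
}

#' Table of droplet-fusion events
#'
#' @param V1,V2 pre-fusion droplet volumes (um^3, > 0).
#' @param V3 post-fusion volume (um^3, > 0).
#' @param tau_c coalescence relaxation time (s, > 0; `NA` for gel-like
#'   events that did not relax).
#' @param ell characteristic length: mean pre-fusion radius (um, > 0).
#' @return A `data.frame` of class `fusion_events` with those columns and an
#'   `event` id.
#' @export
fusion_events <- function(V1, V2, V3, tau_c, ell) {
  if (any(c(V1, V2, V3) <= 0)) .stopf("volumes must be > 0")
  if (any(tau_c <= 0, na.rm = TRUE)) .stopf("tau_c must be > 0")
  if (any(ell <= 0)) .stopf("ell must be > 0")
  out <- data.frame(event = seq_along(V1), V1 = V1, V2 = V2, V3 = V3,
                    tau_c = tau_c, ell = ell)
  class(out) <- c("fusion_events", "data.frame")
  out
}

#' Read / write fusion-event tables as CSV
#'
#' Columns: `event_id, V1_um3, V2_um3, V3_um3, tau_c_s, ell_um`.
#' @param events a [fusion_events] table.
#' @param path CSV path.
#' @return `read_fusion_events()` returns a [fusion_events] table.
#' @export
write_fusion_events <- function(events, path) {
  df <- data.frame(event_id = events$event, V1_um3 = events$V1,
                   V2_um3 = events$V2, V3_um3 = events$V3,
                   tau_c_s = events$tau_c, ell_um = events$ell)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fusion_events
#' @export
read_fusion_events <- function(path) {
  df <- read.csv(path)
  fusion_events(df$V1_um3, df$V2_um3, df$V3_um3, df$tau_c_s, df$ell_um)
}

#' Volume conservation across fusion events
#'
#' Regresses the post-fusion volume `V3` on the summed pre-fusion volume
#' `V1 + V2` with the intercept fixed at zero. A slope of 1 means droplet
#' volume is conserved on merging.
#'
#' @param events a [fusion_events] table (>= 3 events).
#' @param conf confidence level of the interval.
#' @return List with `slope`, `se`, `ci` (length 2), `n`.
#' @export
fusion_volume_regression <- function(events, conf = 0.95) {
  if (nrow(events) < 3L) .stopf("need at least 3 fusion events")
  vsum <- events$V1 + events$V2
  fit <- lm(V3 ~ 0 + vsum, data = data.frame(V3 = events$V3, vsum = vsum))
  # noiseless synthetic events fit exactly; the perfect-fit summary caveat
  # is expected there, not actionable
  ci <- suppressWarnings(confint(fit, level = conf))
  list(slope = unname(coef(fit)[1]),
       se = suppressWarnings(unname(sqrt(diag(vcov(fit)))[1])),
       ci = as.numeric(ci), n = nrow(events))
}

#' Extract a fusion event from an image time series
#'
#' Segments every frame of a two-droplet coalescence movie; pre-fusion
#' volumes come from the last frame showing two separate components, and the
#' post-contact shape relaxation is measured as the aspect ratio of the
#' merged object's equatorial plane (principal-axis ratio of the mask),
#' fitted with `AR(t) = 1 + (AR0 - 1) exp(-t / tau_c)`. The characteristic
#' length is the mean of the two pre-fusion (volume-equivalent) radii. A
#' series whose aspect ratio does not relax within the movie (gel-like
#' droplets that cannot merge) is returned flagged `"no merge relaxation"`
#' with `tau_c = NA`.
#'
#' @param event_stack an [image_stack] time series containing exactly one
#'   two-droplet merge (e.g. from [gen_fusion_series()]).
#' @param channel channel index.
#' @param smoothing_sigma pre-threshold smoothing passed to
#'   [segment_droplets()]; use 0 for noiseless series, since smoothing
#'   erodes the high-curvature tips of the elongated merged droplet and
#'   biases the early aspect ratios.
#' @return A one-row [fusion_events] table with attributes
#'   `"aspect_ratio"` (data.frame time_s, AR) and `"flag"`.
#' @export
coalescence_relaxation <- function(event_stack, channel = 1L,
                                   smoothing_sigma = NULL) {
  stopifnot(inherits(event_stack, "image_stack"))
  nt <- dim(event_stack$data)[5]
  if (nt < 3L) .stopf("need at least 3 frames")
  px <- event_stack$pixel_size; pz <- event_stack$z_step
  frames <- lapply(seq_len(nt), function(t)
    suppressWarnings(segment_droplets(event_stack, channel = channel, time = t,
                                      smoothing_sigma = smoothing_sigma,
                                      split_touching = FALSE)))
  ncomp <- vapply(frames, nrow, integer(1))
  merge_at <- which(ncomp == 1L)
  if (!length(merge_at) || !any(ncomp == 2L))
    .stopf("no merge detected: need frames with two droplets followed by one")
  cand <- merge_at[merge_at > max(which(ncomp == 2L))]
  if (!length(cand)) .stopf("no merge detected after the two-droplet frames")
  i_merge <- min(cand)
  i_pre <- max(which(ncomp == 2L & seq_len(nt) < i_merge))
  if (nt - i_merge + 1L < 3L) .stopf("fewer than 3 post-contact frames")
  pre <- frames[[i_pre]]
  v1 <- pre$volume_um3[1]; v2 <- pre$volume_um3[2]
  r_eq <- (3 * c(v1, v2) / (4 * pi))^(1 / 3)
  ell <- mean(r_eq)

  aspect <- function(rec) {
    labels <- attr(rec, "labels")
    m <- which(labels[, , rec$eq_z[1]] == rec$label[1], arr.ind = TRUE)
    cv <- stats::cov(m)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    sqrt(max(ev) / max(min(ev), 1e-12))
  }
  post_idx <- seq(i_merge, nt)
  ar <- vapply(frames[post_idx], aspect, numeric(1))
  t_post <- (post_idx - i_merge) * event_stack$frame_interval
  v3 <- frames[[nt]]$volume_um3[1]

  flag <- NA_character_
  tau_c <- NA_real_
  relax <- (ar[1] - ar[length(ar)]) / max(ar[1] - 1, 1e-9)
  if (ar[1] < 1.05 || relax < 0.2) {
    flag <- "no merge relaxation"
  } else {
    # drop the fully relaxed tail, where mask voxelization quantizes AR
    floor_ar <- 1 + 0.05 * (ar[1] - 1)
    cut <- which(ar <= floor_ar)
    use <- if (length(cut) && cut[1] > 3L) seq_len(cut[1]) else seq_along(ar)
    fit <- .best_nls(y ~ 1 + (ar0 - 1) * exp(-t / tau),
                     data.frame(t = t_post[use], y = ar[use]),
                     lapply(max(t_post[use]) * c(0.05, 0.2, 1), function(tau0)
                       list(ar0 = ar[1], tau = tau0)),
                     lower = c(1, 1e-9), upper = c(Inf, Inf))
    if (is.null(fit)) flag <- "no merge relaxation"
    else tau_c <- unname(coef(fit)["tau"])
  }
  ev <- fusion_events(V1 = v1, V2 = v2, V3 = v3, tau_c = tau_c, ell = ell)
  attr(ev, "aspect_ratio") <- data.frame(time_s = t_post, AR = ar)
  attr(ev, "flag") <- flag
  ev
}

#' Surface tension from coalescence relaxation times
#'
#' For liquid droplets the shape-relaxation time of a merge scales with the
#' droplet size as `tau_c = (eta / gamma) * ell`; the through-origin slope of
#' `tau_c` against `ell` is the inverse capillary velocity (s/um), and with
#' an independent viscosity the surface tension follows as
#' `gamma = eta / slope` (Pa s / (s/um) = uN/m). Events flagged without
#' relaxation (`tau_c = NA`) are excluded.
#'
#' @param events a [fusion_events] table with >= 3 liquid-like events.
#' @param eta condensate viscosity (Pa s, > 0).
#' @param R_h,T_K optional provenance of `eta`, carried into the result.
#' @return An object of class `rheology_result`: list with `viscosity`
#'   (Pa s), `surface_tension` (uN/m), `inverse_capillary_velocity` (s/um),
#'   `R_h`, `T_K`, `n_events`.
#' @export
surface_tension <- function(events, eta, R_h = NA_real_, T_K = NA_real_) {
  if (!isTRUE(eta > 0)) .stopf("eta must be > 0")
  ok <- !is.na(events$tau_c)
  if (sum(ok) < 3L) .stopf("need at least 3 liquid-like (relaxing) events")
  ev <- events[ok, ]
  fit <- lm(tau_c ~ 0 + ell, data = ev)
  slope <- unname(coef(fit)[1])
  if (slope <= 0) .stopf("non-positive tau_c vs ell slope; no capillary regime")
  structure(list(viscosity = eta, surface_tension = eta / slope,
                 inverse_capillary_velocity = slope,
                 R_h = R_h, T_K = T_K, n_events = sum(ok)),
            class = "rheology_result")
}

#' @export
print.rheology_result <- function(x, ...) {
  cat(sprintf("<rheology_result> eta = %.3g Pa s, gamma = %.3g uN/m (eta/gamma = %.3g s/um, n = %d)\n",
              x$viscosity, x$surface_tension, x$inverse_capillary_velocity,
              x$n_events))
  invisible(x)
}
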
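#' Simulate FRAP recovery by finite-difference diffusion in a disk
#'
#' Explicit (FTCS) diffusion of the mobile pool on a square grid masked to a
#' disk of radius `domain_radius`, with no-flux (reflecting) walls by default.
#' The initial concentration is uniform at 1; at t = 0 the bleach mask is
#' applied, multiplying both pools by `1 - bleach_depth` inside the mask. The
#' immobile pool (fraction `immobile_fraction` of the initial material) never
#' moves. The masked no-flux stencil conserves total mass to floating-point
#' accuracy in `"closed"` mode; `"exchange"` mode instead holds ghost cells
#' just outside the domain wall at the unbleached exterior concentration, so
#' bleached material is replaced by influx (whole-droplet bleach scenario).
#'
#' The explicit scheme is stable only for `dt <= grid_spacing^2 / (4 D)`;
#' violating the bound is an error, not a warning.
#'
#' @param domain_radius droplet (domain) radius in micrometres.
#' @param D diffusion coefficient of the mobile pool (um^2/s).
#' @param immobile_fraction fraction of material that never exchanges, in
#'   \[0, 1\].
#' @param bleach_mask logical matrix on the simulation grid marking bleached
#'   pixels; defaults to a centred disk of radius `bleach_radius`.
#' @param bleach_radius convenience alternative to `bleach_mask` (um).
#' @param bleach_center centre of the default bleach disk (x, y) in um,
#'   relative to the domain centre.
#' @param bleach_depth fraction of fluorescence removed in the mask, in
#'   \[0, 1\].
#' @param dt time step (s); must satisfy the stability bound.
#' @param n_steps number of diffusion steps.
#' @param grid_spacing grid pitch (um).
#' @param record_every record the field every this many steps.
#' @param mode `"closed"` (reflecting wall, mass conserved) or `"exchange"`.
#' @param seed stored in the ground truth for provenance; the simulation
#'   itself is deterministic.
#' @return A list of class `frap_field_sim`: `times` (s), `fields` (x, y,
#'   frame array of total concentration), `domain` (logical mask),
#'   `bleach_mask`, `grid_spacing`, `mass` (total in-domain mass per recorded
#'   frame) and `ground_truth`.
#' @seealso [recovery_curve()], [fit_radial_diffusion()]
#' @export
simulate_frap_field <- function(domain_radius = 5, D = 0.01,
                                immobile_fraction = 0,
                                bleach_mask = NULL, bleach_radius = 1,
                                bleach_center = c(0, 0), bleach_depth = 1,
                                dt = NULL, n_steps = 200L,
                                grid_spacing = 0.1, record_every = 1L,
                                mode = c("closed", "exchange"), seed = NULL) {
  mode <- match.arg(mode)
  if (!(immobile_fraction >= 0 && immobile_fraction <= 1))
    .stopf("immobile_fraction must be in [0, 1]")
  if (!(bleach_depth >= 0 && bleach_depth <= 1))
    .stopf("bleach_depth must be in [0, 1]")
  h <- grid_spacing
  bound <- h^2 / (4 * D)
  if (is.null(dt)) dt <- 0.9 * bound
  if (dt > bound * (1 + 1e-12))
    .stopf("dt = %.4g s violates the explicit-scheme stability bound dt <= grid_spacing^2/(4 D) = %.4g s",
           dt, bound)
  default_mask <- is.null(bleach_mask)
  half <- ceiling(domain_radius / h)
  n <- 2L * half + 1L
  co <- (seq_len(n) - 1 - half) * h          # grid coordinates, 0 at centre
  r2 <- outer(co^2, co^2, `+`)
  domain <- r2 <= domain_radius^2
  if (is.null(bleach_mask)) {
    b2 <- outer((co - bleach_center[1])^2, (co - bleach_center[2])^2, `+`)
    bleach_mask <- b2 <= bleach_radius^2
  }
  if (!identical(dim(bleach_mask), dim(domain)))
    .stopf("bleach_mask must match the %d x %d simulation grid", n, n)
  if (any(bleach_mask & !domain))
    .stopf("bleach mask extends outside the domain")

  shift <- function(m, dx, dy) {
    out <- matrix(0, n, n)
    xs <- seq_len(n) - dx; ys <- seq_len(n) - dy
    okx <- xs >= 1 & xs <= n; oky <- ys >= 1 & ys <= n
    out[okx, oky] <- m[xs[okx], ys[oky]]
    out
  }
  dom <- domain * 1
  # number of in-domain 4-neighbours of each cell
  deg <- shift(dom, 1, 0) + shift(dom, -1, 0) + shift(dom, 0, 1) + shift(dom, 0, -1)
  alpha <- D * dt / h^2

  mob0 <- 1 - immobile_fraction
  keep <- 1 - bleach_depth * bleach_mask
  mob <- mob0 * keep * domain
  imm <- immobile_fraction * keep * domain

  n_rec <- n_steps %/% record_every + 1L
  fields <- array(0, c(n, n, n_rec))
  times <- numeric(n_rec)
  mass <- numeric(n_rec)
  fields[, , 1L] <- mob + imm
  mass[1L] <- sum(mob + imm)
  rec <- 1L
  for (s in seq_len(n_steps)) {
    nb <- shift(mob, 1, 0) + shift(mob, -1, 0) + shift(mob, 0, 1) + shift(mob, 0, -1)
    if (mode == "closed") {
      mob <- mob + alpha * (nb - deg * mob)
    } else {
      # ghost cells outside the wall held at the unbleached mobile level
      mob <- mob + alpha * (nb + (4 - deg) * mob0 - 4 * mob)
    }
    mob <- mob * domain
    if (s %% record_every == 0L) {
      rec <- rec + 1L
      fields[, , rec] <- mob + imm
      times[rec] <- s * dt
      mass[rec] <- sum(mob + imm)
    }
  }
  gt <- ground_truth("frap_field", list(
    domain_radius_um = domain_radius, D_um2_s = D,
    immobile_fraction = immobile_fraction, bleach_depth = bleach_depth,
    bleach_radius_um = if (default_mask) bleach_radius else NA_real_,
    dt_s = dt, n_steps = n_steps, grid_spacing_um = h, mode = mode),
    if (is.null(seed)) NA_integer_ else seed)
  structure(list(times = times, fields = fields, domain = domain,
                 bleach_mask = bleach_mask, grid_spacing = h, mass = mass,
                 ground_truth = gt),
            class = "frap_field_sim")
}

#' Mean-intensity recovery curve over a region of a simulated FRAP field
#'
#' @param sim a `frap_field_sim` from [simulate_frap_field()].
#' @param mask logical matrix selecting the readout region; defaults to the
#'   simulation's bleach mask.
#' @return A data.frame with columns `time_s` and `intensity` (mean total
#'   concentration over the mask).
#' @export
recovery_curve <- function(sim, mask = NULL) {
  stopifnot(inherits(sim, "frap_field_sim"))
  if (is.null(mask)) mask <- sim$bleach_mask
  v <- apply(sim$fields, 3, function(f) mean(f[mask]))
  data.frame(time_s = sim$times, intensity = v)
}

#' Generate a synthetic single-exponential FRAP trace
#'
#' Prebleach frames sit at 1, the bleach frame at 0, and recovery follows
#' `F_m * (1 - 2^(-t / tau_half))` with Gaussian noise added to every frame.
#'
#' @param tau_half recovery halftime (s), > 0.
#' @param mobile_fraction plateau of the normalized recovery, in \[0, 1\].
#' @param prebleach_frames,total_frames frame counts (bleach occurs at frame
#'   `prebleach_frames + 1`).
#' @param frame_interval s between frames.
#' @param noise_sd Gaussian noise sd on the normalized scale (>= 0).
#' @param bleach_radius bleach-spot radius recorded on the trace (um),
#'   used downstream for apparent diffusion coefficients.
#' @param seed integer seed.
#' @return A [frap_trace] carrying a [ground_truth].
#' @export
gen_frap_trace <- function(tau_half = 27.16, mobile_fraction = 0.62,
                           prebleach_frames = 5L, total_frames = 120L,
                           frame_interval = 2, noise_sd = 0.03,
                           bleach_radius = 0.55, seed = 1L) {
  if (!isTRUE(tau_half > 0)) .stopf("tau_half must be > 0")
  if (!isTRUE(noise_sd >= 0)) .stopf("noise_sd must be >= 0")
  if (!(mobile_fraction >= 0 && mobile_fraction <= 1))
    .stopf("mobile_fraction must be in [0, 1]")
  if (total_frames <= prebleach_frames + 1L)
    .stopf("need frames after the bleach")
  times <- (seq_len(total_frames) - 1) * frame_interval
  bleach_index <- prebleach_frames + 1L
  t_rel <- times - times[bleach_index]
  v <- ifelse(t_rel < 0, 1,
              mobile_fraction * (1 - 2^(-t_rel / tau_half)))
  if (noise_sd > 0)
    v <- .with_seed(seed, v + rnorm(length(v), sd = noise_sd))
  gt <- ground_truth("frap_trace", list(
    tau_half_s = tau_half, mobile_fraction = mobile_fraction,
    prebleach_frames = prebleach_frames, total_frames = total_frames,
    frame_interval_s = frame_interval, noise_sd = noise_sd,
    bleach_radius_um = bleach_radius), seed)
  frap_trace(times, v, prebleach_frames = prebleach_frames,
             bleach_index = bleach_index, roi_radius = bleach_radius,
             normalized = FALSE, ground_truth = gt)
}
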
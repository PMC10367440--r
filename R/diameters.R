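#' Droplet-diameter statistics from the empirical CDF
#'
#' Fits the empirical cumulative distribution of diameters to a normal CDF by
#' least squares; the fitted mean equals the median of the (symmetric) fitted
#' distribution and is reported with standard error `sigma / sqrt(n)`.
#'
#' @param diameters droplet diameters in micrometres (n >= 5).
#' @return An object of class `diameter_stats`: list with `median`, `sem`,
#'   `mu`, `sigma`, `n`.
#' @export
measure_diameter_cdf <- function(diameters) {
  diameters <- as.numeric(diameters)
  n <- length(diameters)
  if (n < 5L) .stopf("need at least 5 diameters, got %d", n)
  if (sd(diameters) == 0) {
    return(structure(list(median = diameters[1], sem = 0, mu = diameters[1],
                          sigma = 0, n = n), class = "diameter_stats"))
  }
  ds <- sort(diameters)
  p <- (seq_len(n) - 0.5) / n             # Hazen plotting positions
  fit <- minpack.lm::nlsLM(p ~ pnorm(ds, mu, sigma),
                           start = list(mu = mean(ds), sigma = sd(ds)),
                           lower = c(-Inf, 1e-12))
  co <- coef(fit)
  structure(list(median = unname(co["mu"]),
                 sem = unname(co["sigma"]) / sqrt(n),
                 mu = unname(co["mu"]), sigma = unname(co["sigma"]), n = n),
            class = "diameter_stats")
}

#' @export
print.diameter_stats <- function(x, ...) {
  cat(sprintf("<diameter_stats> median %.3g +/- %.2g um (n = %d)\n",
              x$median, x$sem, x$n))
  invisible(x)
}

#' Fit the droplet size vs concentration law y = a x^b + c
#'
#' Weighted nonlinear least squares of median diameter on concentration with
#' the shifted power law `y = a * x^b + c` (y um, x uM), multistarted over
#' `b in {0.25, 0.5, 1, 2}` with (a, c) initialized by linear regression at
#' each fixed b; the converged fit with the lowest residual sum of squares
#' wins and is never worse than any initialization. When the fitted offset c
#' is negative the law crosses zero at `x* = (-c/a)^(1/b)` — the critical
#' concentration below which no droplets form; for c >= 0 the critical
#' concentration is reported as `NA` ("none").
#'
#' @param concentrations protein concentrations (uM, > 0).
#' @param medians median diameters (um).
#' @param sems optional standard errors of the medians; weights are `1/sem^2`
#'   when given.
#' @param b_bounds allowed exponent range; a fit driven to a bound is
#'   flagged.
#' @return An object of class `power_law_fit`: list with `a`, `b`, `c`,
#'   `critical_concentration` (uM or NA), `vcov`, `rss`, `init_rss` (RSS at
#'   each multistart initialization), `flag` (`NA`, `"b_at_bound"` or
#'   `"degenerate"`), and `fitted`.
#' @export
fit_shifted_power_law <- function(concentrations, medians, sems = NULL,
                                  b_bounds = c(0.05, 5)) {
  x <- as.numeric(concentrations); y <- as.numeric(medians)
  if (length(x) < 4L) .stopf("need at least 4 points")
  if (any(x <= 0)) .stopf("concentrations must be > 0")
  w <- if (!is.null(sems)) 1 / sems^2 else rep(1, length(x))
  if (sd(y) == 0) {
    return(structure(list(a = 0, b = NA_real_, c = y[1],
                          critical_concentration = NA_real_, vcov = NULL,
                          rss = 0, init_rss = numeric(0), flag = "degenerate",
                          fitted = y),
                     class = "power_law_fit"))
  }
  best <- NULL; init_rss <- c()
  for (b0 in c(0.25, 0.5, 1, 2)) {
    lin <- lm(y ~ I(x^b0), weights = w)
    a0 <- coef(lin)[2]; c0 <- coef(lin)[1]
    init_rss[as.character(b0)] <-
      sum(w * (y - (a0 * x^b0 + c0))^2)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * x^b + c,
                        start = list(a = unname(a0), b = b0, c = unname(c0)),
                        weights = w,
                        lower = c(-Inf, b_bounds[1], -Inf),
                        upper = c(Inf, b_bounds[2], Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    .stopf("shifted power law failed to converge from all starts (best init RSS %.4g)",
           min(init_rss))
  co <- coef(best$fit)
  a <- unname(co["a"]); b <- unname(co["b"]); cc <- unname(co["c"])
  flag <- NA_character_
  if (min(abs(b - b_bounds)) < 1e-6) flag <- "b_at_bound"
  xstar <- if (cc < 0 && a > 0) (-cc / a)^(1 / b) else NA_real_
  structure(list(a = a, b = b, c = cc, critical_concentration = xstar,
                 vcov = vcov(best$fit), rss = best$rss, init_rss = init_rss,
                 flag = flag, fitted = as.numeric(predict(best$fit))),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g x^%.4g + %.4g\n", x$a, x$b, x$c))
  if (!is.na(x$critical_concentration))
    cat(sprintf("  critical concentration x* = %.4g uM\n",
                x$critical_concentration))
  else cat("  critical concentration: none (c >= 0)\n")
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Contact angle of a surface-resting droplet from an X-Z section
#'
#' Segments the X-Z cross-section (largest above-threshold component), fits
#' a circle to the free boundary (excluding the substrate rows) by algebraic
#' least squares, and reports the interior angle between the substrate line
#' and the circle tangent at the contact point:
#' `theta = acos((z0 - zc) / R)` with circle centre height `zc`, radius `R`
#' and substrate plane `z0`. A hemispherical cap gives 90 degrees; wetting
#' droplets less, dewetting droplets more.
#'
#' @param xz_stack an [image_stack] whose second axis is the optical axis,
#'   substrate at index 1 (e.g. from [gen_contact_cap()]); the z calibration
#'   is taken from `z_step`.
#' @param channel,time channel and frame index.
#' @return An object of class `contact_angle`: list with `theta_deg`,
#'   `radius_um`, `center_um`, `residual` (RMS circle-fit residual, um).
#' @export
contact_angle <- function(xz_stack, channel = 1L, time = 1L) {
  stopifnot(inherits(xz_stack, "image_stack"))
  px <- xz_stack$pixel_size; pz <- xz_stack$z_step
  img <- stack_volume(xz_stack, time = time, channel = channel)[, , 1]
  sm <- .gauss_blur3(array(img, c(dim(img), 1L)), 1, 0)[, , 1]
  thr <- .otsu_threshold(sm)
  bin <- sm > thr
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) .stopf("no droplet found in the X-Z image")
  id <- which.max(tabulate(lab[lab > 0]))
  mask <- lab == id
  w <- which(mask, arr.ind = TRUE)
  zmin <- min(w[, 2])
  contact_width <- sum(w[, 2] == zmin)
  if (zmin > 3L || contact_width < 2L)
    .stopf("droplet not wetting / not at surface: no substrate contact detected")
  # free boundary: mask pixels with a background 4-neighbour, above substrate
  er <- EBImage::erode(EBImage::Image(mask * 1),
                       EBImage::makeBrush(3L, "diamond")) > 0
  bnd <- which(mask & !er, arr.ind = TRUE)
  bnd <- bnd[bnd[, 2] > zmin + 1L, , drop = FALSE]
  if (nrow(bnd) < 10L) .stopf("too few free-boundary points for a circle fit")
  bx <- (bnd[, 1] - 1) * px
  bz <- (bnd[, 2] - 1) * pz
  # Kasa algebraic circle fit: x^2 + z^2 + D x + E z + F = 0
  A <- cbind(bx, bz, 1)
  rhs <- -(bx^2 + bz^2)
  sol <- qr.solve(A, rhs)
  xc <- -sol[1] / 2; zc <- -sol[2] / 2
  R <- sqrt(xc^2 + zc^2 - sol[3])
  z0 <- (zmin - 1) * pz
  cosq <- (z0 - zc) / R
  if (abs(cosq) > 1) .stopf("degenerate circle fit (substrate outside circle)")
  theta <- acos(cosq) * 180 / pi
  resid_rms <- sqrt(mean((sqrt((bx - xc)^2 + (bz - zc)^2) - R)^2))
  structure(list(theta_deg = theta, radius_um = R, center_um = c(xc, zc),
                 residual = resid_rms),
            class = "contact_angle")
}

#' @export
print.contact_angle <- function(x, ...) {
  cat(sprintf("<contact_angle> theta = %.1f deg (R = %.3g um, fit RMS %.3g um)\n",
              x$theta_deg, x$radius_um, x$residual))
  invisible(x)
}
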
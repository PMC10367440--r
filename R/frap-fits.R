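# multistart bounded Levenberg-Marquardt helper: returns the converged fit
# with lowest RSS, or NULL
.best_nls <- function(formula, data, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < sum(resid(best)^2)) best <- fit
  }
  best
}

.ci95 <- function(fit, name) {
  se <- tryCatch(sqrt(diag(vcov(fit)))[name], error = function(e) NA_real_)
  unname(coef(fit)[name] + c(-1, 1) * qnorm(0.975) * se)
}

#' Fit a single-exponential FRAP recovery
#'
#' Least-squares fit of `I(t) = F_m * (1 - exp(-t / tau))` to the post-bleach
#' points of a normalized trace (the trace is normalized first if it is not
#' already). Reports the halftime `tau_half = tau * ln 2`, the mobile
#' fraction `F_m` (the plateau of the fitted model, robust to truncated
#' acquisitions), 95% confidence intervals from the covariance, and the
#' apparent diffusion coefficient `r^2 / tau_half` using the trace's
#' bleach-spot radius.
#'
#' The fit is multistarted over three decades of `tau`. A trace that never
#' recovers (flat at zero) is returned as a flagged degenerate fit with
#' `F_m = 0` and `tau = NA` rather than an error.
#'
#' @param trace a [frap_trace].
#' @return An object of class `frap_fit`: list with `tau_half`, `tau`,
#'   `mobile_fraction`, `Dapp`, `bleach_radius`, `ci_tau_half`,
#'   `ci_mobile_fraction`, `residual_sd`, `n_post`, `flag`.
#' @export
fit_single_exponential <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (!trace$normalized) trace <- normalize_trace(trace)
  post <- trace$time >= 0
  t <- trace$time[post]; y <- trace$roi[post]
  if (length(t) < 10L) .stopf("need at least 10 post-bleach points")
  r <- trace$roi_radius
  if (max(y) < 0.02 && sd(y) < 0.02) {    # flat zero: no recovery at all
    return(structure(list(tau_half = NA_real_, tau = NA_real_,
                          mobile_fraction = 0, Dapp = NA_real_,
                          bleach_radius = r,
                          ci_tau_half = c(NA_real_, NA_real_),
                          ci_mobile_fraction = c(NA_real_, NA_real_),
                          residual_sd = sd(y), n_post = length(t),
                          flag = "degenerate"),
                     class = "frap_fit"))
  }
  span <- max(t[t > 0])
  starts <- lapply(span * c(0.02, 0.2, 2), function(tau0)
    list(Fm = min(max(y[y > 0], 0.1), 1.05), tau = tau0))
  fit <- .best_nls(y ~ Fm * (1 - exp(-t / tau)), data.frame(t = t, y = y),
                   starts, lower = c(0, 1e-9), upper = c(1.05, Inf))
  if (is.null(fit))
    .stopf("single-exponential fit failed to converge; residual spread %.3g",
           sd(y))
  co <- coef(fit)
  tau <- unname(co["tau"]); fm <- unname(co["Fm"])
  flag <- NA_character_
  if (fm >= 1.05 - 1e-9 || fm <= 1e-9) flag <- "mobile_fraction_at_bound"
  tau_half <- tau * log(2)
  structure(list(tau_half = tau_half, tau = tau, mobile_fraction = fm,
                 Dapp = apparent_diffusion(tau_half, r),
                 bleach_radius = r,
                 ci_tau_half = .ci95(fit, "tau") * log(2),
                 ci_mobile_fraction = .ci95(fit, "Fm"),
                 residual_sd = sd(resid(fit)), n_post = length(t),
                 flag = flag),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> tau_half = %.4g s, mobile fraction = %.3g, Dapp = %.3g um^2/s\n",
              x$tau_half, x$mobile_fraction, x$Dapp))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Apparent diffusion coefficient from a recovery halftime
#'
#' The operational mobility estimator `Dapp = r^2 / tau_half` with `r` the
#' bleach-spot radius. Deliberately *not* the Soumpasis spot-FRAP expression
#' (`0.224 r^2 / tau_half`): this simple ratio is the convention used for the
#' tabulated condensate values this package reproduces, and is therefore an
#' "apparent" coefficient, comparable within but not across conventions.
#'
#' @param tau_half recovery halftime (s), > 0.
#' @param bleach_radius bleach-spot radius (um), > 0.
#' @return Dapp in um^2/s.
#' @examples
#' apparent_diffusion(27.2, 0.55) * 100   # ~1.11 (in 1e-2 um^2/s units)
#' @export
apparent_diffusion <- function(tau_half, bleach_radius) {
  if (any(tau_half <= 0) || any(bleach_radius <= 0))
    .stopf("tau_half and bleach_radius must be > 0")
  bleach_radius^2 / tau_half
}

#' Estimate the bleach-spot radius from the first post-bleach image
#'
#' Fits the radial intensity depression around the bleach centre with an
#' inverted Gaussian `I(d) = base - depth * exp(-d^2 / (2 sigma^2))` and
#' returns the half width at half depth, `r = sigma * sqrt(2 ln 2)`. The
#' estimate depends only on intensity ratios, so it is invariant to global
#' intensity scaling.
#'
#' @param stack an [image_stack] whose first frame is the first post-bleach
#'   image, or a plain matrix (then `pixel_size` must be given).
#' @param bleach_center (x, y) bleach centre in micrometres.
#' @param pixel_size um per pixel (taken from the stack if omitted).
#' @param z,channel,time plane selection when a stack is given.
#' @return Bleach radius r in micrometres.
#' @export
estimate_bleach_radius <- function(stack, bleach_center, pixel_size = NULL,
                                   z = 1L, channel = 1L, time = 1L) {
  if (inherits(stack, "image_stack")) {
    plane <- stack_plane(stack, z = z, time = time, channel = channel)
    pixel_size <- stack$pixel_size
  } else {
    plane <- stack
    if (is.null(pixel_size)) .stopf("pixel_size required for a plain matrix")
  }
  prof <- radial_profile(plane, bleach_center, pixel_size)
  d <- prof$positions; y <- prof$intensity
  base0 <- max(y); depth0 <- base0 - min(y)
  if (depth0 < 0.02 * base0) .stopf("no bleach depression detected at the given centre")
  fit <- .best_nls(y ~ base - depth * exp(-d^2 / (2 * sigma^2)),
                   data.frame(d = d, y = y),
                   lapply(c(0.25, 0.5, 1), function(f)
                     list(base = base0, depth = depth0,
                          sigma = f * max(d) / 3)),
                   lower = c(0, 0, 1e-6), upper = c(Inf, Inf, Inf))
  if (is.null(fit)) .stopf("no bleach depression detected: Gaussian fit failed")
  co <- coef(fit)
  if (co["depth"] < 0.02 * co["base"])
    .stopf("no bleach depression detected (fitted depth %.3g of base)",
           co["depth"] / co["base"])
  unname(co["sigma"]) * sqrt(2 * log(2))
}

#' Fit a biphasic (double-exponential) FRAP recovery
#'
#' Four-parameter least squares of
#' `I(t) = A (1 - exp(-t/tau1)) + B (1 - exp(-t/tau2))` with `tau1 < tau2`
#' enforced by reordering after the fit, describing two-component recovery
#' such as fast boundary exchange plus slow interior mixing of tubulin in
#' condensates. The plateau of the fitted model is `A + B`. The fit is
#' compared against the nested single-exponential model by AIC
#' (`delta_aic < 0` favours the biphasic model); time constants within a
#' ratio of 0.8, or a vanishing component, are flagged
#' `"effectively monophasic"`.
#'
#' @param trace a [frap_trace] with at least 20 post-bleach points.
#' @return An object of class `biphasic_fit`: list with `A`, `tau1`, `B`,
#'   `tau2`, `plateau`, `ci_tau1`, `ci_tau2`, `delta_aic`, `residual_sd`,
#'   `flag`.
#' @export
fit_biphasic <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (!trace$normalized) trace <- normalize_trace(trace)
  post <- trace$time >= 0
  t <- trace$time[post]; y <- trace$roi[post]
  if (length(t) < 20L) .stopf("need at least 20 post-bleach points")
  span <- max(t)
  starts <- list()
  for (t1 in span * c(0.01, 0.05)) for (t2 in span * c(0.3, 1.5))
    starts[[length(starts) + 1L]] <-
      list(A = max(y) / 2, tau1 = t1, B = max(y) / 2, tau2 = t2)
  fit <- .best_nls(y ~ A * (1 - exp(-t / tau1)) + B * (1 - exp(-t / tau2)),
                   data.frame(t = t, y = y), starts,
                   lower = c(0, 1e-9, 0, 1e-9), upper = c(2, Inf, 2, Inf))
  if (is.null(fit)) .stopf("biphasic fit failed to converge")
  co <- coef(fit)
  ord <- order(c(co["tau1"], co["tau2"]))
  amps <- c(co["A"], co["B"])[ord]
  taus <- c(co["tau1"], co["tau2"])[ord]
  names_tau <- c("tau1", "tau2")[ord]
  flag <- NA_character_
  if (taus[1] / taus[2] > 0.8 || min(amps) < 0.01 * sum(amps))
    flag <- "effectively monophasic"
  single <- .best_nls(y ~ Fm * (1 - exp(-t / tau)), data.frame(t = t, y = y),
                      lapply(span * c(0.02, 0.2, 2),
                             function(tau0) list(Fm = max(y), tau = tau0)),
                      lower = c(0, 1e-9), upper = c(2, Inf))
  delta_aic <- if (!is.null(single)) AIC(fit) - AIC(single) else NA_real_
  structure(list(A = unname(amps[1]), tau1 = unname(taus[1]),
                 B = unname(amps[2]), tau2 = unname(taus[2]),
                 plateau = unname(sum(amps)),
                 ci_tau1 = .ci95(fit, names_tau[1]),
                 ci_tau2 = .ci95(fit, names_tau[2]),
                 delta_aic = delta_aic, residual_sd = sd(resid(fit)),
                 flag = flag),
            class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf("<biphasic_fit> A = %.3g (tau1 = %.4g s), B = %.3g (tau2 = %.4g s)\n",
              x$A, x$tau1, x$B, x$tau2))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Fit condensate aging kinetics of the mobile fraction
#'
#' Exponential decay of the FRAP mobile fraction with droplet maturation
#' time: `F(t) = F_inf + A * exp(-t / tau_age)` with the long-time mobile
#' fraction `F_inf` bounded to \[0, 1\] and amplitude `A >= 0`. The
#' extrapolated initial fraction `F0 = F_inf + A` is reported but not bounded
#' above by 1, because the first observation typically lies well after t = 0
#' and the back-extrapolated intercept exceeds the physical range without
#' affecting the decay constant.
#'
#' @param times_h maturation times in hours (>= 4 points, increasing).
#' @param mobile_fractions mobile fractions in \[0, 1\].
#' @return An object of class `aging_fit`: list with `tau_age` (h), `F_inf`,
#'   `F0`, `ci_tau_age`, `ci_F_inf`, `residual_sd`, `flag`.
#' @examples
#' fit_aging(c(1, 2, 3, 4, 4.5), c(0.62, 0.25, 0.16, 0.14, 0.13))
#' @export
fit_aging <- function(times_h, mobile_fractions) {
  t <- as.numeric(times_h); y <- as.numeric(mobile_fractions)
  if (length(t) < 4L) .stopf("need at least 4 points")
  if (any(diff(t) <= 0)) .stopf("times must be increasing")
  if (any(y < 0 | y > 1)) .stopf("mobile fractions must be in [0, 1]")
  if (sd(y) == 0) {
    return(structure(list(tau_age = NA_real_, F_inf = y[1], F0 = y[1],
                          ci_tau_age = c(NA_real_, NA_real_),
                          ci_F_inf = c(NA_real_, NA_real_),
                          residual_sd = 0, flag = "constant"),
                     class = "aging_fit"))
  }
  if (coef(lm(y ~ t))[2] >= 0) {
    # rising mobile fractions: no aging decay to fit
    return(structure(list(tau_age = NA_real_, F_inf = y[length(y)], F0 = y[1],
                          ci_tau_age = c(NA_real_, NA_real_),
                          ci_F_inf = c(NA_real_, NA_real_),
                          residual_sd = NA_real_, flag = "no decay"),
                     class = "aging_fit"))
  }
  flag <- NA_character_
  fit <- .best_nls(y ~ Finf + A * exp(-t / tau),
                   data.frame(t = t, y = y),
                   lapply(c(0.3, 0.7, 1.5, 3), function(tau0)
                     list(Finf = min(y), A = max(diff(range(y)), 0.1),
                          tau = tau0)),
                   lower = c(0, 0, 1e-9), upper = c(1, Inf, Inf))
  if (is.null(fit)) .stopf("aging fit failed to converge")
  co <- coef(fit)
  structure(list(tau_age = unname(co["tau"]), F_inf = unname(co["Finf"]),
                 F0 = unname(co["Finf"] + co["A"]),
                 ci_tau_age = .ci95(fit, "tau"),
                 ci_F_inf = .ci95(fit, "Finf"),
                 residual_sd = sd(resid(fit)), flag = flag),
            class = "aging_fit")
}

#' @export
print.aging_fit <- function(x, ...) {
  cat(sprintf("<aging_fit> tau_age = %.3g h, F_inf = %.3g (F0 = %.3g)\n",
              x$tau_age, x$F_inf, x$F0))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Internal diffusion coefficient from whole-droplet bleach profiles
#'
#' Models the radial bleach front of a whole-droplet photobleach as an
#' error-function edge `I(r) = lo + (hi - lo) * Phi((r - edge) / sigma)`
#' whose squared width grows diffusively, `sigma^2(t) = sigma0^2 + 2 Din t`.
#' Each radially averaged profile is fitted for its edge width; `Din` then
#' comes from a linear regression of `sigma^2` on time.
#'
#' @param profiles list of radial profiles (as from [radial_profile()]):
#'   each with `positions` (um) and `intensity`.
#' @param times acquisition times of the profiles (s), >= 3.
#' @param droplet_radius droplet radius (um); profile points beyond it are
#'   ignored (outside the droplet there is no bleach front).
#' @return An object of class `radial_diffusion_fit`: list with `Din`
#'   (um^2/s, >= 0), `sigma0` (um), `sigma2` (fitted squared widths),
#'   `times`, `residual_sd`, `flag` (`"non_monotone"` when the widths shrink
#'   beyond tolerance).
#' @export
fit_radial_diffusion <- function(profiles, times, droplet_radius) {
  if (length(profiles) < 3L) .stopf("need profiles at >= 3 time points")
  if (length(profiles) != length(times)) .stopf("one time per profile")
  sig <- vapply(profiles, function(p) {
    sel <- p$positions <= droplet_radius
    d <- p$positions[sel]; y <- p$intensity[sel]
    lo0 <- min(y); hi0 <- max(y)
    edge0 <- d[which.min(abs(y - (lo0 + hi0) / 2))]
    fit <- .best_nls(y ~ lo + (hi - lo) * pnorm((d - edge) / sigma),
                     data.frame(d = d, y = y),
                     lapply(c(0.05, 0.2, 0.5) * droplet_radius, function(s0)
                       list(lo = lo0, hi = hi0, edge = edge0, sigma = s0)),
                     lower = c(-Inf, -Inf, 0, 1e-4),
                     upper = c(Inf, Inf, droplet_radius * 2, Inf))
    if (is.null(fit)) return(NA_real_)
    unname(coef(fit)["sigma"])
  }, numeric(1))
  ok <- !is.na(sig)
  if (sum(ok) < 3L) .stopf("edge fits failed at too many time points")
  s2 <- sig[ok]^2; tt <- times[ok]
  lfit <- lm(s2 ~ tt)
  slope <- unname(coef(lfit)[2])
  flag <- NA_character_
  # non-monotone growth beyond tolerance: any decrease larger than the
  # residual spread of the regression
  tol <- max(2 * sd(resid(lfit)), 1e-12)
  if (any(diff(s2) < -tol)) flag <- "non_monotone"
  din <- max(slope / 2, 0)
  if (slope < 0) flag <- "non_monotone"
  structure(list(Din = din,
                 sigma0 = sqrt(max(unname(coef(lfit)[1]), 0)),
                 sigma2 = s2, times = tt,
                 residual_sd = sd(resid(lfit)), flag = flag),
            class = "radial_diffusion_fit")
}

#' @export
print.radial_diffusion_fit <- function(x, ...) {
  cat(sprintf("<radial_diffusion_fit> Din = %.4g um^2/s (sigma0 = %.3g um)\n",
              x$Din, x$sigma0))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}
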
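test_that("normalize_trace is idempotent and affine-invariant", {
  tr <- gen_frap_trace(seed = 21, noise_sd = 0.02)
  n1 <- normalize_trace(tr)
  n2 <- normalize_trace(n1)
  expect_equal(n2$roi, n1$roi, tolerance = 1e-12)
  expect_equal(n2$time, n1$time)
  # positive affine transform of the raw intensities changes nothing
  tr2 <- frap_trace(tr$time, 37.5 * tr$roi + 211,
                    prebleach_frames = tr$prebleach_frames,
                    bleach_index = tr$bleach_index,
                    roi_radius = tr$roi_radius)
  expect_equal(normalize_trace(tr2)$roi, n1$roi, tolerance = 1e-12)
})

test_that("reference-ROI division removes linear photofade", {
  tt <- seq(0, 238, 2)
  fade <- 1 - 0.1 * tt / max(tt)          # 10% linear fade per acquisition
  recov <- ifelse(tt < 10, 1, 0.62 * (1 - 2^(-(tt - 10) / 27)))
  tr <- frap_trace(tt, 500 * recov * fade, reference = 800 * fade,
                   bleach_index = 6L)
  tn <- normalize_trace(tr)
  pre <- tn$time < 0
  slope <- coef(lm(tn$roi[pre] ~ seq_len(sum(pre))))[2]
  expect_lt(abs(slope), 1e-3)
})

test_that("no bleach is detected on a flat trace", {
  tr <- frap_trace(1:20, rep(5, 20), bleach_index = 6L)
  expect_error(normalize_trace(tr), "no bleach")
})

test_that("bleach frame auto-detection finds the post-drop minimum", {
  tr <- gen_frap_trace(prebleach_frames = 7L, noise_sd = 0, seed = 3)
  auto <- frap_trace(tr$time, tr$roi, roi_radius = 0.55)
  expect_identical(auto$bleach_index, 8L)
})

test_that("single-exponential fit recovers noiseless generating parameters", {
  tr <- gen_frap_trace(tau_half = 27.16, mobile_fraction = 0.62, noise_sd = 0)
  fit <- fit_single_exponential(tr)
  expect_equal(fit$tau_half, 27.16, tolerance = 1e-6)
  expect_equal(fit$mobile_fraction, 0.62, tolerance = 1e-6)
  expect_equal(fit$tau_half, fit$tau * log(2), tolerance = 1e-12)
  expect_equal(fit$Dapp, 0.55^2 / fit$tau_half, tolerance = 1e-12)
})

test_that("flat-zero trace yields a flagged degenerate fit", {
  tt <- seq(0, 100, 2)
  tr <- frap_trace(c(-2, tt), c(1, rep(0, length(tt))), bleach_index = 2L,
                   normalized = TRUE)
  fit <- fit_single_exponential(tr)
  expect_identical(fit$flag, "degenerate")
  expect_identical(fit$mobile_fraction, 0)
  expect_true(is.na(fit$tau_half))
})

test_that("median fitted halftime over noisy replicates is within 5%", {
  fits <- vapply(seq_len(200), function(s)
    fit_single_exponential(gen_frap_trace(tau_half = 27.16,
                                          mobile_fraction = 0.62,
                                          noise_sd = 0.03,
                                          seed = s))$tau_half,
    numeric(1))
  expect_lt(abs(median(fits) / 27.16 - 1), 0.05)
})

test_that("apparent diffusion is r^2 / tau_half in the table's units", {
  expect_equal(apparent_diffusion(1, 1), 1)
  expect_equal(apparent_diffusion(27.2, 0.55) * 100, 1.11, tolerance = 0.005)
  expect_equal(apparent_diffusion(56.3, 0.55) * 100, 0.54, tolerance = 0.01)
  expect_error(apparent_diffusion(-1, 0.55), "> 0")
  # strictly decreasing in tau_half at fixed radius
  taus <- c(27.2, 34.6, 46.1, 48.0, 56.3)
  expect_true(all(diff(apparent_diffusion(taus, 0.55)) < 0))
})

test_that("bleach radius comes back from a synthetic Gaussian depression", {
  px <- 0.05
  n <- 81L
  xs <- (seq_len(n) - 1) * px
  c0 <- max(xs) / 2
  r2 <- outer((xs - c0)^2, (xs - c0)^2, `+`)
  img <- 200 * (1 - 0.8 * exp(-r2 / (2 * 0.467^2)))
  r <- estimate_bleach_radius(img, c(c0, c0), pixel_size = px)
  expect_equal(r, 0.467 * sqrt(2 * log(2)), tolerance = 0.02)
  # invariant to global intensity scaling
  expect_equal(estimate_bleach_radius(3 * img, c(c0, c0), pixel_size = px),
               r, tolerance = 1e-6)
  expect_error(estimate_bleach_radius(matrix(100, n, n), c(c0, c0),
                                      pixel_size = px), "no bleach depression")
})

test_that("biphasic fit recovers two-timescale recovery and its plateau", {
  tr <- biphasic_trace(A = 0.4, tau1 = 5, B = 0.3, tau2 = 300)
  fit <- fit_biphasic(tr)
  expect_equal(fit$A, 0.4, tolerance = 1e-4)
  expect_equal(fit$tau1, 5, tolerance = 1e-4)
  expect_equal(fit$B, 0.3, tolerance = 1e-4)
  expect_equal(fit$tau2, 300, tolerance = 1e-4)
  expect_lt(fit$tau1, fit$tau2)
  expect_equal(fit$plateau, 0.7, tolerance = 1e-4)
  expect_lt(fit$delta_aic, 0)           # biphasic beats single exponential
})

test_that("single-component recovery is flagged effectively monophasic", {
  tr <- biphasic_trace(A = 0.6, tau1 = 30, B = 0, tau2 = 30)
  fit <- fit_biphasic(tr)
  expect_identical(fit$flag, "effectively monophasic")
})

test_that("aging fit reproduces the maturation decay and round-trips", {
  fit <- fit_aging(c(1, 2, 3, 4, 4.5), c(0.62, 0.25, 0.16, 0.14, 0.13))
  expect_equal(fit$tau_age, 0.71, tolerance = 0.01)
  expect_equal(fit$F_inf, 0.13, tolerance = 0.008)
  expect_lt(fit$residual_sd, 0.03)
  expect_lte(fit$F_inf, fit$F0)
  # exact round trip from a synthetic decay
  tt <- c(0.5, 1, 2, 3, 5)
  y <- 0.1 + (0.7 - 0.1) * exp(-tt / 0.5)
  rt <- fit_aging(tt, y)
  expect_equal(rt$tau_age, 0.5, tolerance = 1e-6)
  expect_equal(rt$F_inf, 0.1, tolerance = 1e-6)
  expect_equal(rt$F0, 0.7, tolerance = 1e-6)
  # constant data flagged
  expect_identical(fit_aging(1:4, rep(0.3, 4))$flag, "constant")
  expect_identical(fit_aging(1:5, c(0.1, 0.12, 0.15, 0.2, 0.3))$flag,
                   "no decay")
})

test_that("radial diffusion fit: identical profiles give Din = 0", {
  prof <- list(positions = seq(0.05, 2, 0.05),
               intensity = pnorm(seq(0.05, 2, 0.05), 1, 0.2))
  fit <- fit_radial_diffusion(list(prof, prof, prof), c(0, 10, 20), 2)
  expect_equal(fit$Din, 0, tolerance = 1e-9)
})

test_that("radial diffusion fit recovers D from a whole-droplet bleach", {
  # whole droplet bleached; recovery by influx through the boundary, so the
  # bleach front is an inward-moving error-function edge at the droplet rim
  R <- 2
  sim <- simulate_frap_field(domain_radius = R, D = 0.011, bleach_radius = R,
                             bleach_depth = 1, grid_spacing = 0.05,
                             n_steps = 140, record_every = 20,
                             mode = "exchange")
  n <- dim(sim$fields)[1]
  c0 <- (n - 1) / 2 * sim$grid_spacing
  idx <- 2:8
  profs <- lapply(idx, function(i)
    radial_profile(sim$fields[, , i], c(c0, c0), sim$grid_spacing,
                   max_radius = R))
  fit <- fit_radial_diffusion(profs, sim$times[idx], droplet_radius = R)
  expect_lt(abs(fit$Din / 0.011 - 1), 0.2)
})
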
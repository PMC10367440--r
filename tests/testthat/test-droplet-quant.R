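test_that("uniform background segments to an empty table", {
  s <- gen_droplet_stack(numeric(0), matrix(numeric(0), ncol = 3),
                         dim_px = c(48, 48, 5), seed = 9)
  recs <- segment_droplets(s)
  expect_s3_class(recs, "droplet_records")
  expect_identical(nrow(recs), 0L)
})

test_that("a single synthetic droplet is found with the right geometry", {
  s <- gen_droplet_stack(2, c(4.8, 4.8, 3), dim_px = c(96, 96, 13),
                         pixel_size = 0.1, z_step = 0.5, seed = 2)
  recs <- segment_droplets(s)
  expect_identical(nrow(recs), 1L)
  expect_equal(recs$diameter_um, 4, tolerance = 0.2 / 4)  # within ~1 px
  expect_equal(recs$x_um, 4.8, tolerance = 0.1)
  expect_equal(recs$y_um, 4.8, tolerance = 0.1)
  expect_false(recs$border)
})

test_that("well-separated droplets give one record each, centres correct", {
  s <- gen_droplet_stack(c(1, 1), rbind(c(2.5, 2.5, 2), c(9.5, 9.5, 2)),
                         dim_px = c(120, 120, 9), seed = 13)
  recs <- segment_droplets(s)
  expect_identical(nrow(recs), 2L)
  recs <- recs[order(recs$x_um), ]
  expect_equal(recs$x_um, c(2.5, 9.5), tolerance = 0.1)
  expect_equal(recs$y_um, c(2.5, 9.5), tolerance = 0.1)
})

test_that("segmentation diameters are stable under background shifts", {
  mk <- function(bg) segment_droplets(
    gen_droplet_stack(1.5, c(3.2, 3.2, 2), background_level = bg,
                      dim_px = c(64, 64, 9), seed = 5))$diameter_um
  expect_equal(mk(50), mk(200), tolerance = 0.2 / 3)   # within ~1 px
})

test_that("partition coefficient recovers generating enrichment ratios", {
  p_for <- function(ratio, seed) {
    s <- gen_droplet_stack(1.5, c(3.2, 3.2, 2), partition_ratio = ratio,
                           dim_px = c(64, 64, 9), seed = seed)
    partition_coefficient(s, segment_droplets(s))$p
  }
  ps <- vapply(1:8, function(s) p_for(20.5, s), numeric(1))
  expect_lt(abs(mean(ps) / 20.5 - 1), 0.1)
  pt <- vapply(1:8, function(s) p_for(7.2, s + 50), numeric(1))
  expect_lt(abs(mean(pt) / 7.2 - 1), 0.1)
})

test_that("partition coefficient is scale-invariant and 1 on uniform data", {
  s <- gen_droplet_stack(1.5, c(3.2, 3.2, 2), dim_px = c(64, 64, 9),
                         seed = 31)
  recs <- segment_droplets(s)
  p1 <- partition_coefficient(s, recs)
  s2 <- s; s2$data <- s$data * 7.3
  expect_equal(partition_coefficient(s2, recs)$p, p1$p, tolerance = 1e-12)
  # uniform image measured through the same masks gives p = 1
  s3 <- s; s3$data[] <- 123
  expect_equal(partition_coefficient(s3, recs)$p, 1, tolerance = 1e-12)
})

test_that("shell profile separates rim and core enrichment", {
  s <- gen_droplet_stack(2, c(4.8, 4.8, 3), partition_ratio = 2.1,
                         shell_ratio = 4.8, shell_thickness_um = 0.4,
                         dim_px = c(96, 96, 13), psf_sigma_xy = 0.05,
                         seed = 17)
  recs <- segment_droplets(s)
  prof <- shell_profile(s, recs)
  expect_equal(prof$peak, 4.8, tolerance = 0.1 * 4.8)
  expect_equal(prof$center, 2.1, tolerance = 0.1 * 2.1)
  # an ordinary filled droplet has no rim excess
  s2 <- gen_droplet_stack(2, c(4.8, 4.8, 3), partition_ratio = 5,
                          dim_px = c(96, 96, 13), seed = 18)
  prof2 <- shell_profile(s2, segment_droplets(s2))
  expect_gte(prof2$center / prof2$peak, 0.9)
  # uniform image gives a flat profile at 1
  s3 <- s; s3$data[] <- 50
  prof3 <- shell_profile(s3, recs)
  expect_true(all(abs(prof3$intensity - 1) < 1e-9))
})

test_that("diameter CDF fit matches generating normal parameters", {
  expect_error(measure_diameter_cdf(c(1, 2, 3)), "at least 5")
  st0 <- measure_diameter_cdf(rep(2.5, 8))
  expect_identical(st0$median, 2.5)
  expect_identical(st0$sem, 0)
  d <- withr::with_seed(99, rnorm(10000, 1.04, 0.3))
  st <- measure_diameter_cdf(d)
  expect_equal(st$median, 1.04, tolerance = 0.01)
  # fitted mean tracks the sample mean for symmetric samples
  d2 <- withr::with_seed(7, rnorm(400, 3.08, 0.5))
  st2 <- measure_diameter_cdf(d2)
  expect_lt(abs(st2$mu - mean(d2)), 3 * sd(d2) / sqrt(length(d2)))
})

test_that("generated diameters round-trip through the CDF fit", {
  d <- gen_diameter_samples(10, a = 1.0395, b = 0.5, c = -0.2087,
                            spread_sd = 0.5, n_per_conc = 10000, seed = 12)
  st <- measure_diameter_cdf(d$diameter_um)
  expect_equal(st$median, 3.08, tolerance = 0.02 / 3.08)
})

test_that("shifted power law recovers parameters and critical concentration", {
  x <- c(0.05, 0.1, 0.5, 1, 5, 10, 14)
  y <- 1 * x^0.5 - 0.22
  fit <- fit_shifted_power_law(x, y)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$b, 0.5, tolerance = 1e-6)
  expect_equal(fit$c, -0.22, tolerance = 1e-6)
  expect_equal(fit$critical_concentration, 0.0484, tolerance = 1e-6)
  # solution residual no worse than any multistart initialization
  expect_true(all(fit$rss <= fit$init_rss + 1e-9))
  # constant medians are flagged degenerate
  expect_identical(fit_shifted_power_law(x, rep(2, 7))$flag, "degenerate")
  # positive offset means no critical concentration
  fit2 <- fit_shifted_power_law(x, 0.8 * x^0.4 + 0.1)
  expect_true(is.na(fit2$critical_concentration))
})

test_that("noisy synthetic concentration series localizes x* near 48 nM", {
  x <- c(0.05, 0.1, 0.5, 1, 5, 10, 14)
  xs <- vapply(1:10, function(s) {
    y <- withr::with_seed(s, (1 * x^0.5 - 0.2087) * (1 + rnorm(7, 0, 0.02)))
    fit_shifted_power_law(x, y)$critical_concentration
  }, numeric(1))
  expect_lt(abs(median(xs) - 0.048), 0.010)
})

test_that("median diameter increases with concentration on synthetic series", {
  d <- gen_diameter_samples(c(1, 5, 10, 14), a = 1, b = 0.5, c = -0.22,
                            spread_sd = 0.15, n_per_conc = 300, seed = 6)
  med <- vapply(split(d$diameter_um, d$concentration_uM),
                function(v) measure_diameter_cdf(v)$median, numeric(1))
  expect_true(all(diff(med[order(as.numeric(names(med)))]) > 0))
})

test_that("contact angle recovers wetting, neutral and dewetting caps", {
  for (th in c(50, 90, 130)) {
    cap <- gen_contact_cap(th, seed = th)
    ca <- contact_angle(cap)
    tol <- if (th == 90) 3 else 5
    expect_lt(abs(ca$theta_deg - th), tol)
    expect_true(ca$theta_deg > 0 && ca$theta_deg < 180)
  }
})

test_that("a free-floating droplet is not reported as wetting", {
  # droplet suspended far above the substrate row
  px <- 0.05
  n <- 120L
  xs <- (seq_len(n) - 1) * px
  mask <- outer((xs - 3)^2, (xs - 3)^2, `+`) <= 1
  img <- array(50 * (1 + 9 * mask), c(n, n, 1L))
  s <- image_stack(img, pixel_size = px)
  expect_error(contact_angle(s), "not wetting|substrate")
})

test_that("tubulin ring concentration follows from partitioning", {
  expect_equal(interior_concentration(4.8, 3.75), 18)
  expect_equal(interior_concentration(7.2, 3.75), 27, tolerance = 1e-12)
  expect_error(interior_concentration(-1, 3), "positive")
})
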
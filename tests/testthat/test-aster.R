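test_that("a bare droplet yields zero projections", {
  ast <- gen_aster_image(droplet_diameter = 1.04, n_arms = 0, seed = 5)
  expect_identical(count_projections(ast, aster_droplet(ast))$n, 0L)
})

test_that("printed-median scenarios count exactly", {
  # small droplets carry 2 arms (tactoid), medium 12, large 28
  cases <- list(list(d = 1.04, n = 2), list(d = 2.43, n = 12),
                list(d = 3.08, n = 28))
  for (cs in cases) {
    ast <- gen_aster_image(droplet_diameter = cs$d, n_arms = cs$n,
                           angular_jitter_deg = 3, seed = 40 + cs$n)
    rec <- count_projections(ast, aster_droplet(ast))
    expect_identical(rec$n, as.integer(cs$n))
    expect_length(rec$angles_deg, cs$n)
    expect_true(all(rec$angles_deg >= 0 & rec$angles_deg < 360))
  }
})

test_that("counted angles match the generated arm angles", {
  ast <- gen_aster_image(droplet_diameter = 3.08, n_arms = 8, seed = 12)
  rec <- count_projections(ast, aster_droplet(ast))
  truth <- sort(ast$ground_truth$params$arm_angles_deg)
  expect_identical(rec$n, 8L)
  dd <- abs(rec$angles_deg - truth)
  expect_lt(max(pmin(dd, 360 - dd)), 3)
})

test_that("counting survives image rotation", {
  ast <- gen_aster_image(droplet_diameter = 3.08, n_arms = 9, seed = 23)
  rec <- count_projections(ast, aster_droplet(ast))
  # rotate the image by 90 degrees (transpose + flip of the pixel grid)
  rot <- ast
  d <- dim(ast$data)
  m <- ast$data[, , 1, 1, 1]
  rot$data <- array(t(m)[, rev(seq_len(d[1]))], d)
  dr <- aster_droplet(ast)
  rec_rot <- count_projections(rot, dr)
  expect_lte(abs(rec_rot$n - rec$n), 1)
})

test_that("counting a seeded battery of asters is at least 95% exact", {
  ok <- 0L
  for (s in 1:100) {
    na <- s %% 31
    ast <- gen_aster_image(droplet_diameter = 3.2, n_arms = na,
                           angular_jitter_deg = 3, seed = s)
    n <- count_projections(ast, aster_droplet(ast))$n
    ok <- ok + (n == na)
  }
  expect_gte(ok, 95L)
})

test_that("counted arms never decrease with generated arms, noiselessly", {
  counts <- vapply(c(0, 4, 10, 18, 26), function(na) {
    ast <- gen_aster_image(droplet_diameter = 3.2, n_arms = na,
                           angular_jitter_deg = 0, poisson = FALSE,
                           read_noise_sd = 0, seed = 1)
    count_projections(ast, aster_droplet(ast))$n
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("tiny droplets and escaping annuli raise informative errors", {
  ast <- gen_aster_image(droplet_diameter = 3.08, n_arms = 4, seed = 2)
  dr <- aster_droplet(ast)
  small <- dr; small$diameter_um <- 0.1
  expect_error(count_projections(ast, small), "too small")
  expect_error(count_projections(ast, dr, annulus_factor = 10),
               "exits the image")
  expect_error(count_projections(ast, dr, annulus_factor = 0.9), "> 1")
})

test_that("parabola through the three printed medians is exact", {
  fit <- fit_projection_scaling(c(1.04, 2.43, 3.08), c(2, 12, 28))
  pred <- fit$alpha * c(1.04, 2.43, 3.08)^2 +
    fit$beta * c(1.04, 2.43, 3.08) + fit$delta
  expect_equal(pred, c(2, 12, 28), tolerance = 1e-9)
})

test_that("pure quadratic counts give alpha only", {
  d <- seq(0.5, 4, 0.5)
  fit <- fit_projection_scaling(d, 3 * d^2)
  expect_equal(fit$alpha, 3, tolerance = 1e-9)
  expect_equal(fit$beta, 0, tolerance = 1e-9)
  expect_equal(fit$delta, 0, tolerance = 1e-9)
  expect_error(fit_projection_scaling(c(1, 2), c(1, 2)), "at least 3")
})

test_that("noisy parabola coefficients are recovered within uncertainty", {
  d <- seq(0.8, 3.6, length.out = 20)
  truth <- c(alpha = 3.2, beta = -1, delta = 0.8)
  n <- withr::with_seed(31,
    truth["alpha"] * d^2 + truth["beta"] * d + truth["delta"] + rnorm(20, 0, 1))
  fit <- fit_projection_scaling(d, n)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$alpha - truth["alpha"]), 2 * se["I(d^2)"])
  expect_lt(abs(fit$beta - truth["beta"]), 2 * se["d"])
  expect_lt(abs(fit$delta - truth["delta"]), 2 * se["(Intercept)"])
})
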
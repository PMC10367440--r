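test_that("unstable time steps are rejected with the stability bound", {
  expect_error(simulate_frap_field(D = 0.05, grid_spacing = 0.1, dt = 0.1,
                                   n_steps = 5),
               "stability bound")
})

test_that("bleach masks outside the domain are rejected", {
  expect_error(simulate_frap_field(domain_radius = 2, bleach_radius = 1,
                                   bleach_center = c(1.8, 0), n_steps = 5),
               "outside the domain")
})

test_that("mass is conserved to 1e-9 per step with reflecting walls", {
  sim <- simulate_frap_field(domain_radius = 3, D = 0.02, bleach_radius = 1,
                             immobile_fraction = 0.3, grid_spacing = 0.1,
                             n_steps = 400, record_every = 40)
  drift <- abs(diff(sim$mass)) / sim$mass[1]
  expect_true(all(drift < 1e-9 * 40))    # 40 steps between records
})

test_that("a fully immobile field never recovers", {
  sim <- simulate_frap_field(domain_radius = 2, D = 0.02,
                             immobile_fraction = 1, bleach_radius = 0.8,
                             grid_spacing = 0.1, n_steps = 200,
                             record_every = 50)
  rc <- recovery_curve(sim)
  expect_true(all(abs(rc$intensity - rc$intensity[1]) < 1e-12))
})

test_that("fast diffusion reaches the uniform well-mixed level", {
  sim <- simulate_frap_field(domain_radius = 1.5, D = 0.5, bleach_radius = 0.6,
                             grid_spacing = 0.1, n_steps = 4000,
                             record_every = 4000)
  final <- sim$fields[, , dim(sim$fields)[3]][sim$domain]
  expect_lt(diff(range(final)), 1e-6)
  expect_equal(mean(final) * sum(sim$domain), sim$mass[1], tolerance = 1e-9)
})

test_that("recovery halftime scales inversely with D", {
  ht <- vapply(c(0.02, 0.04), function(D)
    sim_halftime(simulate_frap_field(domain_radius = 3, D = D,
                                     bleach_radius = 1, grid_spacing = 0.1,
                                     n_steps = 3000, record_every = 10)),
    numeric(1))
  expect_lt(abs(ht[1] / ht[2] / 2 - 1), 0.05)
})

test_that("finite-difference field matches a random-walk particle oracle", {
  # independent oracle: 2e5 Brownian particles with rejection at the wall,
  # compared on the 64x64 disk after identical bleach and elapsed time
  h <- 0.1; R <- 3.15; D <- 0.02
  sim <- simulate_frap_field(domain_radius = R, D = D, bleach_radius = 1.2,
                             grid_spacing = h, n_steps = 600,
                             record_every = 600)
  n <- dim(sim$fields)[1]
  t_end <- sim$times[2]
  withr::with_seed(202, {
    npart <- 2e5L
    # start uniform in the disk, thinned inside the bleach spot
    ang <- runif(3 * npart, 0, 2 * pi); rad <- R * sqrt(runif(3 * npart))
    x <- rad * cos(ang); y <- rad * sin(ang)
    keep <- x^2 + y^2 > 1.2^2            # bleach_depth = 1 removes the rest
    x <- x[keep][seq_len(npart)]; y <- y[keep][seq_len(npart)]
    dt <- 0.9 * h^2 / (4 * D)
    nstep <- ceiling(t_end / dt); step_sd <- sqrt(2 * D * (t_end / nstep))
    for (s in seq_len(nstep)) {
      xp <- x + rnorm(npart, sd = step_sd)
      yp <- y + rnorm(npart, sd = step_sd)
      ok <- xp^2 + yp^2 <= R^2           # reflect by rejection
      x[ok] <- xp[ok]; y[ok] <- yp[ok]
    }
    xi <- pmin(pmax(round(x / h + (n + 1) / 2), 1), n)
    yi <- pmin(pmax(round(y / h + (n + 1) / 2), 1), n)
    hist2 <- matrix(tabulate(xi + (yi - 1) * n, n * n), n, n)
  })
  # normalize both to mean concentration 1 over the domain and smooth both
  pde <- sim$fields[, , 2]
  pde <- pde / mean(pde[sim$domain])
  prt <- hist2 / mean(hist2[sim$domain])
  sm <- function(m) condquant:::.gauss_blur3(array(m, c(n, n, 1)), 5, 0)[, , 1]
  pde_s <- sm(pde); prt_s <- sm(prt)
  rng <- diff(range(pde_s[sim$domain]))
  mad_diff <- mean(abs(pde_s[sim$domain] - prt_s[sim$domain]))
  expect_lt(mad_diff / rng, 0.02)
})

test_that("exchange mode refills a whole-droplet bleach from outside", {
  sim <- simulate_frap_field(domain_radius = 2, D = 0.05, bleach_radius = 2,
                             bleach_depth = 1, grid_spacing = 0.1,
                             n_steps = 2000, record_every = 500,
                             mode = "exchange")
  rc <- recovery_curve(sim, mask = sim$domain)
  expect_lt(rc$intensity[1], 0.01)
  expect_gt(rc$intensity[nrow(rc)], 0.5) # influx through the wall
  expect_true(all(diff(rc$intensity) > 0))
})
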
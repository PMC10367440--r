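# shared fixture builders (all synthetic, generated at test time)

# droplet record list built from an aster image's ground truth
aster_droplet <- function(ast) {
  g <- ast$ground_truth$params
  list(x_um = (g$center_px[1] - 1) * g$pixel_size_um,
       y_um = (g$center_px[2] - 1) * g$pixel_size_um,
       diameter_um = g$droplet_diameter_um)
}

# noiseless biphasic trace on the normalized scale
biphasic_trace <- function(A = 0.4, tau1 = 5, B = 0.3, tau2 = 300,
                           dt = 2, t_max = 900) {
  tt <- seq(0, t_max, dt)
  y <- A * (1 - exp(-tt / tau1)) + B * (1 - exp(-tt / tau2))
  frap_trace(c(-dt, tt), c(1, y), bleach_index = 2L)
}

# halftime of a simulated recovery curve (linear interpolation to plateau/2)
sim_halftime <- function(sim) {
  rc <- recovery_curve(sim)
  plateau <- utils::tail(rc$intensity, 1)
  i <- min(which(rc$intensity >= plateau / 2))
  if (i == 1L) return(rc$time_s[1])
  y0 <- rc$intensity[i - 1L]; y1 <- rc$intensity[i]
  rc$time_s[i - 1L] + (plateau / 2 - y0) / (y1 - y0) * diff(rc$time_s[(i - 1L):i])
}
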
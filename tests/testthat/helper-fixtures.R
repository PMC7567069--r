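# shared fixtures and independent oracles, built in code at test time

# Monte-Carlo Rayleigh null: P(resultant length >= R_obs) under uniformity.
# Independent of the analytic approximation under test.
mc_rayleigh_p <- function(n, R_obs, n_resamples = 1e5, seed = 20260922) {
  set.seed(seed)
  th <- matrix(stats::runif(n_resamples * n, 0, 2 * pi), ncol = n)
  R_null <- sqrt(rowMeans(cos(th))^2 + rowMeans(sin(th))^2)
  mean(R_null >= R_obs)
}

# analytic ellipse radius at polar angle theta (semi-axes a along x, b along y)
ellipse_radius <- function(theta_deg, a, b) {
  th <- theta_deg * pi / 180
  a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
}

# rotate a track rigidly (degrees CCW) about the origin, then translate
transform_track <- function(track, angle_deg = 0, shift = c(0, 0)) {
  th <- angle_deg * pi / 180
  x <- track$x * cos(th) - track$y * sin(th) + shift[1]
  y <- track$x * sin(th) + track$y * cos(th) + shift[2]
  cil_track(track$frame, x, y, track_id = attr(track, "track_id"),
            dt = attr(track, "dt"))
}

# rotate an image matrix 90 degrees counterclockwise in the y-up scene frame
rotate_ccw90 <- function(m) t(m)[, ncol(m):1]

# a batch of scripted collision events with distinct seeds
scripted_events <- function(n = 40, mode = "cil", mean_deg = 180, sd_deg = 30,
                            seed0 = 100, speed_ratio = 1) {
  lapply(seq_len(n), function(i) {
    simulate_collision_pair(
      collision_script(mode, mean_deg, sd_deg, speed_ratio = speed_ratio,
                       contact_frame = 40),
      walk_params(rot_diffusion = 0, n_steps = 80),
      seed = seed0 + i)$event
  })
}
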
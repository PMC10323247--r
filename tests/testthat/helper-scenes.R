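# shared fixture builders (all synthetic, generated at test time)

# noiseless pixel-integrated Gaussian frame, independent of render_stack
# (used as an oracle for detection tests)
oracle_gaussian_frame <- function(H, W, x0, y0, sigma, volume, offset = 0) {
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  fx <- pnorm(xs + 0.5, x0, sigma) - pnorm(xs - 0.5, x0, sigma)
  fy <- pnorm(ys + 0.5, y0, sigma) - pnorm(ys - 0.5, y0, sigma)
  offset + volume * outer(fy, fx)
}

# 1D Brownian positions (um), plain cumulative-sum oracle
brownian_1d <- function(n_steps, D, dt, s0 = 0) {
  s0 + c(0, cumsum(rnorm(n_steps, 0, sqrt(2 * D * dt))))
}

# wrap a numeric arclength series as a projected_track
as_projected <- function(s_um, frame = seq_along(s_um)) {
  structure(list(track_id = 1L, frame = frame, s_um = s_um,
                 residual_um = rep(0, length(s_um))),
            class = "projected_track")
}

# brute-force exact two-sided Mann-Whitney p-value by enumeration,
# independent of the package implementation
oracle_mw_exact <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- combn(n, na)
  Us <- apply(combos, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

# small stack with one static emitter per frame at (x0, y0)
single_spot_stack <- function(n_frames = 20, x0 = 12.4, y0 = 16.2,
                              seed = 1, snr_boost = 1, noise = TRUE) {
  cfg <- scene_config(image_size = c(32L, 32L), n_frames = n_frames,
                      static_fraction = 1, bleach_rate = 0,
                      unit_intensity = 300 * snr_boost, seed = seed)
  path <- straight_path(c(x0 - 5, y0), c(x0 + 5, y0),
                        pixel_size = cfg$pixel_size)
  truth <- simulate_tracks(cfg, path, n_particles = 1)
  # pin the particle exactly at (x0, y0)
  truth$positions$x_px[] <- x0
  truth$positions$y_px[] <- y0
  list(cfg = cfg, truth = truth,
       stack = render_stack(truth, cfg, noise = noise))
}
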
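test_that("projection onto a straight horizontal path is the x coordinate", {
  px <- 0.107
  path <- straight_path(c(0, 10), c(100, 10), pixel_size = px)
  track <- data.frame(track_id = 1, frame = 1:5,
                      x = c(3, 10, 25, 40, 80), y = rep(10, 5))
  p1 <- project_onto_path(track, path)
  expect_equal(p1$s_um, track$x * px, tolerance = 1e-9)
  expect_equal(p1$residual_um, rep(0, 5), tolerance = 1e-9)

  track2 <- track; track2$y <- track$y + 2
  p2 <- project_onto_path(track2, path)
  expect_equal(p2$s_um, p1$s_um, tolerance = 1e-9)
  expect_equal(abs(p2$residual_um), rep(2 * px, 5), tolerance = 1e-9)
})

test_that("arclengths on a semicircular path equal r * theta", {
  px <- 0.1; r <- 40
  theta_path <- seq(0, pi, length.out = ceiling(pi * r) + 1)  # ~1 px sampling
  pts <- cbind(x = 50 + r * cos(theta_path), y = 10 + r * sin(theta_path))
  path <- microtubule_path(pts, pixel_size = px)
  theta_i <- c(0.3, 0.9, 1.7, 2.6)
  track <- data.frame(track_id = 1, frame = seq_along(theta_i),
                      x = 50 + r * cos(theta_i), y = 10 + r * sin(theta_i))
  p1 <- project_onto_path(track, path)
  expect_equal(p1$s_um, r * theta_i * px, tolerance = 0.01)
})

test_that("principal-axis projection is an isometry for straight tracks", {
  set.seed(61)
  px <- 0.107
  theta <- 0.4                                  # oblique line in the image
  s_true <- cumsum(runif(50, 0.2, 2))
  track <- data.frame(track_id = 1, frame = 1:50,
                      x = 5 + s_true * cos(theta), y = 3 + s_true * sin(theta))
  p1 <- project_onto_path(track, pixel_size = px)
  d_proj <- outer(p1$s_um, p1$s_um, "-")
  d_true <- outer(s_true, s_true, "-") * px
  expect_lt(max(abs(abs(d_proj) - abs(d_true))), 1e-9)
})

test_that("CVE is exact on degenerate and long clean tracks", {
  # constant positions
  est0 <- cve_diffusion(as_projected(rep(1.5, 30)), dt = 0.113)
  expect_equal(est0$D_hat, 0)
  expect_equal(est0$sigma2_loc_hat, 0)

  # long pure Brownian track, no noise
  set.seed(62)
  D <- 0.05; dt <- 0.113
  s <- brownian_1d(5e5, D, dt)
  est <- cve_diffusion(as_projected(s), dt = dt, R = 0)
  expect_equal(est$D_hat, D, tolerance = 0.01)
})

test_that("noise-only closed form: mean D -> 0 and sigma2 recovered", {
  set.seed(63)
  sigma_loc <- 0.02; dt <- 0.113; n_tracks <- 1000; n_pos <- 101
  D_hats <- s2_hats <- numeric(n_tracks)
  for (i in seq_len(n_tracks)) {
    s <- rnorm(n_pos, 0, sigma_loc)            # static + i.i.d. noise
    est <- cve_diffusion(as_projected(s), dt = dt, R = 0)
    D_hats[i] <- est$D_hat
    s2_hats[i] <- est$sigma2_loc_hat
  }
  se <- sd(D_hats) / sqrt(n_tracks)
  expect_lt(abs(mean(D_hats)), 2 * se)
  expect_equal(mean(s2_hats), sigma_loc^2, tolerance = 0.05)
})

test_that("localization variance is recovered within 10% on long tracks", {
  set.seed(64)
  D <- 0.04; dt <- 0.113; sigma_loc <- 0.02
  s <- brownian_1d(500, D, dt) + rnorm(501, 0, sigma_loc)
  ests <- replicate(200, {
    s <- brownian_1d(500, D, dt) + rnorm(501, 0, sigma_loc)
    cve_diffusion(as_projected(s), dt = dt)$sigma2_loc_hat
  })
  expect_equal(mean(ests), sigma_loc^2, tolerance = 0.10)
})

test_that("CVE and MSD estimators agree on clean long tracks", {
  set.seed(65)
  D <- 0.06; dt <- 0.113
  s <- brownian_1d(1e4, D, dt)
  p <- as_projected(s)
  D_cve <- cve_diffusion(p, dt)$D_hat
  D_msd <- msd_diffusion(p, dt, max_lag = 10)$D_hat
  expect_lt(abs(D_cve - D_msd) / D, 0.05)
})

test_that("MSD flags ballistic motion and returns 0 for static tracks", {
  v <- 0.05; dt <- 0.113
  s <- v * (0:500) * dt
  m <- msd_diffusion(as_projected(s), dt, max_lag = 20)
  expect_true(m$nonlinear)
  m0 <- msd_diffusion(as_projected(rep(2, 100)), dt, max_lag = 10)
  expect_equal(m0$D_hat, 0)
  expect_error(msd_diffusion(as_projected(c(1, 2, NA)[1:2]), dt, max_lag = 5),
               "shorter")
})

test_that("gap-spanning displacements are excluded from the moments", {
  set.seed(66)
  dt <- 0.113
  s <- brownian_1d(200, 0.05, dt)
  frames <- seq_along(s)
  # remove a block: estimator must ignore the jump across the gap
  keep <- !(frames %in% 100:110)
  p_gap <- structure(list(track_id = 1L, frame = frames[keep],
                          s_um = s[keep], residual_um = rep(0, sum(keep))),
                     class = "projected_track")
  est_gap <- cve_diffusion(p_gap, dt)
  expect_equal(est_gap$n_steps, sum(diff(frames[keep]) == 1))
  expect_lt(abs(est_gap$D_hat - 0.05) / 0.05, 0.5)  # no gap-induced blow-up
})

test_that("short tracks are flagged rather than estimated", {
  est <- cve_diffusion(as_projected(c(0, 0.1, 0.2)), dt = 0.113,
                       min_steps = 10)
  expect_true(est$too_short)
  expect_true(is.na(est$D_hat))
})

test_that("motility classification is calibrated on static tracks", {
  set.seed(67)
  dt <- 0.113; sigma_loc <- 0.02
  miscalls <- replicate(500, {
    s <- rnorm(101, 0, sigma_loc)
    est <- cve_diffusion(as_projected(s), dt = dt)
    est <- classify_motility(est, alpha = 0.05)
    est$motility_class == "diffusive"
  })
  expect_lte(mean(miscalls), 0.08)             # ~alpha with sampling slack

  est0 <- cve_diffusion(as_projected(rep(1, 50)), dt = dt)
  expect_equal(classify_motility(est0)$motility_class, "static")
})

test_that("classification has power against genuine diffusion", {
  set.seed(68)
  dt <- 0.113; sigma_loc <- 0.02; D <- 0.06
  calls <- replicate(300, {
    s <- brownian_1d(100, D, dt) + rnorm(101, 0, sigma_loc)
    est <- cve_diffusion(as_projected(s), dt = dt)
    classify_motility(est, alpha = 0.05)$motility_class == "diffusive"
  })
  expect_gt(mean(calls), 0.95)
})

test_that("ensemble medians recover D across the measured regime", {
  set.seed(69)
  dt <- 0.113; sigma_loc <- 0.02
  for (D in c(0.011, 0.04, 0.06)) {
    meds <- vapply(1:200, function(i) {
      s <- brownian_1d(100, D, dt) + rnorm(101, 0, sigma_loc)
      cve_diffusion(as_projected(s), dt = dt)$D_hat
    }, numeric(1))
    expect_equal(median(meds), D, tolerance = 0.15)
  }
})
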
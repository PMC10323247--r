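test_that("uniform images have zero background-corrected intensity", {
  cfg <- scene_config(image_size = c(32L, 64L), n_frames = 2, seed = 1)
  st <- image_stack(array(537.2, dim = c(32, 64, 2)), "complex",
                    cfg$pixel_size, cfg$dt)
  mask <- matrix(FALSE, 32, 64); mask[14:18, 10:50] <- TRUE
  bm <- background_corrected_intensity(st, mask)
  expect_equal(bm$mean_bc_intensity, 0, tolerance = 1e-12)
})

test_that("measurement is invariant to a constant offset", {
  set.seed(71)
  frames <- array(rpois(32 * 64 * 2, 50), dim = c(32, 64, 2))
  st <- image_stack(frames, "complex", 0.107, 0.113)
  st2 <- image_stack(frames + 123.4, "complex", 0.107, 0.113)
  mask <- matrix(FALSE, 32, 64); mask[14:18, 10:50] <- TRUE
  b1 <- background_corrected_intensity(st, mask)
  b2 <- background_corrected_intensity(st2, mask)
  expect_equal(b1$mean_bc_intensity, b2$mean_bc_intensity, tolerance = 1e-9)
})

test_that("measured intensity is linear in decoration density", {
  densities <- c(0.1, 0.3, 1, 3)                # fluorophores per um
  cfg <- scene_config(image_size = c(48L, 192L), n_frames = 3,
                      static_fraction = 1, bleach_rate = 0, seed = 72)
  path <- straight_path(c(6, 24), c(185, 24), pixel_size = cfg$pixel_size)
  mean_i <- vapply(seq_along(densities), function(k) {
    cfg_k <- cfg; cfg_k$seed <- 72 + k
    n <- round(densities[k] * path$length_um)
    truth <- simulate_tracks(cfg_k, path, n_particles = n)
    cx <- render_stack(truth, cfg_k)
    mt <- render_stack(truth, cfg_k, channel = "microtubule")
    mt_paths <- segment_microtubules(mt)
    background_corrected_intensity(cx, mt_paths[[1]]$mask)$mean_bc_intensity
  }, numeric(1))
  fit <- lm(mean_i ~ densities)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_gt(coef(fit)[2], 0)
})

test_that("empty or overlapping masks are rejected", {
  st <- image_stack(array(1, dim = c(16, 16, 1)), "complex", 0.107, 0.113)
  expect_error(background_corrected_intensity(st, matrix(FALSE, 16, 16)),
               "empty")
  mask <- matrix(FALSE, 16, 16); mask[4:8, 4:8] <- TRUE
  expect_error(background_corrected_intensity(st, mask, bg_mask = mask),
               "disjoint")
  expect_error(background_corrected_intensity(st, matrix(TRUE, 16, 16)),
               "background")
})

test_that("track mean intensity respects the first-frames window", {
  tr <- data.frame(frame = 1:50, integrated_intensity = rep(7.5, 50))
  expect_equal(track_mean_intensity(tr), 7.5)
  tr2 <- data.frame(frame = 1:50,
                    integrated_intensity = c(rep(10, 20), rep(0, 30)))
  expect_equal(track_mean_intensity(tr2), 10)
  tr3 <- data.frame(frame = 1:20, integrated_intensity = seq(20, 1))
  expect_equal(track_mean_intensity(tr3), 10.5)
  # shorter than the window: plain mean
  tr4 <- data.frame(frame = 1:5, integrated_intensity = 1:5)
  expect_equal(track_mean_intensity(tr4), 3)
})

test_that("step detection finds single noiseless bleach steps", {
  tr <- c(rep(100, 40), rep(0, 40))
  st <- detect_bleach_steps(tr)
  expect_equal(st$n_steps, 1)
  expect_equal(st$change_points, 40)
  expect_equal(st$levels, c(100, 0))
})

test_that("unit intensity calibration is exact on noiseless traces", {
  traces <- lapply(1:25, function(i) c(rep(100, 20 + i), rep(0, 40)))
  cal <- calibrate_unit_intensity(traces)
  expect_equal(cal$unit_intensity, 100)
  expect_equal(cal$n_accepted, 25)
  expect_false(cal$low_confidence)
})

test_that("calibration recovers the unit within 3% under 10% noise", {
  cfg <- scene_config(n_frames = 120, bleach_rate = 0.1, unit_intensity = 200,
                      seed = 73)
  set.seed(73)
  traces <- lapply(1:1000, function(i)
    simulate_photobleach_trace(1, cfg, noise_sd = 20, seed = 73000 + i))
  cal <- suppressWarnings(calibrate_unit_intensity(traces))
  expect_gt(cal$n_accepted, 100)
  expect_equal(cal$unit_intensity, 200, tolerance = 0.03)
})

test_that("two-step oligomer traces are rejected, keeping the unit unbiased", {
  cfg <- scene_config(n_frames = 120, bleach_rate = 0.1, unit_intensity = 200,
                      seed = 74)
  set.seed(74)
  traces <- c(lapply(1:150, function(i)
                simulate_photobleach_trace(1, cfg, noise_sd = 15,
                                           seed = 500 + i)),
              lapply(1:150, function(i)
                simulate_photobleach_trace(2, cfg, noise_sd = 15,
                                           seed = 9000 + i)))
  cal <- suppressWarnings(calibrate_unit_intensity(traces))
  # monomers dominate the accepted set; dimer plateaus (400) excluded
  expect_equal(cal$unit_intensity, 200, tolerance = 0.05)
})

test_that("molecule counting divides by the unit and rounds sensibly", {
  oc <- count_molecules(c(200, 410, 95), unit_intensity = 200)
  expect_equal(oc$n_molecules, c(1, 2.05, 0.475))
  expect_equal(oc$n_molecules_rounded, c(1L, 2L, 1L))
  expect_error(count_molecules(100, 0), "unit_intensity")
})

test_that("pure 7-mers are counted as 7 from pre-bleach intensities", {
  cfg <- scene_config(n_frames = 40, bleach_rate = 0.05, unit_intensity = 200,
                      seed = 75)
  set.seed(75)
  mean_first20 <- vapply(1:500, function(i) {
    tr <- simulate_photobleach_trace(7, cfg, noise_sd = 30, seed = 40000 + i)
    mean(tr[1:20])
  }, numeric(1))
  oc <- count_molecules(mean_first20, unit_intensity = 200)
  expect_equal(median(oc$n_molecules_rounded), 7)
})

test_that("an oligomer size mixture is recovered with small TV distance", {
  sizes <- 1:10
  probs <- c(0.30, 0.22, 0.15, 0.10, 0.08, 0.05, 0.04, 0.03, 0.02, 0.01)
  cfg <- scene_config(n_frames = 40, bleach_rate = 0.02, unit_intensity = 200,
                      seed = 76, oligomer_size_distribution = probs)
  set.seed(76)
  true_sizes <- sample(sizes, 500, replace = TRUE, prob = probs)
  counts <- vapply(seq_along(true_sizes), function(i) {
    tr <- simulate_photobleach_trace(true_sizes[i], cfg, noise_sd = 20,
                                     seed = 60000 + i)
    mean(tr[1:20])
  }, numeric(1))
  oc <- count_molecules(counts, unit_intensity = 200)
  emp <- tabulate(pmin(oc$n_molecules_rounded, 10), nbins = 10) / 500
  tv <- 0.5 * sum(abs(emp - probs))
  expect_lt(tv, 0.1)
})

test_that("larger oligomers diffuse more slowly in joint simulations", {
  set.seed(77)
  dt <- 0.113; unit <- 200
  n_tracks <- 300
  sizes <- sample(1:8, n_tracks, replace = TRUE)
  D_of_size <- function(k) 0.08 / k             # friction grows with size
  rec_size <- rec_D <- numeric(n_tracks)
  for (i in seq_len(n_tracks)) {
    s <- brownian_1d(100, D_of_size(sizes[i]), dt) + rnorm(101, 0, 0.02)
    rec_D[i] <- cve_diffusion(as_projected(s), dt)$D_hat
    rec_size[i] <- max(1, round(rnorm(1, sizes[i], 0.3)))  # noisy size call
  }
  ct <- suppressWarnings(cor.test(rec_size, rec_D, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
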
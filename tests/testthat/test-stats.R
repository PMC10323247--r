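test_that("Mann-Whitney handles degenerate and textbook cases", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mann_whitney_u(rep(5, 4), rep(5, 6))$p, 1)

  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")
})

test_that("Mann-Whitney agrees with the base-R reference", {
  set.seed(81)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), 0.5)
    res <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = (res$method == "exact"),
                       correct = TRUE)
    expect_equal(res$U, unname(ref$statistic))
    expect_equal(res$p, ref$p.value, tolerance = 0.02)
  }
})

test_that("reported p stays within 0.02 of exact enumeration at small n", {
  # in this regime the implementation reports the exact enumeration p, so
  # the comparison against the independent oracle pins the whole path down
  set.seed(82)
  worst <- 0
  for (i in 1:1000) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- rnorm(na); b <- rnorm(nb, runif(1, -1, 1))
    p_exact <- oracle_mw_exact(a, b)
    res <- mann_whitney_u(a, b)
    expect_equal(res$method, "exact")
    worst <- max(worst, abs(res$p - p_exact))
  }
  expect_lt(worst, 0.02)
})

test_that("normal approximation is adequate where the package uses it", {
  # the approximate path only ever runs for pooled n > 16 (or with ties);
  # deviations there are well below the small-sample worst case
  set.seed(86)
  devs <- replicate(300, {
    na <- sample(8:10, 1); nb <- 17 - na + sample(0:4, 1)
    a <- rnorm(na); b <- rnorm(nb, runif(1, -1, 1))
    abs(mann_whitney_u(a, b, exact_max = 0L)$p - oracle_mw_exact(a, b))
  })
  expect_lt(quantile(devs, 0.9), 0.02)
  expect_lt(max(devs), 0.05)
})

test_that("U statistic is antisymmetric and p symmetric under swapping", {
  set.seed(83)
  for (i in 1:25) {
    a <- rnorm(sample(4:12, 1)); b <- rnorm(sample(4:12, 1), 0.3)
    r1 <- mann_whitney_u(a, b); r2 <- mann_whitney_u(b, a)
    expect_identical(r1$U, length(a) * length(b) - r2$U)
    expect_identical(r1$p, r2$p)
  }
})

test_that("median CI uses binomial order statistics with stated coverage", {
  x <- 1:101
  res <- median_ci(x)
  expect_equal(res$median, 51)
  # oracle: largest l with two-sided Binomial(101, 1/2) coverage >= 0.95
  l <- qbinom(0.025, 101, 0.5)
  while (l >= 1 && (1 - 2 * pbinom(l - 1, 101, 0.5)) < 0.95) l <- l - 1
  expect_equal(res$ci_low, sort(x)[l])
  expect_equal(res$ci_high, sort(x)[101 + 1 - l])
  expect_gte(res$coverage, 0.95)

  const <- median_ci(rep(3.3, 20))
  expect_equal(const$ci_low, 3.3)
  expect_equal(const$ci_high, 3.3)
})

test_that("median CI covers the true median at nominal rate", {
  set.seed(84)
  n_rep <- 10000
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rexp(25)                               # true median log(2)
    ci <- median_ci(x)
    covered[i] <- ci$ci_low <= log(2) && log(2) <= ci$ci_high
  }
  expect_gte(mean(covered), 0.94)
})

test_that("bootstrap slope is exact on collinear data", {
  d <- expand.grid(replicate = c("R1", "R2", "R3"),
                   concentration = c(0, 25, 50, 100))
  d$response <- 2 * d$concentration + 1
  bs <- bootstrap_slope(d, n_boot = 200, seed = 5)
  expect_equal(bs$slope_median, 2, tolerance = 1e-12)
  expect_equal(bs$ci_low, 2, tolerance = 1e-12)
  expect_equal(bs$ci_high, 2, tolerance = 1e-12)
})

test_that("single replicate, single point per dose returns the OLS slope", {
  d <- data.frame(replicate = "R1", concentration = c(1, 2, 3, 4),
                  response = c(2.0, 3.1, 3.9, 5.2))
  bs <- bootstrap_slope(d, n_boot = 50, seed = 2)
  ols <- unname(coef(lm(response ~ concentration, d))[2])
  expect_equal(bs$slope_median, ols, tolerance = 1e-12)
  expect_equal(bs$ci_high - bs$ci_low, 0, tolerance = 1e-12)
})

test_that("bootstrap slope is reproducible and defaults to 1000 iterations", {
  d <- expand.grid(replicate = c("R1", "R2", "R3"),
                   concentration = c(0, 25, 50, 100),
                   point = 1:5)
  set.seed(85)
  d$response <- 0.5 * d$concentration + rnorm(nrow(d), 0, 10)
  b1 <- bootstrap_slope(d, seed = 9)
  b2 <- bootstrap_slope(d, seed = 9)
  expect_identical(b1$slopes, b2$slopes)
  expect_equal(b1$n_boot, 1000)
  expect_length(b1$slopes, 1000)
  expect_true(b1$ci_low <= b1$slope_median && b1$slope_median <= b1$ci_high)
  # slope close to truth on this well-powered design
  expect_equal(b1$slope_median, 0.5, tolerance = 0.1)
})

test_that("quadratic isotherm fit recovers Kd from noiseless curves", {
  A <- 5; Kd <- 10
  L <- 10^seq(log10(0.131), log10(4300), length.out = 16)
  f <- ((A + L + Kd) - sqrt((A + L + Kd)^2 - 4 * A * L)) / (2 * A)
  y <- 0.2 + (1.7 - 0.2) * f
  curve <- titration_curve(L, y, fixed_partner_conc = A)
  fit <- fit_kd_quadratic(curve)
  expect_true(fit$converged)
  expect_false(fit$uninformative)
  expect_equal(fit$Kd, Kd, tolerance = 0.001)
  expect_equal(fit$r_free, 0.2, tolerance = 1e-4)
  expect_equal(fit$r_bound, 1.7, tolerance = 1e-4)
})

test_that("saturated titrations are flagged uninformative", {
  A <- 0.01; Kd <- 0.01
  L <- 10^seq(2, 6, length.out = 8)             # L >> A and L >> Kd
  f <- L / (L + Kd)
  y <- 1 + 0.5 * f
  curve <- titration_curve(L, y, fixed_partner_conc = A)
  fit <- fit_kd_quadratic(curve)
  expect_true(fit$uninformative)
})

test_that("weak-binding limit reduces to the linear regime slope", {
  A <- 5; Kd <- 1e5
  L <- 10^seq(log10(0.131), log10(4300), length.out = 16)
  r_free <- 0.1; r_bound <- 2.1
  f <- ((A + L + Kd) - sqrt((A + L + Kd)^2 - 4 * A * L)) / (2 * A)
  y <- r_free + (r_bound - r_free) * f
  lin_slope <- unname(coef(lm(y ~ L))[2])
  expect_equal(lin_slope, (r_bound - r_free) / Kd, tolerance = 0.01)
})

test_that("depletion-free limit matches the hyperbolic isotherm", {
  Kd <- 50; A <- Kd / 100
  L <- 10^seq(-1, 4, length.out = 12)
  f_quad <- ((A + L + Kd) - sqrt((A + L + Kd)^2 - 4 * A * L)) / (2 * A)
  f_hyp <- L / (L + Kd)
  expect_equal(f_quad, f_hyp, tolerance = 0.01)
  # and the two fitting models agree on such data
  y <- 0.3 + 1.2 * f_hyp
  curve <- titration_curve(L, y, fixed_partner_conc = A)
  kq <- fit_kd_quadratic(curve)$Kd
  kh <- fit_kd_quadratic(curve, model = "hyperbolic")$Kd
  expect_equal(kq, kh, tolerance = 0.01)
})

test_that("titration curve validation enforces design range", {
  expect_error(titration_curve(c(1, 2, 3), c(1, 2, 3), 5), ">= 6")
  expect_error(titration_curve(seq(10, 20, length.out = 8), rnorm(8), 5),
               "decades")
})
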
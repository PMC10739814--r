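test_that("kinematic angle reproduces hand-evaluated cases and flags forbidden ones", {
  # cos(theta) = 1 - 511 (1/328 - 1/478) = 0.511111
  expect_equal(kinematic_angle(150, 328), 0.5111108, tolerance = 1e-6)
  expect_equal(kinematic_theta(150, 328), 59.26215, tolerance = 1e-4)
  # forward limit: vanishing energy transfer
  expect_equal(kinematic_angle(1e-9, 478), 1, tolerance = 1e-6)
  # kinematically forbidden pair gives a flag, not a clamped value
  expect_true(is.na(kinematic_angle(350, 128)))
  expect_error(kinematic_angle(-1, 100), "positive")
  expect_error(kinematic_angle(100, 0), "positive")
})

test_that("scattered energy matches the Compton formula and its limits", {
  expect_equal(scattered_energy(478, 90), 246.9747, tolerance = 1e-4)
  expect_equal(scattered_energy(478, 0), 478)
  # backscatter electron energy equals the Compton edge 2E^2/(511 + 2E)
  expect_equal(478 - scattered_energy(478, 180), 2 * 478^2 / (511 + 2 * 478),
               tolerance = 1e-9)
  expect_error(scattered_energy(478, 181), "0, 180")
})

test_that("kinematic_angle and scattered_energy are mutually inverse", {
  for (E0 in c(60, 150, 478, 662, 1500, 2400)) {
    theta <- seq(2, 178, by = 8)
    Ep <- scattered_energy(E0, theta)
    ct <- kinematic_angle(E0 - Ep, Ep)
    expect_equal(ct, cos(theta * pi / 180), tolerance = 1e-9)
  }
})

test_that("Klein-Nishina sampling matches the quadrature oracle (KS test)", {
  E0 <- 478
  # oracle: CDF of theta with density sin(theta) * KN weight, by quadrature
  kn <- function(th) {
    p <- 1 / (1 + (E0 / 511) * (1 - cos(th)))
    p^2 * (p + 1 / p - sin(th)^2) / 2
  }
  th_grid <- seq(0, pi, length.out = 4001)
  dens <- sin(th_grid) * kn(th_grid)
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  set.seed(7)
  n <- 1e5
  draws <- sort(sample_kn_angle(E0, n) * pi / 180)
  F_at <- approx(th_grid, cdf, xout = draws, rule = 2)$y
  ks <- max(abs(F_at - seq_len(n) / n), abs(F_at - (seq_len(n) - 1) / n))
  # critical value at alpha = 0.001
  expect_lt(ks, sqrt(-0.5 * log(0.0005)) / sqrt(n))
})

test_that("Klein-Nishina sampling is seeded-deterministic", {
  set.seed(11); a <- sample_kn_angle(662, 100)
  set.seed(11); b <- sample_kn_angle(662, 100)
  expect_identical(a, b)
})

test_that("geometric angle handles axis-aligned and oblique cases", {
  expect_equal(geometric_angle(c(0, 0, 0), c(0, 0, 1), c(0, 0, 130)), 0)
  expect_equal(geometric_angle(c(0, 0, 0), c(0, 0, 1), c(130, 0, 130)), 45)
  expect_equal(geometric_angle(c(0, 0, 0), c(0, 0, 1), c(87.48866, 0, 1000)),
               5, tolerance = 1e-5)
  expect_error(geometric_angle(c(1, 2, 3), c(0, 0, 1), c(1, 2, 3)),
               "coincides")
})

test_that("geometric angle is invariant under rigid rotations", {
  set.seed(3)
  for (i in 1:20) {
    apex <- rnorm(3) * 10
    axis <- rnorm(3)
    point <- rnorm(3) * 100
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    a0 <- geometric_angle(apex, axis, point)
    a1 <- geometric_angle(as.vector(R %*% apex), as.vector(R %*% axis),
                          as.vector(R %*% point))
    expect_equal(a0, a1, tolerance = 1e-9)
  }
})

test_that("angular displacement converts resolution to lateral shift", {
  expect_equal(angular_displacement(5, 100), 100 * tan(5 * pi / 180))
  expect_equal(signif(angular_displacement(5, 100), 2), 8.7)
  expect_equal(signif(angular_displacement(6, 100), 3), 10.5)
})
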
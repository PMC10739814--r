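test_that("histogramming uses half-open bins and conserves counts", {
  ev <- data.frame(E1_keV = c(100, 100, 100), E2_keV = c(378, 379, 650))
  spec <- histogram_energies(ev, bin_width = 1, range = c(300, 700))
  expect_equal(spec$counts[spec$centers == 478.5], 1)
  expect_equal(spec$counts[spec$centers == 479.5], 1)
  expect_equal(sum(spec$counts) + spec$n_out_of_range, nrow(ev))
  # boundary event falls in the bin whose low edge it sits on
  spec2 <- histogram_energies(data.frame(E1_keV = 100, E2_keV = 368),
                              bin_width = 2, range = c(300, 700))
  expect_equal(spec2$counts[spec2$centers == 469], 1)
  expect_error(histogram_energies(ev, bin_width = 1, range = c(500, 400)),
               "empty")
})

test_that("net/gross is exact on a constructed flat-background spectrum", {
  # flat 10 counts per 1 keV bin over 440-510, plus 10 extra counts in each
  # of the 20 bins with centers inside [468, 488): 200 net over 200 bg
  counts <- rep(10, 70)
  centers <- 440:509 + 0.5
  counts[centers >= 468 & centers <= 488] <- 20
  spec <- make_spectrum(counts, 440)
  res <- net_gross_ratio(spec)
  expect_equal(res$gross, 400)
  expect_equal(res$bg_est, 200, tolerance = 1e-10)
  expect_equal(res$ratio, 0.5, tolerance = 1e-10)
  expect_equal(res$fit_slope, 0, tolerance = 1e-12)
  expect_false(res$low_signal)
})

test_that("pure background gives a ratio consistent with zero", {
  set.seed(31)
  counts <- rpois(70, 400)
  spec <- make_spectrum(counts, 440)
  res <- net_gross_ratio(spec)
  expect_lt(abs(res$ratio), 3 * res$sigma_ratio)
})

test_that("the net estimate is invariant under adding an exact linear background", {
  peak <- ifelse(abs(440:509 + 0.5 - 478) < 6, 50, 0)
  base1 <- 20 + 0 * (440:509)
  base2 <- 5 + 0.8 * (440:509 - 440)
  r1 <- net_gross_ratio(make_spectrum(peak + base1, 440))
  r2 <- net_gross_ratio(make_spectrum(peak + base2, 440))
  expect_equal(r1$net, r2$net, tolerance = 1e-9)
})

test_that("the ratio grows with peak amplitude at fixed background", {
  centers <- 440:509 + 0.5
  ratios <- vapply(c(50, 100, 200), function(A) {
    counts <- 10 + A * exp(-(centers - 478)^2 / (2 * 4^2))
    net_gross_ratio(make_spectrum(counts, 440))$ratio
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("sideband and window misconfiguration raise errors", {
  spec <- make_spectrum(rep(10, 70), 440)
  expect_error(net_gross_ratio(spec, sidebands = list(c(430, 434), c(435, 438))),
               "sideband")
  expect_error(net_gross_ratio(spec, peak_window = c(455, 470)), "disjoint")
})

test_that("photopeak fit recovers a noiseless Gaussian and scales correctly", {
  centers <- 600:719 + 0.5
  sg <- 662 * 0.022 / (2 * sqrt(2 * log(2)))
  counts <- 500 * exp(-(centers - 662)^2 / (2 * sg^2)) + 20
  spec <- make_spectrum(counts, 600)
  f <- fit_photopeak(spec, c(630, 694))
  expect_true(f$converged)
  expect_equal(f$centroid, 662, tolerance = 1e-4)
  expect_equal(f$fwhm / f$centroid, 0.022, tolerance = 1e-3)
  # centroid invariant under uniform count scaling
  f2 <- fit_photopeak(make_spectrum(3 * counts, 600), c(630, 694))
  expect_equal(f2$centroid, f$centroid, tolerance = 1e-6)
  expect_equal(f2$area, 3 * f$area, tolerance = 1e-3)
})

test_that("simulated 478 keV photopeak centroid is recovered within 0.1 keV", {
  ev <- make_events(1e5, E0 = 478, seed = 33)
  spec <- histogram_energies(ev, bin_width = 1, range = c(400, 560))
  f <- fit_photopeak(spec, c(456, 500))
  expect_equal(f$centroid, 478, tolerance = 0.1 / 478)
})

test_that("the 478 keV net/gross ratio is higher with a boron target in place", {
  ratio_of <- function(nm) {
    lm <- generate_listmode(preset_scene(nm), test_geometry, test_response,
                            seed = 321)
    # spectra keep the E1 and X-ray rules but not the energy window
    sel <- select_events(lm, selection_config(window_lo = 1e-9,
                                              window_hi = 1e9),
                         test_geometry)$selected
    net_gross_ratio(histogram_energies(sel, 2, c(300, 700)))$ratio
  }
  r_nt <- ratio_of("no_target")
  expect_gt(ratio_of("b4c_x-2"), r_nt)
  expect_gt(ratio_of("b4c_x-12"), r_nt)
})
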
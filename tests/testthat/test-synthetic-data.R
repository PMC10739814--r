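test_that("capture emissions follow the branching probability", {
  set.seed(71)
  n <- 1e5
  k <- simulate_capture_emissions(n)
  expect_equal(k / n, 0.94, tolerance = 0.005 / 0.94)
  expect_equal(simulate_capture_emissions(1000, branching = 0), 0L)
  expect_equal(simulate_capture_emissions(1000, branching = 1), 1000L)
})

test_that("boron-10 inventory follows the closed-form mass fraction", {
  expect_equal(signif(b10_mass(100), 3), 14.5)
  expect_equal(signif(b10_mass(20), 2), 2.9)
  # pure 10B boron carbide: fraction is 4 m10 / (4 m10 + mC)
  expect_equal(b10_mass(1, abundance = 1),
               4 * 10.013 / (4 * 10.013 + 12.011), tolerance = 1e-9)
})

test_that("clinical-equivalence time matches the worked example and is linear", {
  t0 <- equivalent_treatment_time(1e3, 1, 7200, 1e9, 80, 100, 1.0)
  expect_equal(t0, 0.9)
  expect_equal(round(t0), 1)
  expect_equal(equivalent_treatment_time(1e3, 1, 14400, 1e9, 80, 100), 2 * t0)
  expect_equal(equivalent_treatment_time(2, 3, 1, 6, 1e6, 1, 1), 1)
  expect_error(equivalent_treatment_time(0, 1, 1, 1, 1, 1), "positive")
})

test_that("preset scenes encode the study conditions", {
  labs <- function(nm) vapply(preset_scene(nm)$components,
                              function(c) c$label, "")
  expect_false("PG_target" %in% labs("no_target"))
  expect_true(all(c("AG", "Cd558", "PCB478", "continuum") %in%
                    labs("no_target")))
  pg_int <- function(nm) {
    for (c in preset_scene(nm)$components) {
      if (c$label == "PG_target") return(c$intensity)
    }
  }
  # the recorded PG rate combines the thermal flux (decreasing along +X)
  # with the solid-angle acceptance (largest near the camera axis); both
  # leave the X = +80 mm scene weakest
  expect_gt(pg_int("b4c_x-12"), pg_int("b4c_x8"))
  expect_gt(pg_int("b4c_x-2"), pg_int("b4c_x8"))
  wt <- preset_scene("water_tank")
  expect_true(any(vapply(wt$components, function(c)
    identical(c$line_energy, 2200), TRUE)))
  expect_error(preset_scene("nope"), "b4c_x-12")
})

test_that("generation is reproducible and component streams are independent", {
  sc <- preset_scene("b4c_x-2", exposure = 30)
  a <- generate_listmode(sc, test_geometry, test_response, seed = 5)
  b <- generate_listmode(sc, test_geometry, test_response, seed = 5)
  expect_identical(a$events, b$events)
  # dropping a component leaves the others' events bit-identical
  sc2 <- sc
  sc2$components <- Filter(function(c) c$label != "PG_target", sc$components)
  c_set <- generate_listmode(sc2, test_geometry, test_response, seed = 5)
  expect_identical(c_set$events[, -1],
                   a$events[a$events$truth_label != "PG_target", -1],
                   ignore_attr = TRUE)
})

test_that("truth labels account for every event and hits lie in the stack", {
  sc <- preset_scene("b4c_x-2", exposure = 60)
  lm <- generate_listmode(sc, test_geometry, test_response, seed = 6)
  ev <- lm$events
  expect_equal(sum(table(ev$truth_label)), nrow(ev))
  expect_true(all(ev$E1_keV > 0 & ev$E2_keV > 0))
  expect_true(all(ev$scatterer_layer %in% 0:7))
  expect_true(all(ev$absorber_layer %in% 0:3))
  # unblurred hit Z positions coincide with layer planes
  lm0 <- generate_listmode(sc, test_geometry, test_response, seed = 6,
                           blur = FALSE)
  expect_true(all(lm0$events$z1_mm %in% test_geometry$scatterer_z))
  expect_true(all(lm0$events$z2_mm %in% test_geometry$absorber_z))
  expect_true(all(abs(lm0$events$x1_mm) <= 25 & abs(lm0$events$y1_mm) <= 25))
  expect_true(all(abs(lm0$events$x2_mm) <= 25 & abs(lm0$events$y2_mm) <= 25))
})

test_that("unblurred prompt-gamma events are kinematically exact at 478 keV", {
  sc <- scene("pg_only", list(
    source_component("PG_target", "line", line_energy = 478,
                     spatial = spatial_cylinder(c(-20, 0, 130), 25, 60),
                     intensity = 10)), exposure = 60)
  lm <- generate_listmode(sc, test_geometry, test_response, seed = 7,
                          blur = FALSE)
  ev <- lm$events
  expect_gt(nrow(ev), 100)
  expect_equal(ev$E1_keV + ev$E2_keV, rep(478, nrow(ev)), tolerance = 1e-9)
  ok <- ev$E1_keV > 0.2
  expect_false(any(is.na(kinematic_angle(ev$E1_keV[ok], ev$E2_keV[ok]))))
})

test_that("per-component event counts are Poisson with the configured means", {
  sc <- scene("tiny", list(
    source_component("PG_target", "line", line_energy = 478,
                     spatial = spatial_point(0, 0, 130), intensity = 5)),
    exposure = 1)
  counts <- vapply(1:200, function(s) {
    nrow(generate_listmode(sc, test_geometry, test_response, seed = s)$events)
  }, 0L)
  # chi-square dispersion test for Poisson(5), alpha = 0.001
  stat <- sum((counts - 5)^2 / 5)
  expect_gt(stat, qchisq(0.0005, df = 200))
  expect_lt(stat, qchisq(0.9995, df = 200))
  expect_equal(mean(counts), 5, tolerance = 0.2)
})

test_that("a point-source scene back-projects onto its true position", {
  sc <- scene("pt", list(
    source_component("PG_target", "line", line_energy = 478,
                     spatial = spatial_point(-20, 0, 130), intensity = 60)),
    exposure = 60)
  lm <- generate_listmode(sc, test_geometry, test_response, seed = 8)
  sel <- select_events(lm)$selected
  bp <- backproject(sel, image_grid(pixel = 5), test_response)
  am <- image_argmax(bp)
  expect_lte(abs(am[["x"]] - (-20)), 5)
  expect_lte(abs(am[["y"]]), 5)
})

test_that("list-mode data round-trip through CSV with metadata", {
  sc <- preset_scene("no_target", exposure = 10)
  lm <- generate_listmode(sc, test_geometry, test_response, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_listmode(lm, path)
  back <- read_listmode(path)
  expect_equal(back$events$E1_keV, lm$events$E1_keV, tolerance = 1e-12)
  expect_equal(back$events$truth_label, lm$events$truth_label)
  expect_equal(back$scene_name, "no_target")
  expect_equal(back$exposure_s, 10)
  expect_equal(back$camera_hash, lm$camera_hash)
})

test_that("an all-zero scene warns and returns an empty set", {
  sc <- scene("empty", list(
    source_component("AG", "line", line_energy = 511,
                     spatial = spatial_point(0, 0, 130), intensity = 0)),
    exposure = 10)
  expect_warning(lm <- generate_listmode(sc, test_geometry, test_response,
                                         seed = 1), "zero")
  expect_equal(nrow(lm$events), 0L)
})
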
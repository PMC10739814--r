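# Shared fixtures: a default camera and a response model calibrated once per
# test run (the calibration itself is exercised in its own tests).

test_geometry <- camera_geometry()

test_response <- local({
  calibrate_angular_blur(test_geometry, response_model(), n_events = 20000)
})

# Small seeded point-source event sample.
make_events <- function(n, E0 = 478, source = c(0, 0, 130),
                        model = test_response, seed = 42, blur = TRUE) {
  set.seed(seed)
  simulate_point_source(n, E0, source, test_geometry, model, blur = blur)
}

# A spectrum built directly from bin counts (edges lo:hi at 1 keV).
make_spectrum <- function(counts, lo) {
  edges <- lo + 0:length(counts)
  structure(list(edges = edges, counts = counts, errors = sqrt(counts),
                 centers = edges[-length(edges)] + 0.5,
                 n_out_of_range = 0L),
            class = "spectrum")
}
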
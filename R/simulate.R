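# Seeded Monte-Carlo generation of list-mode two-hit events.
#
# Transport is phenomenological: a component's intensity directly sets the
# expected number of recorded two-hit events; there is no attenuation or
# neutron transport.  For line and target-scatter components the generator
# produces kinematically exact Compton topologies (scatter in a Si layer,
# full absorption in a CdTe layer) and then folds them through the response
# model; continuum components get uncorrelated fake hit geometry.

#' Simulate prompt-gamma emissions from neutron captures
#'
#' Each boron neutron capture leaves the \eqn{^7}Li product in its excited
#' state, and hence emits a 478 keV prompt gamma, with probability
#' `branching` (0.94 by default).  The number of emissions over `n_captures`
#' captures is a single binomial draw.
#'
#' @param n_captures Number of capture reactions.
#' @param branching Per-capture emission probability in \eqn{[0, 1]}.
#' @return Integer count of prompt-gamma emissions.
#' @export
simulate_capture_emissions <- function(n_captures, branching = 0.94) {
  stopifnot(n_captures >= 0, branching >= 0, branching <= 1)
  rbinom(1, size = n_captures, prob = branching)
}

# Sample n emission points from a spatial descriptor; returns an n x 3
# matrix (mm).
sample_origins <- function(spatial, n, geometry) {
  switch(spatial$type,
    point = matrix(spatial$center, nrow = n, ncol = 3, byrow = TRUE),
    box = {
      c0 <- spatial$center; h <- spatial$half_sizes
      cbind(runif(n, c0[1] - h[1], c0[1] + h[1]),
            runif(n, c0[2] - h[2], c0[2] + h[2]),
            runif(n, c0[3] - h[3], c0[3] + h[3]))
    },
    cylinder = {
      c0 <- spatial$center
      r <- spatial$radius * sqrt(runif(n))
      phi <- runif(n, 0, 2 * pi)
      cbind(c0[1] + r * cos(phi), c0[2] + r * sin(phi),
            c0[3] + runif(n, -spatial$height / 2, spatial$height / 2))
    },
    internal_camera = {
      h <- geometry$half_side
      z_lo <- min(geometry$absorber_z) - geometry$thickness
      cbind(runif(n, -h, h), runif(n, -h, h), runif(n, z_lo, 0))
    },
    stop("unknown spatial type: ", spatial$type))
}

# Orthonormal pair perpendicular to each row of unit matrix d (n x 3).
perp_basis <- function(d) {
  n <- nrow(d)
  up <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  steep <- abs(d[, 3]) > 0.99
  up[steep, ] <- matrix(rep(c(1, 0, 0), each = sum(steep)), ncol = 3)
  e1 <- cbind(d[, 2] * up[, 3] - d[, 3] * up[, 2],
              d[, 3] * up[, 1] - d[, 1] * up[, 3],
              d[, 1] * up[, 2] - d[, 2] * up[, 1])
  e1 <- normalize_rows(e1)
  e2 <- cbind(d[, 2] * e1[, 3] - d[, 3] * e1[, 2],
              d[, 3] * e1[, 1] - d[, 1] * e1[, 3],
              d[, 1] * e1[, 2] - d[, 2] * e1[, 1])
  list(e1 = e1, e2 = e2)
}

# Core engine: n true Compton two-hit topologies for photons of energy E0
# (vector) emitted at `origins` (n x 3), folded through the response model.
# Set blur = FALSE for kinematically exact events.
simulate_compton_events <- function(n, E0, origins, geometry, model,
                                    blur = TRUE) {
  if (n == 0) return(empty_event_df())
  E0 <- rep_len(E0, n)
  h <- geometry$half_side

  # scatter hit: uniform over a uniformly chosen Si layer
  L1 <- sample.int(geometry$n_scatterers, n, replace = TRUE) - 1L
  r1 <- cbind(runif(n, -h, h), runif(n, -h, h), geometry$scatterer_z[L1 + 1L])
  # guard against an emission point coinciding with the scatter hit
  close <- which(row_norm(r1 - origins) < 1e-3)
  while (length(close) > 0) {
    r1[close, 1] <- runif(length(close), -h, h)
    r1[close, 2] <- runif(length(close), -h, h)
    close <- close[row_norm(r1[close, , drop = FALSE] -
                              origins[close, , drop = FALSE]) < 1e-3]
  }
  d <- normalize_rows(r1 - origins)

  # scattering angle, azimuth and absorber layer: jointly resampled until
  # the scattered ray crosses the chosen absorber plane inside its lateral
  # extent.  This rejection emulates the finite geometric acceptance of the
  # absorber stack.
  theta <- numeric(n); L2 <- integer(n); r2 <- matrix(0, n, 3)
  active <- seq_len(n)
  basis <- perp_basis(d)
  iter <- 0
  while (length(active) > 0) {
    iter <- iter + 1
    m <- length(active)
    th <- radians(sample_kn_angle(E0[active], m))
    phi <- runif(m, 0, 2 * pi)
    l2 <- sample.int(geometry$n_absorbers, m, replace = TRUE) - 1L
    da <- d[active, , drop = FALSE]
    s <- cos(th) * da +
      sin(th) * (cos(phi) * basis$e1[active, , drop = FALSE] +
                 sin(phi) * basis$e2[active, , drop = FALSE])
    z_t <- geometry$absorber_z[l2 + 1L]
    dz <- s[, 3]
    t <- (z_t - r1[active, 3]) / dz
    x2 <- r1[active, 1] + t * s[, 1]
    y2 <- r1[active, 2] + t * s[, 2]
    ok <- dz < -1e-9 & t > 0 & abs(x2) <= h & abs(y2) <= h
    acc <- active[ok]
    theta[acc] <- th[ok]; L2[acc] <- l2[ok]
    r2[acc, ] <- cbind(x2[ok], y2[ok], z_t[ok])
    active <- active[!ok]
    if (iter > 5000) stop("geometric acceptance rejection did not converge")
  }

  Eprime <- scattered_energy(E0, degrees(theta))
  E1 <- E0 - Eprime
  # forward-scattered events transfer arbitrarily little energy; keep a
  # floor of 0.1 keV so deposited energies stay positive
  E1 <- pmax(E1, 0.1)
  E2 <- Eprime

  if (blur && (model$sigma_pos > 0 || model$sigma_ang_extra > 0 ||
               model$fwhm_ref > 0)) {
    r1m <- r1; r2m <- r2
    if (model$sigma_pos > 0) {
      r1m[, 1:2] <- r1m[, 1:2] + rnorm(2 * n, 0, model$sigma_pos)
      r2m[, 1:2] <- r2m[, 1:2] + rnorm(2 * n, 0, model$sigma_pos)
    }
    if (model$sigma_ang_extra > 0) {
      v <- r1m - r2m
      vn <- row_norm(v)
      u <- v / vn
      b <- perp_basis(u)
      sg <- tan(radians(model$sigma_ang_extra))
      u2 <- normalize_rows(u + rnorm(n, 0, sg) * b$e1 + rnorm(n, 0, sg) * b$e2)
      r2m <- r1m - u2 * vn
    }
    if (model$fwhm_ref > 0) {
      E1 <- blur_energy(E1, model)
      E2 <- blur_energy(E2, model)
    }
  } else {
    r1m <- r1; r2m <- r2
  }

  data.frame(
    E1_keV = E1, E2_keV = E2,
    x1_mm = r1m[, 1], y1_mm = r1m[, 2], z1_mm = r1m[, 3],
    x2_mm = r2m[, 1], y2_mm = r2m[, 2], z2_mm = r2m[, 3],
    scatterer_layer = L1, absorber_layer = L2,
    truth_x_mm = origins[, 1], truth_y_mm = origins[, 2],
    truth_z_mm = origins[, 3]
  )
}

empty_event_df <- function() {
  data.frame(E1_keV = numeric(0), E2_keV = numeric(0),
             x1_mm = numeric(0), y1_mm = numeric(0), z1_mm = numeric(0),
             x2_mm = numeric(0), y2_mm = numeric(0), z2_mm = numeric(0),
             scatterer_layer = integer(0), absorber_layer = integer(0),
             truth_x_mm = numeric(0), truth_y_mm = numeric(0),
             truth_z_mm = numeric(0))
}

#' Simulate two-hit events from a monoenergetic point source
#'
#' Convenience wrapper around the scene generator's Compton engine for a
#' single point source; used for calibration, ARM studies and resolution
#' recovery.  Uses the RNG state in effect (wrap in a seeded context for
#' reproducibility).
#'
#' @param n Number of events.
#' @param E0 Photon energy (keV).
#' @param source_point Source position, length-3 (mm).
#' @param geometry A [camera_geometry()].
#' @param model A [response_model()].
#' @param blur Apply the response blur (default `TRUE`); `FALSE` yields
#'   kinematically exact events.
#' @return A data frame of events (one row per event).
#' @export
simulate_point_source <- function(n, E0, source_point, geometry, model,
                                  blur = TRUE) {
  origins <- matrix(source_point, nrow = n, ncol = 3, byrow = TRUE)
  simulate_compton_events(n, E0, origins, geometry, model, blur = blur)
}

# Continuum component: uncorrelated fake hit geometry with a uniform total
# energy in the component's range, split uniformly between the two hits.
simulate_continuum_events <- function(n, energy_range, geometry, model,
                                      blur = TRUE) {
  if (n == 0) return(empty_event_df())
  h <- geometry$half_side
  L1 <- sample.int(geometry$n_scatterers, n, replace = TRUE) - 1L
  L2 <- sample.int(geometry$n_absorbers, n, replace = TRUE) - 1L
  etot <- runif(n, energy_range[1], energy_range[2])
  u <- runif(n, 0.002, 0.998)
  E1 <- etot * u
  E2 <- etot - E1
  if (blur && model$fwhm_ref > 0) {
    E1 <- blur_energy(E1, model)
    E2 <- blur_energy(E2, model)
  }
  data.frame(
    E1_keV = E1, E2_keV = E2,
    x1_mm = runif(n, -h, h), y1_mm = runif(n, -h, h),
    z1_mm = geometry$scatterer_z[L1 + 1L],
    x2_mm = runif(n, -h, h), y2_mm = runif(n, -h, h),
    z2_mm = geometry$absorber_z[L2 + 1L],
    scatterer_layer = L1, absorber_layer = L2,
    truth_x_mm = NA_real_, truth_y_mm = NA_real_, truth_z_mm = NA_real_
  )
}

#' Generate a list-mode data set for a scene
#'
#' For each component of the scene the event count is drawn as
#' Poisson(intensity x exposure) and that many two-hit events are simulated:
#' line and target-scatter components through the full Compton engine (true
#' emission point, Klein-Nishina scattering angle, kinematic energy split,
#' geometric absorber acceptance, then position, axis-tilt and energy blur);
#' continuum components with uncorrelated fake geometry.  Each component
#' draws from its own RNG stream derived deterministically from the global
#' seed and the component label, so removing a component leaves all others'
#' events bit-identical.  Events are interleaved by a per-event random
#' ordering key drawn inside the component's stream.
#'
#' @param scene A [scene()] (e.g. from [preset_scene()]).
#' @param geometry A [camera_geometry()].
#' @param response A [response_model()], normally calibrated with
#'   [calibrate_angular_blur()].
#' @param seed Integer seed; the run is fully reproducible given
#'   (scene, seed).
#' @param blur Apply the response blur (default `TRUE`).
#' @return A `listmode_set`: list with elements `events` (data frame with
#'   energies, hit positions, layer indices and truth columns), `scene_name`,
#'   `exposure_s`, `seed`, `camera_hash`, `created`.
#' @export
generate_listmode <- function(scene, geometry, response, seed, blur = TRUE) {
  stopifnot(inherits(scene, "scene"))
  if (all(vapply(scene$components, function(c) c$intensity, 0) == 0)) {
    warning("all component intensities are zero; returning an empty set")
  }
  parts <- list()
  for (comp in scene$components) {
    cs <- component_seed(seed, comp$label)
    part <- with_seed(cs, {
      n <- rpois(1, comp$intensity * scene$exposure)
      ev <- if (n == 0) {
        empty_event_df()
      } else if (comp$kind == "continuum") {
        simulate_continuum_events(n, comp$energy_range, geometry, response,
                                  blur = blur)
      } else {
        origins <- sample_origins(comp$spatial, n, geometry)
        E0 <- if (comp$kind == "line") {
          e <- rep(comp$line_energy, n)
          if (comp$intrinsic_fwhm > 0 && n > 0) {
            e <- abs(rnorm(n, e, comp$intrinsic_fwhm / .FWHM_SIGMA))
          }
          e
        } else {
          runif(n, comp$energy_range[1], comp$energy_range[2])
        }
        simulate_compton_events(n, E0, origins, geometry, response,
                                blur = blur)
      }
      if (nrow(ev) > 0) {
        ev$truth_label <- comp$label
        ev$.order_key <- runif(nrow(ev))
      }
      ev
    })
    if (nrow(part) > 0) parts[[length(parts) + 1L]] <- part
  }
  if (length(parts) == 0) {
    events <- empty_event_df()
    events$truth_label <- character(0)
  } else {
    events <- do.call(rbind, parts)
    events <- events[order(events$.order_key), , drop = FALSE]
    events$.order_key <- NULL
    rownames(events) <- NULL
  }
  events <- if (nrow(events) > 0) {
    cbind(event_id = seq_len(nrow(events)), events)
  } else {
    cbind(data.frame(event_id = integer(0)), events)
  }
  listmode_set(events, scene$name, scene$exposure, seed,
               camera_hash(geometry, response))
}

#' Construct a list-mode set
#'
#' @param events Event data frame.
#' @param scene_name,exposure_s,seed,camera_hash Acquisition metadata.
#' @return An object of class `listmode_set`.
#' @export
listmode_set <- function(events, scene_name, exposure_s, seed, camera_hash) {
  lm <- list(events = events, scene_name = scene_name,
             exposure_s = exposure_s, seed = seed,
             camera_hash = camera_hash,
             created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  class(lm) <- "listmode_set"
  lm
}

#' @export
print.listmode_set <- function(x, ...) {
  cat(sprintf("List-mode set '%s': %d events, %g s exposure, seed %s\n",
              x$scene_name, nrow(x$events), x$exposure_s,
              format(x$seed)))
  if (nrow(x$events) > 0 && "truth_label" %in% names(x$events)) {
    tab <- table(x$events$truth_label)
    cat("  components:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Accept either a listmode_set or a bare event data frame.
as_event_df <- function(x) {
  if (inherits(x, "listmode_set")) x$events
  else if (is.data.frame(x)) x
  else stop("expected a listmode_set or an event data frame")
}

#' Fingerprint of a camera configuration
#'
#' Short deterministic hex hash of the geometry and response parameters,
#' stored in list-mode metadata so that data sets can be matched to the
#' configuration that produced them.
#'
#' @param geometry A [camera_geometry()].
#' @param response A [response_model()].
#' @return Hex string.
#' @export
camera_hash <- function(geometry, response) {
  key <- paste(
    c(unlist(geometry[c("n_scatterers", "n_absorbers", "side", "thickness",
                        "scatterer_pitch", "gap", "absorber_pitch")]),
      unlist(response[c("fwhm_ref", "e_ref", "arm_fwhm_ref", "sigma_pos",
                        "sigma_ang_extra")])),
    collapse = "|")
  sprintf("%08x", str_hash31(key))
}

#' Write / read list-mode events as CSV with a YAML metadata sidecar
#'
#' The interchange format is columnar text: one row per event with columns
#' `event_id`, `E1_keV`, `E2_keV`, `x1_mm` ... `z2_mm`, `scatterer_layer`,
#' `absorber_layer`, `truth_label`, `truth_x_mm`, `truth_y_mm`,
#' `truth_z_mm`; acquisition metadata (scene, exposure, seed, camera hash)
#' goes to `<path>.meta.yaml`.
#'
#' @param x A `listmode_set`.
#' @param path CSV file path.
#' @return `write_listmode()` returns `path` invisibly; `read_listmode()`
#'   returns a `listmode_set`.
#' @export
write_listmode <- function(x, path) {
  stopifnot(inherits(x, "listmode_set"))
  write.csv(x$events, path, row.names = FALSE, quote = FALSE)
  meta <- list(scene = x$scene_name, exposure_s = x$exposure_s,
               seed = x$seed, camera_hash = x$camera_hash,
               created = x$created)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path) {
  events <- read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  listmode_set(events,
               scene_name = meta$scene %||% NA_character_,
               exposure_s = meta$exposure_s %||% NA_real_,
               seed = meta$seed %||% NA_integer_,
               camera_hash = meta$camera_hash %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
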
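# Compton-cone back-projection onto the target plane and list-mode MLEM.

#' Image grid on the target plane
#'
#' A regular pixel grid on the plane Z = `z_plane` (130 mm by default: the
#' plane on which the targets sit).  Ranges are trimmed to a whole number of
#' pixels.
#'
#' @param z_plane Plane position (mm).
#' @param x_range,y_range Length-2 lateral ranges (mm).
#' @param pixel Pixel side (mm), positive.
#' @return An object of class `image_grid` with pixel-centre coordinates
#'   `x_centers` (length `nx`) and `y_centers` (length `ny`).
#' @export
image_grid <- function(z_plane = 130, x_range = c(-200, 200),
                       y_range = c(-200, 200), pixel = 5) {
  stopifnot(pixel > 0, x_range[2] > x_range[1], y_range[2] > y_range[1])
  nx <- floor((x_range[2] - x_range[1]) / pixel)
  ny <- floor((y_range[2] - y_range[1]) / pixel)
  g <- list(z_plane = z_plane, pixel = pixel, nx = nx, ny = ny,
            x_range = c(x_range[1], x_range[1] + nx * pixel),
            y_range = c(y_range[1], y_range[1] + ny * pixel),
            x_centers = x_range[1] + pixel * (seq_len(nx) - 0.5),
            y_centers = y_range[1] + pixel * (seq_len(ny) - 0.5))
  class(g) <- "image_grid"
  g
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("z_plane", "pixel", "nx", "ny", "x_range", "y_range")],
                   b[c("z_plane", "pixel", "nx", "ny", "x_range", "y_range")]))
}

#' Construct a plane image
#'
#' @param grid An [image_grid()].
#' @param values Numeric `nx` x `ny` matrix of pixel intensities (rows run
#'   along X, columns along Y).
#' @param provenance One of `"backprojection"`, `"mlem"`, `"subtracted"`.
#' @return An object of class `plane_image`.
#' @export
plane_image <- function(grid, values, provenance) {
  stopifnot(inherits(grid, "image_grid"),
            nrow(values) == grid$nx, ncol(values) == grid$ny)
  img <- list(grid = grid, values = values, provenance = provenance)
  class(img) <- "plane_image"
  img
}

#' @export
print.plane_image <- function(x, ...) {
  cat(sprintf("Plane image (%s): %d x %d pixels of %g mm at Z = %g mm, range [%.3g, %.3g]\n",
              x$provenance, x$grid$nx, x$grid$ny, x$grid$pixel,
              x$grid$z_plane, min(x$values), max(x$values)))
  invisible(x)
}

#' Compton cones of selected events
#'
#' Builds the per-event cone: apex at the scatterer hit, axis from the
#' absorber hit toward the scatterer hit, half-angle the kinematic
#' scattering angle, and a per-event angular uncertainty taken from the
#' response model's ARM scaled to `assumed_E0`.
#'
#' Two energy conventions are supported.  The default, `"measured-total"`,
#' takes the half-angle from the measured pair \eqn{(E_1, E_2)}:
#' \eqn{\cos\theta = 1 - 511(1/E_2 - 1/(E_1+E_2))}; `assumed_E0` then enters
#' only through the angular-uncertainty scaling.  With
#' `"assumed-initial"` the incident energy is fixed at `assumed_E0` (478 keV
#' for prompt-gamma imaging) and \eqn{\cos\theta = 1 -
#' 511(1/(E_0-E_1) - 1/E_0)}; within the 468-488 keV selection window the
#' two differ negligibly.
#'
#' @param data A `listmode_set` or event data frame (normally selected).
#' @param response A [response_model()].
#' @param assumed_E0 Assumed incident energy (keV), default 478.
#' @param convention `"measured-total"` (default) or `"assumed-initial"`.
#' @return List with matrices `apex` (n x 3), `axis` (n x 3, unit rows),
#'   vectors `half_angle` and `sigma_axis` (degrees), and `n_invalid`
#'   (events skipped as kinematically invalid).
#' @export
event_cone <- function(data, response, assumed_E0 = 478,
                       convention = c("measured-total", "assumed-initial")) {
  convention <- match.arg(convention)
  ev <- as_event_df(data)
  ct <- if (convention == "measured-total") {
    kinematic_angle(ev$E1_keV, ev$E2_keV)
  } else {
    e2 <- assumed_E0 - ev$E1_keV
    ct <- rep(NA_real_, nrow(ev))
    pos <- e2 > 0
    ct[pos] <- 1 - .MEC2 * (1 / e2[pos] - 1 / assumed_E0)
    ct[!is.na(ct) & (ct < -1 | ct > 1)] <- NA_real_
    ct
  }
  ok <- !is.na(ct)
  apex <- cbind(ev$x1_mm, ev$y1_mm, ev$z1_mm)[ok, , drop = FALSE]
  r2 <- cbind(ev$x2_mm, ev$y2_mm, ev$z2_mm)[ok, , drop = FALSE]
  axis <- normalize_rows(apex - r2)
  list(apex = apex, axis = axis,
       half_angle = degrees(acos(ct[ok])),
       sigma_axis = rep(arm_sigma_at(response, assumed_E0), sum(ok)),
       n_invalid = sum(!ok))
}

# Event-pixel weight matrix t_ij = exp(-D^2 / 2 sigma_i^2), D the angular
# distance between each cone surface and each pixel-centre direction.
# Computed in row chunks to bound peak memory.
cone_weights <- function(cones, grid, chunk = 512L) {
  px <- as.matrix(expand.grid(x = grid$x_centers, y = grid$y_centers))
  pts <- cbind(px, grid$z_plane)
  n <- nrow(cones$apex)
  np <- nrow(pts)
  t_ij <- matrix(0, n, np)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    idx <- i:j
    dx <- outer(cones$apex[idx, 1], pts[, 1], function(a, b) b - a)
    dy <- outer(cones$apex[idx, 2], pts[, 2], function(a, b) b - a)
    dz <- outer(cones$apex[idx, 3], pts[, 3], function(a, b) b - a)
    dn <- sqrt(dx^2 + dy^2 + dz^2)
    ct <- (cones$axis[idx, 1] * dx + cones$axis[idx, 2] * dy +
             cones$axis[idx, 3] * dz) / dn
    ct <- pmin(1, pmax(-1, ct))
    delta <- degrees(acos(ct)) - cones$half_angle[idx]
    t_ij[idx, ] <- exp(-delta^2 / (2 * cones$sigma_axis[idx]^2))
    i <- j + 1L
  }
  t_ij
}

#' Cone back-projection onto the target plane
#'
#' Each event's cone is spread onto the grid with a Gaussian angular
#' profile: pixel j receives \eqn{t_{ij} = \exp(-\Delta_{ij}^2/2\sigma_i^2)}
#' where \eqn{\Delta_{ij}} is the angle between the cone surface and the
#' apex-to-pixel direction and \eqn{\sigma_i} the per-event angular
#' uncertainty.  The image is the sum over events; it is linear in the data.
#'
#' @param data A `listmode_set` or event data frame of selected events.
#' @param grid An [image_grid()].
#' @param response A [response_model()].
#' @param assumed_E0,convention Passed to [event_cone()].
#' @return A `plane_image` with provenance `"backprojection"` and attribute
#'   `n_invalid`.
#' @export
backproject <- function(data, grid, response, assumed_E0 = 478,
                        convention = "measured-total") {
  ev <- as_event_df(data)
  if (nrow(ev) == 0) {
    img <- plane_image(grid, matrix(0, grid$nx, grid$ny), "backprojection")
    attr(img, "n_invalid") <- 0L
    return(img)
  }
  cones <- event_cone(ev, response, assumed_E0, convention)
  t_ij <- cone_weights(cones, grid)
  vals <- matrix(colSums(t_ij), grid$nx, grid$ny)
  img <- plane_image(grid, vals, "backprojection")
  attr(img, "n_invalid") <- cones$n_invalid
  img
}

#' List-mode MLEM reconstruction
#'
#' Maximum-likelihood expectation-maximization for list-mode Compton data
#' with uniform sensitivity (\eqn{s_j = 1}):
#' \deqn{\lambda_j^{(k+1)} = \lambda_j^{(k)}
#'   \sum_i \frac{t_{ij}}{\sum_m t_{im}\lambda_m^{(k)}}}
#' The Poisson log-likelihood \eqn{\sum_i \log\sum_m t_{im}\lambda_m} is
#' recorded at every iteration and is non-decreasing.  Events with zero
#' forward projection under the initial image are skipped and counted.
#'
#' @param data A `listmode_set` or event data frame of selected events.
#' @param grid An [image_grid()].
#' @param response A [response_model()].
#' @param n_iter Number of iterations, at least 1 (default 10).
#' @param init Initial `plane_image`, or `NULL` for a uniform start.
#' @param assumed_E0,convention Passed to [event_cone()].
#' @return A `plane_image` with provenance `"mlem"`, attributes
#'   `loglik` (per-iteration log-likelihood) and `n_skipped`.
#' @export
mlem <- function(data, grid, response, n_iter = 10, init = NULL,
                 assumed_E0 = 478, convention = "measured-total") {
  stopifnot(n_iter >= 1)
  ev <- as_event_df(data)
  if (nrow(ev) == 0) {
    img <- plane_image(grid, matrix(0, grid$nx, grid$ny), "mlem")
    attr(img, "loglik") <- numeric(0)
    attr(img, "n_skipped") <- 0L
    return(img)
  }
  cones <- event_cone(ev, response, assumed_E0, convention)
  t_ij <- cone_weights(cones, grid)
  np <- grid$nx * grid$ny
  lambda <- if (is.null(init)) {
    # uniform start with total mass equal to the event count: the EM update
    # preserves sum(lambda) = n, and with that mass fixed the logged partial
    # likelihood sum(log(forward)) is non-decreasing from the first
    # iteration (the full Poisson objective subtracts sum(s_j lambda_j),
    # constant on this manifold)
    rep(nrow(ev) / np, np)
  } else {
    stopifnot(inherits(init, "plane_image"), same_grid(init$grid, grid))
    v <- as.vector(init$values)
    if (all(v == 0)) stop("all-zero initial image")
    v
  }
  fwd <- as.vector(t_ij %*% lambda)
  keep <- fwd > 0
  n_skipped <- sum(!keep)
  t_ij <- t_ij[keep, , drop = FALSE]
  loglik <- numeric(n_iter)
  for (k in seq_len(n_iter)) {
    fwd <- as.vector(t_ij %*% lambda)
    loglik[k] <- sum(log(fwd))
    ratio <- 1 / fwd
    lambda <- lambda * as.vector(crossprod(t_ij, ratio))
  }
  img <- plane_image(grid, matrix(lambda, grid$nx, grid$ny), "mlem")
  attr(img, "loglik") <- loglik
  attr(img, "n_skipped") <- n_skipped
  img
}

#' Write / read a plane image as delimited text
#'
#' The grid is written row-major with Y rows from +y down and X columns from
#' -x up, with a YAML sidecar holding the grid geometry and provenance.
#'
#' @param img A `plane_image`.
#' @param path Output file.
#' @return `write_image()` returns `path` invisibly; `read_image()` returns
#'   a `plane_image`.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "plane_image"))
  # values[ix, iy] -> rows of decreasing y
  m <- t(img$values)[rev(seq_len(img$grid$ny)), , drop = FALSE]
  write.table(m, path, row.names = FALSE, col.names = FALSE, sep = "\t")
  g <- img$grid
  yaml::write_yaml(list(z_plane = g$z_plane, pixel = g$pixel,
                        nx = g$nx, ny = g$ny,
                        x_range = g$x_range, y_range = g$y_range,
                        provenance = img$provenance,
                        layout = "rows: +y max down; cols: -x max up"),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  m <- as.matrix(read.table(path, sep = "\t"))
  grid <- image_grid(meta$z_plane, unlist(meta$x_range),
                     unlist(meta$y_range), meta$pixel)
  vals <- t(m[rev(seq_len(grid$ny)), , drop = FALSE])
  dimnames(vals) <- NULL
  plane_image(grid, vals, meta$provenance)
}

#' Pixel position of the image maximum
#'
#' @param img A `plane_image`.
#' @return Length-2 vector: (x, y) of the brightest pixel centre (mm).
#' @export
image_argmax <- function(img) {
  idx <- arrayInd(which.max(img$values), dim(img$values))
  c(x = img$grid$x_centers[idx[1]], y = img$grid$y_centers[idx[2]])
}
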
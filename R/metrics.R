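# Background-image subtraction and the pixel-value-ratio contrast metric.

#' Rectangular region of interest on the image plane
#'
#' @param x_lo,x_hi,y_lo,y_hi Rectangle bounds (mm), `x_lo < x_hi`,
#'   `y_lo < y_hi`.
#' @return An object of class `roi`.
#' @export
roi <- function(x_lo, x_hi, y_lo, y_hi) {
  stopifnot(x_lo < x_hi, y_lo < y_hi)
  r <- list(x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi)
  class(r) <- "roi"
  r
}

#' Subtract a background image pixel-by-pixel
#'
#' Returns `target - scale * background` on the identical grid.  Negative
#' pixels are preserved in the stored image; clipping to zero happens only
#' inside [pvr()].  With equal acquisitions (the usual case: equal-length
#' runs with and without the target) `scale = 1`.
#'
#' @param target_img,background_img `plane_image`s on the same grid.
#' @param scale Background scale factor (default 1; use the exposure ratio
#'   for unequal acquisitions).
#' @return A `plane_image` with provenance `"subtracted"`.
#' @export
subtract_images <- function(target_img, background_img, scale = 1) {
  stopifnot(inherits(target_img, "plane_image"),
            inherits(background_img, "plane_image"))
  if (!same_grid(target_img$grid, background_img$grid)) {
    stop("images are on different grids")
  }
  plane_image(target_img$grid,
              target_img$values - scale * background_img$values,
              "subtracted")
}

#' Pixel-value ratio (PVR) of a region of interest
#'
#' Contrast metric: negative pixels are first clipped to zero, then the mean
#' of the pixels whose centres fall inside the ROI (half-open on the high
#' edges) is divided by the mean of all remaining pixels.  A zero outside
#' mean yields a flagged undefined result rather than an error.
#'
#' @param img A `plane_image`.
#' @param region An [roi()].
#' @return An object of class `pvr_result` with `pvr`, `mean_in`,
#'   `mean_out`, `n_clipped`, `undefined`.
#' @export
pvr <- function(img, region) {
  stopifnot(inherits(img, "plane_image"), inherits(region, "roi"))
  v <- img$values
  n_clipped <- sum(v < 0)
  v[v < 0] <- 0
  in_x <- img$grid$x_centers >= region$x_lo & img$grid$x_centers < region$x_hi
  in_y <- img$grid$y_centers >= region$y_lo & img$grid$y_centers < region$y_hi
  mask <- outer(in_x, in_y, "&")
  if (!any(mask)) stop("ROI does not intersect the image grid")
  mean_in <- mean(v[mask])
  mean_out <- mean(v[!mask])
  res <- list(pvr = if (mean_out > 0) mean_in / mean_out else NA_real_,
              mean_in = mean_in, mean_out = mean_out,
              n_clipped = n_clipped, undefined = !(mean_out > 0))
  class(res) <- "pvr_result"
  res
}

#' @export
print.pvr_result <- function(x, ...) {
  if (x$undefined) {
    cat("PVR: undefined (outside mean is zero)\n")
  } else {
    cat(sprintf("PVR = %.3g (ROI mean %.4g / outside mean %.4g, %d pixels clipped)\n",
                x$pvr, x$mean_in, x$mean_out, x$n_clipped))
  }
  invisible(x)
}

#' ROI covering the target footprint of a scene
#'
#' Projects the lateral extent of the scene's prompt-gamma target onto the
#' image plane: for a cylindrical target, the square of side \eqn{2r}
#' centred on its axis; for a box (the underwater slab), its X-Y bounding
#' rectangle.
#'
#' @param scene A [scene()] containing a `PG_target` component.
#' @param grid An [image_grid()] (used only to check intersection).
#' @return An [roi()].
#' @export
target_roi <- function(scene, grid) {
  comp <- NULL
  for (c in scene$components) if (c$label == "PG_target") comp <- c
  if (is.null(comp)) stop("scene has no PG_target component")
  sp <- comp$spatial
  r <- switch(sp$type,
    cylinder = roi(sp$center[1] - sp$radius, sp$center[1] + sp$radius,
                   sp$center[2] - sp$radius, sp$center[2] + sp$radius),
    box = roi(sp$center[1] - sp$half_sizes[1], sp$center[1] + sp$half_sizes[1],
              sp$center[2] - sp$half_sizes[2], sp$center[2] + sp$half_sizes[2]),
    point = roi(sp$center[1] - grid$pixel, sp$center[1] + grid$pixel,
                sp$center[2] - grid$pixel, sp$center[2] + grid$pixel),
    stop("unsupported target spatial type: ", sp$type))
  if (r$x_hi < grid$x_range[1] || r$x_lo > grid$x_range[2] ||
      r$y_hi < grid$y_range[1] || r$y_lo > grid$y_range[2]) {
    stop("target ROI does not intersect the image grid")
  }
  r
}

#' Is the target region visibly above the background fluctuation?
#'
#' Operational "blob" criterion used to compare reconstructions with the
#' qualitative imaging outcomes: the target is visible when the ROI mean
#' exceeds the mean plus two standard deviations of the non-ROI pixel
#' distribution.
#'
#' @param img A `plane_image`.
#' @param region An [roi()].
#' @return Logical.
#' @export
target_visible <- function(img, region) {
  in_x <- img$grid$x_centers >= region$x_lo & img$grid$x_centers < region$x_hi
  in_y <- img$grid$y_centers >= region$y_lo & img$grid$y_centers < region$y_hi
  mask <- outer(in_x, in_y, "&")
  out <- img$values[!mask]
  mean(img$values[mask]) > mean(out) + 2 * sd(out)
}
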
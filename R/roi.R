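## Ring-shaped region of interest and anatomical quadrants.
##
## The measurement protocol places an annulus concentric with the optic disc,
## from radius (50 + R) to 2(50 + R) pixels where R is the segmented OD
## radius, at the export scale of 1 pixel = 9 microns. The annulus is split
## into supero-temporal (ST), supero-nasal (SN), infero-nasal (IN) and
## infero-temporal (IT) quadrants; which image side is temporal depends on
## eye laterality (for a right eye in a standard non-mirrored export the
## macula, hence the temporal side, lies image-left of the disc).

MICRONS_PER_PIXEL <- 9

#' Convert pixels to microns at the oximetry export scale
#'
#' @param px distance in pixels.
#' @param microns_per_pixel scale, 9 um/px for Oxymap-style exports.
#' @return distance in microns.
#' @examples
#' px_to_microns(8)  # 72, the manual-protocol vessel-diameter cutoff
#' @export
px_to_microns <- function(px, microns_per_pixel = MICRONS_PER_PIXEL) {
  px * microns_per_pixel
}

#' Build the OD-centered ring region of interest
#'
#' @param fit a converged `disc_fit` from [fit_active_disc()] or
#'   [segment_optic_disc()].
#' @param laterality `"right"` or `"left"` eye.
#' @return object of class `ring_roi`: `center` (x, y), `r_inner
#'   = 50 + od_radius`, `r_outer = 2 * r_inner` (pixels), `laterality`,
#'   `pixel_scale` (9 um/px).
#' @export
build_ring_roi <- function(fit, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  stopifnot(inherits(fit, "disc_fit"))
  if (!isTRUE(fit$converged)) {
    stop("disc fit did not converge; refusing to build the ring ROI", call. = FALSE)
  }
  if (!is.finite(fit$od_radius) || fit$od_radius <= 0) {
    stop("od_radius must be positive", call. = FALSE)
  }
  r_inner <- 50 + fit$od_radius
  structure(list(center = c(x = fit$disc$x_c, y = fit$disc$y_c),
                 r_inner = r_inner,
                 r_outer = 2 * r_inner,
                 od_radius = fit$od_radius,
                 laterality = laterality,
                 pixel_scale = MICRONS_PER_PIXEL),
            class = "ring_roi")
}

#' @export
print.ring_roi <- function(x, ...) {
  cat(sprintf("Ring ROI (%s eye): center (%.2f, %.2f), annulus %.1f - %.1f px (%.0f - %.0f um)\n",
              x$laterality, x$center["x"], x$center["y"],
              x$r_inner, x$r_outer,
              px_to_microns(x$r_inner), px_to_microns(x$r_outer)))
  invisible(x)
}

# Quadrant labels for the four diagonal sectors, clockwise from top-left,
# as a named vector c(top_left=, top_right=, bottom_right=, bottom_left=).
quadrant_labels <- function(laterality, swap_temporal = FALSE) {
  temporal_left <- (laterality == "right")
  if (swap_temporal) temporal_left <- !temporal_left
  if (temporal_left) {
    c(top_left = "ST", top_right = "SN", bottom_right = "IN", bottom_left = "IT")
  } else {
    c(top_left = "SN", top_right = "ST", bottom_right = "IT", bottom_left = "IN")
  }
}

#' Ring and quadrant membership masks
#'
#' The ring mask contains pixels whose center lies at distance
#' `r_inner <= d <= r_outer` from the ROI center (closed bounds). Quadrant
#' boundaries are the vertical and horizontal lines through the center, so
#' each quadrant is a diagonal sector (e.g. supero-temporal = top-left for a
#' right eye). The four quadrant masks are pairwise disjoint and their union
#' is exactly the ring mask; flipping laterality relabels ST <-> SN and
#' IT <-> IN.
#'
#' @param roi [build_ring_roi()] result.
#' @param image_shape integer vector `c(rows, cols)`.
#' @param swap_temporal set `TRUE` for mirrored exports where the temporal
#'   side is opposite the standard convention.
#' @return list with `ring` (logical matrix) and `quadrants` (named list of
#'   logical matrices `ST`, `SN`, `IN`, `IT`). A warning is issued when more
#'   than 20\% of the ring area is clipped by the frame.
#' @export
ring_and_quadrant_masks <- function(roi, image_shape, swap_temporal = FALSE) {
  stopifnot(inherits(roi, "ring_roi"), length(image_shape) == 2L,
            all(image_shape >= 1))
  nr <- image_shape[1]; nc <- image_shape[2]
  dx <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - roi$center[["x"]]
  dy <- matrix(seq_len(nr), nr, nc) - roi$center[["y"]]
  d <- sqrt(dx^2 + dy^2)
  ring <- d >= roi$r_inner & d <= roi$r_outer
  n_ring <- sum(ring)
  if (n_ring == 0L) {
    stop_oxi("oxiring_empty_mask", "ring ROI lies fully outside the image")
  }
  full_area <- pi * (roi$r_outer^2 - roi$r_inner^2)
  if (n_ring < 0.8 * full_area) {
    warning(sprintf("ring ROI clipped by the frame: %.0f%% of its area is outside the image",
                    100 * (1 - n_ring / full_area)), call. = FALSE)
  }
  up <- -dy        # superior = decreasing row index
  left <- dx < 0
  top <- up > 0
  sectors <- list(top_left = ring & top & left,
                  top_right = ring & top & !left,
                  bottom_right = ring & !top & !left,
                  bottom_left = ring & !top & left)
  labels <- quadrant_labels(roi$laterality, swap_temporal)
  quadrants <- stats::setNames(sectors[names(labels)], labels)
  list(ring = ring, quadrants = quadrants[c("ST", "SN", "IN", "IT")])
}
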
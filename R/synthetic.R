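## Ground-truthed synthetic oximetry scenes.
##
## The generator emulates the image class the pipeline consumes: a bright
## circular optic disc on a darker background, both rendered in gray (grays
## have r = g = b and therefore decode to "undefined"), and straight vessel
## segments radiating from the disc whose pixels are pseudocolored by the
## exact encoding of known saturations. Arteriolar vessels draw from a high
## mean (healthy arteriolar SatO2, 92.2%), venular vessels from a low mean
## (57.9%), each with i.i.d. per-pixel Gaussian jitter, so the ring
## histogram is bimodal with known ground-truth modes.

#' Synthetic optic-disc test image
#'
#' Bright disc of the given contrast on a zero background, optionally
#' Gaussian-blurred and corrupted with additive Gaussian noise. With zero
#' blur and noise the image is exactly `contrast` times the disc indicator.
#'
#' @param shape `c(rows, cols)`.
#' @param center disc center `c(x, y)` in pixel coordinates.
#' @param radius disc radius in pixels; must be below `min(shape) / 3`.
#' @param contrast disc intensity above the background.
#' @param blur_sd Gaussian blur standard deviation in pixels (0 = none).
#' @param noise_sd additive Gaussian noise standard deviation (0 = none).
#' @param seed RNG seed for the noise; the session RNG state is untouched.
#' @return numeric matrix `[rows, cols]`.
#' @export
make_disc_image <- function(shape, center, radius, contrast = 1,
                            blur_sd = 0, noise_sd = 0, seed = 1) {
  stopifnot(length(shape) == 2L, length(center) == 2L, radius > 0)
  if (radius >= min(shape) / 3) {
    stop("radius must be below min(shape) / 3", call. = FALSE)
  }
  nr <- shape[1]; nc <- shape[2]
  d2 <- outer((seq_len(nr) - center[2])^2, (seq_len(nc) - center[1])^2, "+")
  f <- (d2 <= radius^2) * contrast
  if (blur_sd > 0) f <- EBImage::gblur(f, sigma = blur_sd)
  if (noise_sd > 0) {
    f <- f + with_seed(seed, matrix(rnorm(nr * nc, sd = noise_sd), nr, nc))
  }
  f
}

#' Ground truth for a synthetic oximetry scene
#'
#' The defaults are the standard study conditions used throughout the test
#' suite: a 60 px optic disc at the image center, four arteriolar vessels at
#' the healthy arteriolar mean of 92.2\% SatO2 and four venular vessels at
#' the healthy venular mean of 57.9\%, per-pixel saturation jitter of 1.5\%,
#' vessel width 10 px. One arteriole and one venule are placed in each
#' anatomical quadrant, at seeded random angles keeping at least 5 degrees
#' away from the quadrant boundaries so the quadrant membership of every
#' vessel is unambiguous.
#'
#' @param shape image shape `c(rows, cols)`.
#' @param od_center optic-disc center `c(x, y)`; default image center.
#' @param od_radius optic-disc radius in pixels.
#' @param laterality `"right"` or `"left"`.
#' @param arteriolar_sat,venular_sat generator means in percent.
#' @param n_arterioles,n_venules vessel counts (balanced across quadrants).
#' @param vessel_width vessel width in pixels.
#' @param sat_jitter_sd per-pixel saturation jitter (percent).
#' @param background_value,od_value gray levels (0-255) of background and
#'   disc; both decode to undefined since r = g = b.
#' @param seed RNG seed controlling vessel angles and saturation jitter.
#' @return object of class `scene_truth`.
#' @export
scene_ground_truth <- function(shape = c(512, 512),
                               od_center = NULL,
                               od_radius = 60,
                               laterality = "right",
                               arteriolar_sat = 92.2,
                               venular_sat = 57.9,
                               n_arterioles = 4,
                               n_venules = 4,
                               vessel_width = 10,
                               sat_jitter_sd = 1.5,
                               background_value = 40,
                               od_value = 200,
                               seed = 1) {
  stopifnot(vessel_width >= 1, od_radius > 0,
            arteriolar_sat >= 0, arteriolar_sat <= 100,
            venular_sat >= 0, venular_sat <= 100,
            sat_jitter_sd >= 0)
  if (is.null(od_center)) od_center <- c(shape[2] / 2, shape[1] / 2)

  types <- c(rep("arteriole", n_arterioles), rep("venule", n_venules))
  n <- length(types)
  # one vessel of each type per quadrant where counts allow; angles stay
  # >= 5 degrees from the vertical/horizontal quadrant boundaries
  angles <- with_seed(seed, {
    quad_base <- rep(c(0, 90, 180, 270), length.out = n)
    offset_lo <- ifelse(seq_len(n) <= 4, 5, 50)
    offset_hi <- ifelse(seq_len(n) <= 4, 40, 85)
    quad_base + runif(n, offset_lo, offset_hi)
  })
  vessels <- lapply(seq_len(n), function(i) {
    list(angle_deg = angles[i],
         width = vessel_width,
         mean_sat = if (types[i] == "arteriole") arteriolar_sat else venular_sat,
         type = types[i])
  })
  structure(list(shape = shape,
                 od_center = od_center,
                 od_radius = od_radius,
                 laterality = laterality,
                 vessels = vessels,
                 sat_jitter_sd = sat_jitter_sd,
                 background_value = background_value,
                 od_value = od_value,
                 seed = seed),
            class = "scene_truth")
}

# pixels within width/2 of the radial segment [r0, r1] at angle a (degrees,
# measured counterclockwise from image-right; superior = up = decreasing row)
radial_segment_mask <- function(shape, center, angle_deg, width, r0, r1) {
  nr <- shape[1]; nc <- shape[2]
  a <- angle_deg * pi / 180
  ux <- cos(a); uy <- -sin(a)
  px <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[1]
  py <- matrix(seq_len(nr), nr, nc) - center[2]
  along <- px * ux + py * uy
  perp <- abs(px * uy - py * ux)
  along >= r0 & along <= r1 & perp <= width / 2
}

#' Render a synthetic oximetry scene
#'
#' @param truth [scene_ground_truth()].
#' @param shape optional override of `truth$shape`.
#' @return list with `image` (integer array `[rows, cols, 3]`, 0-255) and
#'   `truth`, where `truth` is augmented with `vessel_mask` (logical matrix
#'   of pseudocolored pixels, after the optic disc is drawn on top) and
#'   `n_vessel_pixels`. Vessels reaching outside the frame are clipped with
#'   a warning.
#' @export
make_oximetry_scene <- function(truth = scene_ground_truth(), shape = NULL) {
  stopifnot(inherits(truth, "scene_truth"))
  if (!is.null(shape)) truth$shape <- shape
  nr <- truth$shape[1]; nc <- truth$shape[2]
  cx <- truth$od_center[1]; cy <- truth$od_center[2]

  r_outer <- 2 * (50 + truth$od_radius)
  r_end <- r_outer * 1.07
  if (cx - r_end < 1 || cx + r_end > nc || cy - r_end < 1 || cy + r_end > nr) {
    warning("vessels reach outside the frame and are clipped", call. = FALSE)
  }

  img <- array(as.integer(truth$background_value), dim = c(nr, nc, 3L))
  vessel_mask <- matrix(FALSE, nr, nc)

  sat_values <- with_seed(truth$seed + 1L, {
    lapply(truth$vessels, function(v) {
      m <- radial_segment_mask(truth$shape, truth$od_center, v$angle_deg,
                               v$width, truth$od_radius * 0.5, r_end)
      s <- clamp(v$mean_sat + rnorm(sum(m), sd = truth$sat_jitter_sd), 0, 100)
      list(mask = m, sat = s)
    })
  })
  for (v in sat_values) {
    rgbv <- encode_saturation(v$sat)
    idx <- which(v$mask)
    img[idx] <- rgbv[, "r"]
    img[idx + nr * nc] <- rgbv[, "g"]
    img[idx + 2 * nr * nc] <- rgbv[, "b"]
    vessel_mask[idx] <- TRUE
  }

  d2 <- outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+")
  od <- d2 <= truth$od_radius^2
  for (ch in 0:2) img[which(od) + ch * nr * nc] <- as.integer(truth$od_value)
  vessel_mask[od] <- FALSE

  truth$vessel_mask <- vessel_mask
  truth$n_vessel_pixels <- sum(vessel_mask)
  list(image = img, truth = truth)
}

#' Write a scene to disk
#'
#' @param scene result of [make_oximetry_scene()].
#' @param image_path PNG path for the rendered scene.
#' @param truth_path optional JSON path for the ground truth (vessel mask is
#'   stored as a pixel count, not rasterized).
#' @return `image_path`, invisibly.
#' @export
write_scene <- function(scene, image_path, truth_path = NULL) {
  png::writePNG(scene$image / 255, image_path)
  if (!is.null(truth_path)) {
    tr <- scene$truth
    tr$vessel_mask <- NULL
    writeLines(jsonlite::toJSON(unclass(tr), auto_unbox = TRUE, digits = NA),
               truth_path)
  }
  invisible(image_path)
}
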
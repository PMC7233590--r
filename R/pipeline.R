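## End-to-end pipeline: image in, per-region oximetry report out.

#' Pipeline configuration
#'
#' @param laterality `"right"` or `"left"` eye.
#' @param channel scalar channel for disc fitting ([to_scalar_channel()]).
#' @param radii_grid candidate radii for the NCC initialization (pixels).
#' @param optimizer [optimizer_config()].
#' @param bin_width saturation histogram bin width (percent).
#' @param min_separation,min_height_frac peak admissibility settings for
#'   [fit_bimodal()].
#' @param swap_temporal flip the temporal/nasal sides (mirrored exports).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(laterality = c("right", "left"),
                            channel = "luminance",
                            radii_grid = seq(30, 90, by = 10),
                            optimizer = optimizer_config(),
                            bin_width = 1,
                            min_separation = 10,
                            min_height_frac = 0.05,
                            swap_temporal = FALSE) {
  laterality <- match.arg(laterality)
  structure(list(laterality = laterality, channel = channel,
                 radii_grid = radii_grid, optimizer = optimizer,
                 bin_width = bin_width, min_separation = min_separation,
                 min_height_frac = min_height_frac,
                 swap_temporal = swap_temporal),
            class = "pipeline_config")
}

#' Read an 8-bit RGB oximetry export
#'
#' @param path PNG or TIFF file.
#' @return integer array `[rows, cols, 3]` with values 0-255 (any alpha
#'   channel is dropped).
#' @export
read_oximetry_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (PNG or TIFF expected)", call. = FALSE)
  )
  if (length(dim(img)) == 2L) stop("grayscale image: RGB export expected", call. = FALSE)
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  array(as.integer(round(img * 255)), dim = dim(img))
}

#' Run the full oximetry analysis
#'
#' Chains [segment_optic_disc()], [build_ring_roi()],
#' [ring_and_quadrant_masks()], [decode_image()] and [analyze_regions()].
#' Stage failures are re-raised with the failing stage named in the message.
#'
#' @param image path to a PNG/TIFF export, or an integer RGB array
#'   `[rows, cols, 3]` (0-255).
#' @param config [pipeline_config()].
#' @return `oximetry_report` augmented with `fit` (the disc fit), `masks`,
#'   `satmap`, and `provenance` (input path/checksum, config hash, package
#'   version).
#' @export
run_pipeline <- function(image, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  input_path <- NA_character_
  input_md5 <- NA_character_
  if (is.character(image)) {
    input_path <- image
    input_md5 <- unname(tools::md5sum(image))
    image <- read_oximetry_image(image)
  }
  stage <- function(name, expr) {
    withCallingHandlers(expr, error = function(e) {
      if (is.null(attr(e, "oxiring_stage"))) {
        e$message <- paste0("[stage ", name, "] ", conditionMessage(e))
        attr(e, "oxiring_stage") <- name
        stop(e)
      }
    })
  }

  fit <- stage("segment_optic_disc",
               segment_optic_disc(image, config$optimizer, config$radii_grid,
                                  config$channel))
  roi <- stage("build_ring_roi", build_ring_roi(fit, config$laterality))
  masks <- stage("ring_and_quadrant_masks",
                 ring_and_quadrant_masks(roi, dim(image)[1:2], config$swap_temporal))
  satmap <- stage("decode_image", decode_image(image))
  report <- stage("analyze_regions",
                  analyze_regions(satmap, roi, masks, config$bin_width,
                                  config$min_separation, config$min_height_frac))

  report$fit <- fit
  report$masks <- masks
  report$satmap <- satmap
  report$provenance <- list(input_path = input_path,
                            input_md5 = input_md5,
                            config_hash = content_hash(unclass(config)),
                            package_version = as.character(packageVersion("oxiring")))
  report
}

#' Write an oximetry report to JSON and CSV
#'
#' @param report `oximetry_report` from [run_pipeline()] or
#'   [analyze_regions()].
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return the JSON string, invisibly.
#' @export
write_oximetry_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "oximetry_report"))
  tab <- summary(report)
  x <- list(laterality = report$laterality,
            roi = list(center = unname(report$roi$center),
                       r_inner = report$roi$r_inner,
                       r_outer = report$roi$r_outer,
                       od_radius = report$roi$od_radius,
                       pixel_scale = report$roi$pixel_scale),
            regions = lapply(split(tab, seq_len(nrow(tab))), as.list),
            provenance = report$provenance)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(json_path)) writeLines(js, json_path)
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  invisible(js)
}

#' Overlay plot of segmentation and ROI
#'
#' Draws the export with the fitted disc circles, the ring annulus and the
#' quadrant boundaries.
#'
#' @param x `oximetry_report` from [run_pipeline()].
#' @param image the RGB array the report was computed from (optional if the
#'   report holds a readable `provenance$input_path`).
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.oximetry_report <- function(x, image = NULL, ...) {
  if (is.null(image) && !is.na(x$provenance$input_path)) {
    image <- read_oximetry_image(x$provenance$input_path)
  }
  if (is.null(image)) stop("supply the source image for the overlay", call. = FALSE)
  nr <- dim(image)[1]; nc <- dim(image)[2]
  plot(NA, xlim = c(1, nc), ylim = c(nr, 1), asp = 1, xlab = "", ylab = "",
       axes = FALSE, ...)
  rasterImage(image / 255, 1, nr, nc, 1)
  cx <- x$roi$center[["x"]]; cy <- x$roi$center[["y"]]
  tt <- seq(0, 2 * pi, length.out = 361)
  for (r in c(x$roi$od_radius, x$roi$r_inner, x$roi$r_outer)) {
    lines(cx + r * cos(tt), cy + r * sin(tt), col = "white")
  }
  for (a in c(0, 90, 180, 270) * pi / 180) {
    lines(cx + c(x$roi$r_inner, x$roi$r_outer) * cos(a),
          cy - c(x$roi$r_inner, x$roi$r_outer) * sin(a), col = "white", lty = 2)
  }
  invisible(x)
}
#' @importFrom graphics rasterImage
NULL
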
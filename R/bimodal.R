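## Saturation histogram analysis.
##
## Within a region of interest the decoded saturation values form a bimodal
## distribution: the lower mode is venular blood, the higher mode arteriolar.
## The two modes are located as the two dominant local maxima of a
## least-squares polynomial of order twelve fitted to the histogram; reading
## modes rather than means makes the estimate insensitive to extreme values.

#' Histogram of decoded saturation values within a mask
#'
#' @param satmap `sat_map` from [decode_image()].
#' @param mask logical matrix of the same shape; only defined pixels inside
#'   the mask are counted.
#' @param bin_width bin width in percent; must divide 100.
#' @return object of class `sat_histogram`: `bin_edges`, `mids`, `counts`,
#'   `n_defined`. `sum(counts) == n_defined`.
#' @export
build_histogram <- function(satmap, mask, bin_width = 1) {
  stopifnot(inherits(satmap, "sat_map"), is.logical(mask))
  if (!all(dim(mask) == dim(satmap$values))) {
    stop("mask shape must match the saturation map", call. = FALSE)
  }
  if (bin_width <= 0 || abs(100 / bin_width - round(100 / bin_width)) > 1e-9) {
    stop("bin_width must divide 100", call. = FALSE)
  }
  v <- satmap$values[mask & satmap$defined]
  if (length(v) == 0L) {
    stop_oxi("oxiring_insufficient_data", "no defined saturation pixels inside the mask")
  }
  edges <- seq(0, 100, by = bin_width)
  nb <- length(edges) - 1L
  # bins [e_i, e_{i+1}), last bin closed at 100
  idx <- pmin(findInterval(v, edges), nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(bin_edges = edges,
                 mids = edges[-length(edges)] + bin_width / 2,
                 counts = counts,
                 bin_width = bin_width,
                 n_defined = length(v)),
            class = "sat_histogram")
}

#' Locate the venular and arteriolar modes of a saturation histogram
#'
#' Fits a degree-12 polynomial by least squares to all (bin center, count)
#' pairs of the histogram over its full 0-100\% axis (the abscissa is
#' affinely mapped to `[-1, 1]` and the fit uses an orthogonal-polynomial
#' basis; a raw degree-12 Vandermonde on `[0, 100]` is catastrophically
#' ill-conditioned, while the fitted curve is mathematically identical). The
#' polynomial is evaluated on a 0.1\% grid over the data support (the hull
#' of nonzero bins) and its local maxima are extracted; ripple maxima are
#' rejected by a minimum height (5\% of the
#' tallest peak) and the two tallest admissible maxima at least
#' `min_separation` apart are reported, lower abscissa as the venular mode,
#' higher as the arteriolar mode.
#'
#' @param hist `sat_histogram` from [build_histogram()].
#' @param min_separation minimum distance between the two reported peaks, in
#'   percent saturation.
#' @param min_height_frac admissibility threshold as a fraction of the
#'   tallest peak.
#' @return object of class `bimodal_fit`: `venular_sat`, `arteriolar_sat`,
#'   `avsd` (`= arteriolar - venular`), `peak_heights`, `poly_coefficients`
#'   (13 coefficients on the normalized abscissa, constant term first),
#'   `support`, `grid`, `fitted`, `quality_flags`.
#'   Raises an `oxiring_insufficient_data` error when fewer than 13 bins have
#'   nonzero counts (the fit would be under-determined) and an
#'   `oxiring_unimodal` error (carrying field `peak`) when fewer than two
#'   admissible peaks exist.
#' @export
fit_bimodal <- function(hist, min_separation = 10, min_height_frac = 0.05) {
  stopifnot(inherits(hist, "sat_histogram"))
  nz <- which(hist$counts > 0)
  if (length(nz) < 13L) {
    stop_oxi("oxiring_insufficient_data",
             sprintf("only %d nonzero histogram bins; a degree-12 fit needs at least 13",
                     length(nz)))
  }
  support <- range(hist$mids[nz])
  # fit over the full histogram axis (every bin-count pair, zeros included);
  # a fixed domain keeps the fitted curve insensitive to a few stray pixels
  # at extreme saturations, which only matter through their small counts
  dom <- range(hist$bin_edges)
  x <- hist$mids
  y <- hist$counts
  z <- 2 * (x - dom[1]) / diff(dom) - 1
  fit <- stats::lm(y ~ stats::poly(z, 12, raw = FALSE))

  # peaks are searched over the support actually covered by data
  grid <- seq(support[1], support[2], by = 0.1)
  zg <- 2 * (grid - dom[1]) / diff(dom) - 1
  yg <- as.numeric(predict(fit, newdata = data.frame(z = zg)))

  # raw coefficients on the normalized abscissa (well-conditioned on [-1, 1])
  zfull <- seq(-1, 1, length.out = 201)
  yfull <- as.numeric(predict(fit, newdata = data.frame(z = zfull)))
  raw <- stats::lm(yfull ~ stats::poly(zfull, 12, raw = TRUE))
  poly_coefficients <- unname(coef(raw))

  i_max <- which(diff(sign(diff(yg))) == -2) + 1L
  if (length(i_max) == 0L) {
    stop_oxi("oxiring_unimodal", "fitted polynomial has no interior maximum",
             peak = NA_real_)
  }
  pk_x <- grid[i_max]
  pk_h <- yg[i_max]
  admissible <- pk_h >= min_height_frac * max(pk_h)
  pk_x <- pk_x[admissible]; pk_h <- pk_h[admissible]
  ord <- order(pk_h, decreasing = TRUE)
  pk_x <- pk_x[ord]; pk_h <- pk_h[ord]

  second <- which(abs(pk_x - pk_x[1]) >= min_separation)[1]
  if (length(pk_x) < 2L || is.na(second)) {
    stop_oxi("oxiring_unimodal",
             sprintf("only one admissible peak (at %.1f%%)", pk_x[1]),
             peak = pk_x[1])
  }
  pair_x <- c(pk_x[1], pk_x[second])
  pair_h <- c(pk_h[1], pk_h[second])
  ven <- which.min(pair_x); art <- which.max(pair_x)

  structure(list(venular_sat = pair_x[ven],
                 arteriolar_sat = pair_x[art],
                 avsd = pair_x[art] - pair_x[ven],
                 peak_heights = c(venular = pair_h[ven], arteriolar = pair_h[art]),
                 poly_coefficients = poly_coefficients,
                 support = support,
                 grid = grid,
                 fitted = yg,
                 n_defined = hist$n_defined,
                 quality_flags = list(n_peaks_found = length(pk_x),
                                      separation_ok = abs(diff(pair_x)) >= min_separation)),
            class = "bimodal_fit")
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat(sprintf("Bimodal saturation fit (n = %d pixels):\n", x$n_defined))
  cat(sprintf("  venular    %6.1f %%\n  arteriolar %6.1f %%\n  AVSD       %6.1f %%\n",
              x$venular_sat, x$arteriolar_sat, x$avsd))
  invisible(x)
}

#' @export
plot.bimodal_fit <- function(x, hist = NULL, ...) {
  plot(x$grid, x$fitted, type = "l", xlab = "SatO2 (%)", ylab = "pixel count", ...)
  if (!is.null(hist)) {
    rect(hist$mids - hist$bin_width / 2, 0, hist$mids + hist$bin_width / 2,
         hist$counts, border = NA, col = "gray80")
    lines(x$grid, x$fitted)
  }
  abline(v = c(x$venular_sat, x$arteriolar_sat), lty = 2)
  invisible(x)
}

#' Per-region bimodal saturation analysis
#'
#' Runs [build_histogram()] and [fit_bimodal()] on the full ring and on each
#' anatomical quadrant. A region whose histogram is insufficient or unimodal
#' is recorded with its failure flag without aborting the other regions.
#'
#' @param satmap `sat_map` from [decode_image()].
#' @param roi [build_ring_roi()] result.
#' @param masks [ring_and_quadrant_masks()] result.
#' @param bin_width histogram bin width in percent.
#' @param min_separation,min_height_frac passed to [fit_bimodal()].
#' @return object of class `oximetry_report` with one entry per region
#'   (`ring`, `ST`, `SN`, `IN`, `IT`), each either a `bimodal_fit` or a flag
#'   string; raises `oxiring_empty_report` if every region fails.
#' @export
analyze_regions <- function(satmap, roi, masks, bin_width = 1,
                            min_separation = 10, min_height_frac = 0.05) {
  region_masks <- c(list(ring = masks$ring), masks$quadrants)
  regions <- lapply(region_masks, function(m) {
    tryCatch({
      h <- build_histogram(satmap, m, bin_width)
      fit <- fit_bimodal(h, min_separation, min_height_frac)
      fit$histogram <- h
      fit
    },
    oxiring_insufficient_data = function(e) {
      structure(list(flag = "insufficient-data", message = conditionMessage(e)),
                class = "region_failure")
    },
    oxiring_unimodal = function(e) {
      structure(list(flag = "unimodal-data", message = conditionMessage(e),
                     peak = e$peak),
                class = "region_failure")
    })
  })
  if (all(vapply(regions, inherits, logical(1), "region_failure"))) {
    stop_oxi("oxiring_empty_report", "saturation analysis failed in every region")
  }
  structure(list(regions = regions,
                 roi = roi,
                 laterality = roi$laterality,
                 bin_width = bin_width),
            class = "oximetry_report")
}

#' @export
print.oximetry_report <- function(x, ...) {
  cat(sprintf("Oximetry report (%s eye), ring %.1f - %.1f px:\n",
              x$laterality, x$roi$r_inner, x$roi$r_outer))
  cat(sprintf("  %-5s %9s %9s %9s %9s\n", "region", "n_pixels", "venular",
              "arteriolar", "AVSD"))
  for (nm in names(x$regions)) {
    r <- x$regions[[nm]]
    if (inherits(r, "region_failure")) {
      cat(sprintf("  %-5s %9s   [%s]\n", nm, "-", r$flag))
    } else {
      cat(sprintf("  %-5s %9d %9.1f %9.1f %9.1f\n", nm, r$n_defined,
                  r$venular_sat, r$arteriolar_sat, r$avsd))
    }
  }
  invisible(x)
}

#' Tabulate an oximetry report
#'
#' @param object `oximetry_report`.
#' @param ... unused.
#' @return data frame with one row per region: `region`, `n_pixels`,
#'   `venular`, `arteriolar`, `avsd`, `flag`.
#' @export
summary.oximetry_report <- function(object, ...) {
  rows <- lapply(names(object$regions), function(nm) {
    r <- object$regions[[nm]]
    if (inherits(r, "region_failure")) {
      data.frame(region = nm, n_pixels = NA_integer_, venular = NA_real_,
                 arteriolar = NA_real_, avsd = NA_real_, flag = r$flag)
    } else {
      data.frame(region = nm, n_pixels = r$n_defined, venular = r$venular_sat,
                 arteriolar = r$arteriolar_sat, avsd = r$avsd, flag = "ok")
    }
  })
  do.call(rbind, rows)
}
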
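## Pseudocolor lookup-table inversion.
##
## Oximetry exports encode per-pixel oxygen saturation as pseudocolor. The
## encoding is piecewise linear in one channel per band and is inverted by
## three published conditions (first match wins):
##   C1a: r = 255, g != 255, b = 0   ->  SatO2 = 100 - 0.1 g    (74.5, 100]
##   C1b: r != 255, g = 255, b = 0   ->  SatO2 = 50 + 0.1 r     [50, 75.5)
##   C2 : r = 0,   g != 0,  b != 0   ->  SatO2 = 25 + 0.1 g     (25, 50)
##   C3 : r != 0,  g = 0,  b != 0    ->  SatO2 = 25 - 0.2 r     [0, 25) (clamped)
## Pixels matching no condition (e.g. any gray, r = g = b) carry no
## saturation and are marked undefined. The junction triple (255, 255, 0)
## satisfies neither C1 clause; it decodes to 75, the midpoint of the two
## clause limits at the band junction.

#' Decode pseudocolor pixels to oxygen saturation
#'
#' Vectorized over equal-length channel vectors. Values are clamped to
#' `[0, 100]` (condition C3 reaches negative values for `r > 125`; the map
#' bottoms at 0\%).
#'
#' @param r,g,b integer channel values in 0-255.
#' @return numeric vector of SatO2 in percent, `NA` where the pixel matches
#'   no condition. Attributes `n_clamped` and `n_junction` count clamped
#'   condition-3 pixels and `(255, 255, 0)` junction pixels.
#' @examples
#' decode_pixel(255, 60, 0)   # 94, condition 1a
#' decode_pixel(200, 255, 0)  # 70, condition 1b
#' decode_pixel(0, 100, 255)  # 35, condition 2
#' decode_pixel(50, 0, 255)   # 15, condition 3
#' decode_pixel(128, 128, 128)  # NA, background gray
#' @export
decode_pixel <- function(r, g, b) {
  n <- length(r)
  if (length(g) != n || length(b) != n) {
    stop("r, g, b must have equal length", call. = FALSE)
  }
  ch <- c(r, g, b)
  if (any(!is.finite(ch)) || any(ch < 0) || any(ch > 255) || any(ch != round(ch))) {
    stop("channel values must be integers in 0..255", call. = FALSE)
  }
  out <- rep(NA_real_, n)
  undecided <- rep(TRUE, n)

  c1a <- undecided & r == 255 & g != 255 & b == 0
  out[c1a] <- 100 - 0.1 * g[c1a]; undecided[c1a] <- FALSE

  c1b <- undecided & r != 255 & g == 255 & b == 0
  out[c1b] <- 50 + 0.1 * r[c1b]; undecided[c1b] <- FALSE

  c2 <- undecided & r == 0 & g != 0 & b != 0
  out[c2] <- 25 + 0.1 * g[c2]; undecided[c2] <- FALSE

  c3 <- undecided & r != 0 & g == 0 & b != 0
  out[c3] <- 25 - 0.2 * r[c3]; undecided[c3] <- FALSE

  junction <- undecided & r == 255 & g == 255 & b == 0
  out[junction] <- 75

  n_clamped <- sum(out < 0 | out > 100, na.rm = TRUE)
  out <- clamp(out, 0, 100)
  structure(out, n_clamped = n_clamped, n_junction = sum(junction))
}

#' Decode a full RGB raster to a saturation map
#'
#' @param image integer array `[rows, cols, 3]` with 8-bit channels (0-255).
#' @return object of class `sat_map`: `values` (numeric matrix, `NA` where
#'   undefined), `defined` (logical matrix), `n_defined`, plus the decode
#'   counters `n_clamped`, `n_junction`.
#' @export
decode_image <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an RGB array [rows, cols, 3]", call. = FALSE)
  }
  v <- decode_pixel(as.vector(image[, , 1]), as.vector(image[, , 2]),
                    as.vector(image[, , 3]))
  values <- matrix(as.numeric(v), dim(image)[1], dim(image)[2])
  defined <- !is.na(values)
  structure(list(values = values,
                 defined = defined,
                 n_defined = sum(defined),
                 n_clamped = attr(v, "n_clamped"),
                 n_junction = attr(v, "n_junction")),
            class = "sat_map")
}

#' @export
print.sat_map <- function(x, ...) {
  cat(sprintf("Saturation map %d x %d: %d defined pixels (%.1f%%)",
              nrow(x$values), ncol(x$values), x$n_defined,
              100 * x$n_defined / length(x$values)))
  if (x$n_defined > 0) {
    cat(sprintf(", SatO2 range %.1f - %.1f%%", min(x$values, na.rm = TRUE),
                max(x$values, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' Encode oxygen saturation as a pseudocolor triple
#'
#' Piecewise right-inverse of [decode_pixel()], used by the synthetic scene
#' generator. Bands: `(74.5, 100]` -> `(255, round(10 (100 - S)), 0)`;
#' `[50, 74.5]` -> `(round(10 (S - 50)), 255, 0)`; `(25, 50)` ->
#' `(0, round(10 (S - 25)), 255)`; `[0, 25]` -> `(round(5 (25 - S)), 0, 255)`.
#' A variable channel that would round to 0 in the two blue bands is bumped
#' to 1 so every emitted triple remains decodable (both blue-band conditions
#' require that channel to be nonzero); the worst round-trip error this
#' introduces is 0.2\% at S = 25.
#'
#' Round trip: `|decode(encode(S)) - S|` is at most 0.05 away from band
#' edges, 0.1 throughout `(25, 100]`, and 0.2 in `[0, 25]` (the coarser
#' 0.2\%-per-level slope of condition 3).
#'
#' @param S numeric vector of SatO2 in percent, each in `[0, 100]`.
#' @return integer matrix with columns `r`, `g`, `b`, one row per value.
#' @export
encode_saturation <- function(S) {
  if (any(!is.finite(S)) || any(S < 0) || any(S > 100)) {
    stop("S must lie in [0, 100]", call. = FALSE)
  }
  n <- length(S)
  r <- integer(n); g <- integer(n); b <- integer(n)

  hi <- S > 74.5                 # red band, condition 1a
  r[hi] <- 255L; g[hi] <- as.integer(round(10 * (100 - S[hi]))); b[hi] <- 0L

  mid <- S >= 50 & S <= 74.5     # green band, condition 1b
  r[mid] <- as.integer(round(10 * (S[mid] - 50))); g[mid] <- 255L; b[mid] <- 0L

  lo <- S > 25 & S < 50          # cyan-blue band, condition 2
  g[lo] <- pmax(1L, as.integer(round(10 * (S[lo] - 25)))); r[lo] <- 0L; b[lo] <- 255L

  bot <- S <= 25                 # violet band, condition 3
  r[bot] <- pmax(1L, as.integer(round(5 * (25 - S[bot])))); g[bot] <- 0L; b[bot] <- 255L

  cbind(r = r, g = g, b = b)
}

#' Export a saturation map
#'
#' Writes the map either as 16-bit grayscale PNG (`value = 100 * SatO2`,
#' undefined pixels at the sentinel 65535) or as a CSV of defined pixels
#' (`row`, `col`, `sat`).
#'
#' @param satmap `sat_map` object.
#' @param path output file path.
#' @param format `"png16"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_sat_map <- function(satmap, path, format = c("png16", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(satmap, "sat_map"))
  if (format == "png16") {
    v <- satmap$values * 100
    v[!satmap$defined] <- 65535
    png::writePNG(v / 65535, path)
  } else {
    idx <- which(satmap$defined, arr.ind = TRUE)
    df <- data.frame(row = idx[, 1], col = idx[, 2],
                     sat = satmap$values[idx])
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
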
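## Active-disc optic-disc segmentation.
##
## The active disc is a pair of concentric circles (unit radii 1 and 1/sqrt(2))
## carrying three free parameters: scale R (outer radius, px) and center
## (x_c, y_c). Its energy is the normalized contrast between the annulus and
## the inner disc,
##     E = (E1 - 2 E2) / R^2,
## where E1, E2 are the image integrals over the outer and inner discs. For a
## bright disc on a dark background the energy is minimized when the inner
## circle coincides with the bright disc (closed form: E = -pi/2 at
## R = sqrt(2) * rho for a unit-contrast disc of radius rho), so the reported
## optic-disc boundary is the inner circle and the reported OD radius R/sqrt(2).

#' Construct an active disc
#'
#' @param x_c,y_c disc center in pixel coordinates (column, row; pixel centers
#'   at integers, origin top-left). Continuous values allowed.
#' @param R scale parameter: outer-circle radius in pixels. The inner circle
#'   (the reported optic-disc boundary) has radius `R / sqrt(2)`.
#' @return object of class `active_disc`.
#' @export
active_disc <- function(x_c, y_c, R) {
  stopifnot(is.numeric(x_c), is.numeric(y_c), is.numeric(R),
            length(x_c) == 1L, length(y_c) == 1L, length(R) == 1L,
            is.finite(x_c), is.finite(y_c), is.finite(R))
  if (R <= 0) stop("active disc scale R must be positive", call. = FALSE)
  structure(list(x_c = x_c, y_c = y_c, R = R), class = "active_disc")
}

#' @export
print.active_disc <- function(x, ...) {
  cat(sprintf("Active disc: center (%.2f, %.2f), scale R = %.2f (inner radius %.2f)\n",
              x$x_c, x$y_c, x$R, x$R / sqrt(2)))
  invisible(x)
}

#' Optimizer settings for the active-disc fit
#'
#' @param n_contour_samples number of uniform samples of the contour parameter
#'   t in (0, 2*pi] used to discretize the gradient line integrals (>= 64).
#' @param step_scale,step_translation gradient-descent step sizes (pixels) for
#'   the scale and translation parameters; the descent direction is the
#'   normalized gradient, so these are step lengths in parameter space.
#' @param max_iterations iteration cap for the descent.
#' @param energy_tolerance relative convergence threshold on |dE|.
#' @param R_min,R_max clamp on the scale parameter (pixels); `R_max = NULL`
#'   defaults to `min(image dims) / 4` at fit time.
#' @param energy_oversample the energy line integral is evaluated on an
#'   angular grid this many times finer than `n_contour_samples`; the sum is
#'   cheap and the finer grid makes the energy smooth enough in the
#'   parameters that finite differences of the energy reproduce the analytic
#'   contour gradients.
#' @return object of class `optimizer_config`.
#' @export
optimizer_config <- function(n_contour_samples = 720L,
                             step_scale = 0.5,
                             step_translation = 1.0,
                             max_iterations = 200L,
                             energy_tolerance = 1e-6,
                             R_min = 20,
                             R_max = NULL,
                             energy_oversample = 8L) {
  stopifnot(is_count(n_contour_samples), n_contour_samples >= 64,
            step_scale > 0, step_translation > 0,
            is_count(max_iterations), energy_tolerance > 0,
            R_min > 0, is.null(R_max) || R_max > R_min,
            is_count(energy_oversample))
  structure(list(n_contour_samples = as.integer(n_contour_samples),
                 step_scale = step_scale,
                 step_translation = step_translation,
                 max_iterations = as.integer(max_iterations),
                 energy_tolerance = energy_tolerance,
                 R_min = R_min, R_max = R_max,
                 energy_oversample = as.integer(energy_oversample)),
            class = "optimizer_config")
}

## ---- image field: exact cumulative antiderivative -------------------------

# Precompute the running x-antiderivative of the image, row by row
# (trapezoid rule, exact for the piecewise-linear row profile). Together with
# Catmull-Rom interpolation across rows this yields a C^1 cumulative field
# F(x, y) = int_1^x f(u, y) du whose exact x-derivative is the interpolated
# image itself -- the property that makes the Green's-theorem contour
# gradients consistent with finite differences of the energy.
oxi_field <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(image))) stop("image must be finite-valued", call. = FALSE)
  nc <- ncol(image)
  Tm <- t(apply(image, 1L, function(r) c(0, cumsum((r[-nc] + r[-1]) / 2))))
  structure(list(f = image, Tm = Tm, nr = nrow(image), nc = nc),
            class = "oxi_field")
}

# Catmull-Rom weights for fractional offset u in [0, 1)
cr_weights <- function(u) {
  list(-0.5 * u + u^2 - 0.5 * u^3,
       1 - 2.5 * u^2 + 1.5 * u^3,
       0.5 * u + 2 * u^2 - 1.5 * u^3,
       -0.5 * u^2 + 0.5 * u^3)
}

# Sample the cumulative field F at continuous points (exact quadratic in x
# within a cell, Catmull-Rom cubic across rows).
field_F <- function(fld, x, y) {
  f <- fld$f; Tm <- fld$Tm; nr <- fld$nr; nc <- fld$nc
  x <- clamp(x, 1, nc - 1e-9); y <- clamp(y, 1, nr - 1e-9)
  i0 <- pmin(floor(x), nc - 1L); j0 <- pmin(floor(y), nr - 1L)
  w <- x - i0; u <- y - j0
  rowF <- function(j) {
    j <- clamp(j, 1L, nr)
    Tm[cbind(j, i0)] + f[cbind(j, i0)] * w +
      (f[cbind(j, i0 + 1L)] - f[cbind(j, i0)]) * w^2 / 2
  }
  cw <- cr_weights(u)
  cw[[1]] * rowF(j0 - 1L) + cw[[2]] * rowF(j0) +
    cw[[3]] * rowF(j0 + 1L) + cw[[4]] * rowF(j0 + 2L)
}

# Sample the image as the exact x-derivative of the cumulative field
# (linear in x, Catmull-Rom in y).
field_f <- function(fld, x, y) {
  f <- fld$f; nr <- fld$nr; nc <- fld$nc
  x <- clamp(x, 1, nc - 1e-9); y <- clamp(y, 1, nr - 1e-9)
  i0 <- pmin(floor(x), nc - 1L); j0 <- pmin(floor(y), nr - 1L)
  w <- x - i0; u <- y - j0
  rowf <- function(j) {
    j <- clamp(j, 1L, nr)
    f[cbind(j, i0)] + (f[cbind(j, i0 + 1L)] - f[cbind(j, i0)]) * w
  }
  cw <- cr_weights(u)
  cw[[1]] * rowf(j0 - 1L) + cw[[2]] * rowf(j0) +
    cw[[3]] * rowf(j0 + 1L) + cw[[4]] * rowf(j0 + 2L)
}

check_disc_bounds <- function(disc, nr, nc) {
  if (disc$x_c - disc$R < 1 || disc$x_c + disc$R > nc ||
      disc$y_c - disc$R < 1 || disc$y_c + disc$R > nr) {
    stop_oxi("oxiring_out_of_bounds",
             sprintf("active disc (center %.1f, %.1f, R = %.1f) extends outside the %d x %d image",
                     disc$x_c, disc$y_c, disc$R, nr, nc))
  }
}

energy_impl <- function(fld, disc, n) {
  t <- (seq_len(n) - 0.5) * 2 * pi / n
  dt <- 2 * pi / n
  ct <- cos(t); st <- sin(t)
  R <- disc$R; r2 <- R / sqrt(2)
  E1 <- dt * sum(field_F(fld, disc$x_c + R * ct, disc$y_c + R * st) * R * ct)
  E2 <- dt * sum(field_F(fld, disc$x_c + r2 * ct, disc$y_c + r2 * st) * r2 * ct)
  structure(list(E1 = E1, E2 = E2, E = (E1 - 2 * E2) / R^2),
            class = "disc_energy")
}

gradient_impl <- function(fld, disc, n, E) {
  t <- (seq_len(n) - 0.5) * 2 * pi / n
  dt <- 2 * pi / n
  ct <- cos(t); st <- sin(t)
  R <- disc$R; r2 <- R / sqrt(2)
  f1 <- field_f(fld, disc$x_c + R * ct, disc$y_c + R * st)
  f2 <- field_f(fld, disc$x_c + r2 * ct, disc$y_c + r2 * st)
  S1 <- dt * sum(f1); S2 <- dt * sum(f2)
  c(dE_dR = (S1 - S2 - 2 * E) / R,
    dE_dxc = (dt * sum(f1 * ct) - sqrt(2) * dt * sum(f2 * ct)) / R,
    dE_dyc = (dt * sum(f1 * st) - sqrt(2) * dt * sum(f2 * st)) / R)
}

#' Active-disc contrast energy
#'
#' Evaluates `E = (E1 - 2 E2) / R^2` where `E1`, `E2` are the image integrals
#' over the outer and inner discs, computed as Green's-theorem line integrals
#' of the cumulative field around the two circles. A uniform image gives
#' `E = 0` (annulus and inner disc have equal area); a unit-contrast bright
#' disc of radius `rho` concentric with an active disc of scale
#' `R = sqrt(2) rho` gives the closed-form minimum `E = -pi / 2`.
#'
#' @param image numeric matrix (single-channel scalar field).
#' @param disc [active_disc()].
#' @param config [optimizer_config()].
#' @return list with elements `E1`, `E2`, `E` (class `disc_energy`), with
#'   `E = (E1 - 2 E2) / R^2` holding to machine precision.
#' @export
compute_energy <- function(image, disc, config = optimizer_config()) {
  fld <- if (inherits(image, "oxi_field")) image else oxi_field(image)
  check_disc_bounds(disc, fld$nr, fld$nc)
  energy_impl(fld, disc, config$n_contour_samples * config$energy_oversample)
}

#' Analytic gradient of the active-disc energy
#'
#' Contour-integral gradients obtained from Green's theorem:
#' `dE/dR = (1/R) (int f(X1, Y1) dt - int f(X2, Y2) dt - 2 E)` and
#' `dE/dx_c = (1/R) int [f(X1, Y1) - sqrt(2) f(X2, Y2)] cos t dt`
#' (`sin t` for `y_c`), discretized over `n_contour_samples` uniform angles
#' with the image sampled as the exact x-derivative of the cumulative field.
#' Each component matches a central finite difference of [compute_energy()]
#' to relative accuracy of about 1e-3 or better on smooth images.
#'
#' @inheritParams compute_energy
#' @return named numeric vector `c(dE_dR, dE_dxc, dE_dyc)`.
#' @export
compute_gradient <- function(image, disc, config = optimizer_config()) {
  fld <- if (inherits(image, "oxi_field")) image else oxi_field(image)
  check_disc_bounds(disc, fld$nr, fld$nc)
  E <- energy_impl(fld, disc, config$n_contour_samples * config$energy_oversample)$E
  gradient_impl(fld, disc, config$n_contour_samples, E)
}

## ---- gradient descent -----------------------------------------------------

#' Fit an active disc by gradient descent
#'
#' Minimizes the contrast energy over `(R, x_c, y_c)` starting from `init`.
#' Steps follow the normalized analytic gradient with separate step lengths
#' for scale and translation; a step that would increase the energy is halved
#' (up to 30 times) so the accepted energy sequence is non-increasing.
#' Terminates when the relative energy change falls below
#' `config$energy_tolerance` or after `config$max_iterations`. A fit whose
#' scale sticks to the clamp for more than 10 consecutive iterations is
#' returned flagged `converged = FALSE` rather than raising an error.
#'
#' @param image numeric matrix (single-channel scalar field).
#' @param init [active_disc()] starting point (e.g. from [ncc_initialize()]).
#' @param config [optimizer_config()].
#' @return object of class `disc_fit`: `disc` (final [active_disc()]),
#'   `od_radius` (`= disc$R / sqrt(2)`, the reported optic-disc radius),
#'   `energy` (final), `energy_trace` (accepted energies, non-increasing),
#'   `n_iterations`, `converged`, `init`.
#' @export
fit_active_disc <- function(image, init, config = optimizer_config()) {
  fld <- if (inherits(image, "oxi_field")) image else oxi_field(image)
  stopifnot(inherits(init, "active_disc"), inherits(config, "optimizer_config"))
  nr <- fld$nr; nc <- fld$nc
  R_max <- if (is.null(config$R_max)) min(nr, nc) / 4 else config$R_max
  R_min <- config$R_min
  ne <- config$n_contour_samples * config$energy_oversample

  clamp_params <- function(R, xc, yc) {
    R <- clamp(R, R_min, R_max)
    list(R = R,
         xc = clamp(xc, R + 2, nc - R - 1),
         yc = clamp(yc, R + 2, nr - R - 1))
  }

  p <- clamp_params(init$R, init$x_c, init$y_c)
  disc <- active_disc(p$xc, p$yc, p$R)
  E <- energy_impl(fld, disc, ne)$E
  trace <- E
  at_clamp <- 0L
  converged <- FALSE
  it <- 0L

  while (it < config$max_iterations) {
    it <- it + 1L
    g <- gradient_impl(fld, disc, config$n_contour_samples, E)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-14) { converged <- TRUE; break }
    sR <- config$step_scale
    sT <- config$step_translation
    accepted <- FALSE
    for (halving in seq_len(30L)) {
      p <- clamp_params(disc$R - sR * g[["dE_dR"]] / gn,
                        disc$x_c - sT * g[["dE_dxc"]] / gn,
                        disc$y_c - sT * g[["dE_dyc"]] / gn)
      cand <- active_disc(p$xc, p$yc, p$R)
      E_new <- energy_impl(fld, cand, ne)$E
      if (E_new <= E) { accepted <- TRUE; break }
      sR <- sR / 2; sT <- sT / 2
    }
    if (!accepted) { converged <- TRUE; break }
    dE <- abs(E_new - E)
    at_clamp <- if (p$R <= R_min || p$R >= R_max) at_clamp + 1L else 0L
    disc <- cand
    E <- E_new
    trace <- c(trace, E)
    if (dE < config$energy_tolerance * max(abs(E), 1e-12)) { converged <- TRUE; break }
    if (at_clamp > 10L) { converged <- FALSE; break }
  }
  if (at_clamp > 10L) converged <- FALSE
  # a scale pinned to the clamp is not an interior optimum
  if (disc$R <= R_min + 1e-9 || disc$R >= R_max - 1e-9) converged <- FALSE

  structure(list(disc = disc,
                 od_radius = disc$R / sqrt(2),
                 energy = E,
                 energy_trace = trace,
                 n_iterations = it,
                 converged = converged,
                 init = init),
            class = "disc_fit")
}

#' @export
print.disc_fit <- function(x, ...) {
  cat(sprintf("Active-disc fit: center (%.2f, %.2f), OD radius %.2f px (scale R = %.2f)\n",
              x$disc$x_c, x$disc$y_c, x$od_radius, x$disc$R))
  cat(sprintf("  energy %.5f after %d iterations (%s)\n", x$energy, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.disc_fit <- function(object, ...) {
  c(x_c = object$disc$x_c, y_c = object$disc$y_c,
    R = object$disc$R, od_radius = object$od_radius)
}

#' @export
plot.disc_fit <- function(x, image = NULL, ...) {
  if (!is.null(image)) {
    img <- to_scalar_channel(image)
    image(t(img)[, nrow(img):1], col = gray(seq(0, 1, length.out = 256)),
          axes = FALSE, asp = nrow(img) / ncol(img), ...)
    nr <- nrow(img); nc <- ncol(img)
    tt <- seq(0, 2 * pi, length.out = 181)
    for (r in c(x$od_radius, x$disc$R)) {
      lines((x$disc$x_c + r * cos(tt) - 1) / (nc - 1),
            1 - (x$disc$y_c + r * sin(tt) - 1) / (nr - 1))
    }
    points((x$disc$x_c - 1) / (nc - 1), 1 - (x$disc$y_c - 1) / (nr - 1), pch = 3)
  } else {
    plot(seq_along(x$energy_trace) - 1, x$energy_trace, type = "b",
         xlab = "iteration", ylab = "energy", ...)
  }
  invisible(x)
}

## ---- NCC initialization ---------------------------------------------------

# 2-D cross-correlation of `image` with (zero-mean) kernel, evaluated at all
# template positions fully inside the image; FFT-based (Lewis running-sum
# normalization is applied by the caller). Returns the valid-region matrix.
xcorr_valid <- function(image, kernel) {
  nr <- nrow(image); nc <- ncol(image)
  s <- nrow(kernel)
  P <- nr + s - 1L; Q <- nc + s - 1L
  A <- matrix(0, P, Q); A[seq_len(nr), seq_len(nc)] <- image
  B <- matrix(0, P, Q)
  B[seq_len(s), seq_len(s)] <- kernel[s:1, s:1]   # flip -> correlation
  conv <- Re(fft(fft(A) * fft(B), inverse = TRUE)) / (P * Q)
  conv[s:nr, s:nc, drop = FALSE]                  # valid part: (nr-s+1) x (nc-s+1)
}

# Windowed sums over an s x s box via integral images.
box_sums <- function(image, s) {
  nr <- nrow(image); nc <- ncol(image)
  ii <- rbind(0, apply(rbind(image), 2, cumsum))
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  r0 <- seq_len(nr - s + 1L); c0 <- seq_len(nc - s + 1L)
  ii[r0 + s, c0 + s, drop = FALSE] - ii[r0, c0 + s, drop = FALSE] -
    ii[r0 + s, c0, drop = FALSE] + ii[r0, c0, drop = FALSE]
}

#' Automatic initialization by normalized cross-correlation
#'
#' Matches a bright-disc-on-dark-surround circular template against the image
#' at every valid integer position, for each candidate radius in
#' `radii_grid`, and returns the best match as an [active_disc()] whose inner
#' circle has the winning template radius (`R = radius * sqrt(2)`).
#'
#' @param image numeric matrix (single-channel scalar field).
#' @param radii_grid candidate template radii in pixels (defaults to
#'   30-90 px in steps of 10, the optic-disc range at the 9 um/px export
#'   scale); each must be below `min(dim(image)) / 4`.
#' @return [active_disc()] at the best-matching position and scale, with
#'   attribute `ncc` (the winning correlation value) and `ncc_radius`.
#' @export
ncc_initialize <- function(image, radii_grid = seq(30, 90, by = 10)) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (length(radii_grid) == 0L) {
    stop("radii_grid must be non-empty", call. = FALSE)
  }
  nr <- nrow(image); nc <- ncol(image)
  if (any(radii_grid >= min(nr, nc) / 4)) {
    stop("all radii in radii_grid must be < min(image dims) / 4", call. = FALSE)
  }
  if (stats::sd(image) < 1e-12) {
    stop_oxi("oxiring_degenerate_ncc",
             "image has zero variance; normalized cross-correlation is undefined")
  }

  best <- list(ncc = -Inf)
  sumsq1 <- NULL
  for (r in radii_grid) {
    half <- ceiling(1.25 * r)
    s <- 2L * half + 1L
    if (s > nr || s > nc) {
      stop("image smaller than the template for radius ", r, call. = FALSE)
    }
    ix <- seq_len(s) - half - 1L
    tmpl <- (outer(ix^2, ix^2, "+") <= r^2) * 1
    tz <- tmpl - mean(tmpl)
    t_ss <- sum(tz^2)

    cross <- xcorr_valid(image, tz)
    sums <- box_sums(image, s)
    ssq <- box_sums(image^2, s)
    varw <- pmax(ssq - sums^2 / (s * s), 0)
    denom <- sqrt(varw * t_ss)
    ncc <- ifelse(denom > 1e-8 * s, cross / denom, -Inf)

    if (all(!is.finite(ncc))) next
    k <- which.max(ncc)
    ij <- arrayInd(k, dim(ncc))
    val <- ncc[k]
    if (val > best$ncc) {
      best <- list(ncc = val,
                   y = ij[1] + half,   # valid-region offset -> image coords
                   x = ij[2] + half,
                   r = r)
    }
  }
  if (!is.finite(best$ncc)) {
    stop_oxi("oxiring_degenerate_ncc",
             "normalized cross-correlation degenerate at every position")
  }
  out <- active_disc(best$x, best$y, best$r * sqrt(2))
  attr(out, "ncc") <- best$ncc
  attr(out, "ncc_radius") <- best$r
  out
}

#' Segment the optic disc in an RGB oximetry export
#'
#' Converts the RGB raster to a scalar channel, localizes the disc by
#' normalized cross-correlation and refines it by active-disc gradient
#' descent.
#'
#' @param image numeric array `[rows, cols, 3]` (0-255 or 0-1) or a matrix
#'   already reduced to one channel.
#' @param config [optimizer_config()].
#' @param radii_grid candidate radii for [ncc_initialize()].
#' @param channel scalar channel used for fitting; see [to_scalar_channel()].
#' @return [fit_active_disc()] result (class `disc_fit`).
#' @export
segment_optic_disc <- function(image, config = optimizer_config(),
                               radii_grid = seq(30, 90, by = 10),
                               channel = "luminance") {
  f <- to_scalar_channel(image, channel)
  radii_grid <- radii_grid[radii_grid < min(dim(f)) / 4]
  if (length(radii_grid) == 0L) {
    stop("no candidate radius below min(image dims) / 4", call. = FALSE)
  }
  init <- tryCatch(
    ncc_initialize(f, radii_grid),
    oxiring_degenerate_ncc = function(e) {
      stop_oxi("oxiring_degenerate_ncc", paste0("ncc_initialize: ", conditionMessage(e)))
    }
  )
  fit_active_disc(f, init, config)
}

#' Serialize a disc fit to JSON
#'
#' @param fit `disc_fit` object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
disc_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "disc_fit"))
  x <- list(center = c(fit$disc$x_c, fit$disc$y_c),
            R = fit$disc$R,
            od_radius = fit$od_radius,
            converged = fit$converged,
            n_iterations = fit$n_iterations,
            final_energy = fit$energy)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
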
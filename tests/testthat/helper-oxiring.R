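## Test helpers: independent oracles and fixture builders. These deliberately
## avoid the package's own numerical paths (interpolated cumulative fields,
## FFT correlation) so that agreement between the two routes is informative.

# smooth random test image via separable Gaussian convolution (reflection
# padding), independent of EBImage and of the package field machinery
smooth_image <- function(n = 128, blur = 3, seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(n * n), n, n)
  k <- dnorm(seq(-ceiling(4 * blur), ceiling(4 * blur)), sd = blur)
  k <- k / sum(k)
  pad <- (length(k) - 1) / 2
  conv1 <- function(v) {
    vp <- c(rev(v[seq_len(pad) + 1]), v, rev(v[length(v) - seq_len(pad)]))
    stats::filter(vp, k, sides = 2)[(pad + 1):(pad + length(v))]
  }
  t(apply(apply(f, 2, conv1), 1, conv1))
}

# brute-force pixel-membership region sums (the quadrature oracle)
pixel_sum_energy <- function(f, disc) {
  d2 <- outer((seq_len(nrow(f)) - disc$y_c)^2,
              (seq_len(ncol(f)) - disc$x_c)^2, "+")
  E1 <- sum(f[d2 <= disc$R^2])
  E2 <- sum(f[d2 <= disc$R^2 / 2])
  list(E1 = E1, E2 = E2, E = (E1 - 2 * E2) / disc$R^2)
}

# central finite differences of compute_energy (the gradient oracle)
fd_gradient <- function(f, disc, config = optimizer_config(), h = 1e-3) {
  E <- function(R, x, y) compute_energy(f, active_disc(x, y, R), config)$E
  c(dE_dR = (E(disc$R + h, disc$x_c, disc$y_c) - E(disc$R - h, disc$x_c, disc$y_c)) / (2 * h),
    dE_dxc = (E(disc$R, disc$x_c + h, disc$y_c) - E(disc$R, disc$x_c - h, disc$y_c)) / (2 * h),
    dE_dyc = (E(disc$R, disc$x_c, disc$y_c + h) - E(disc$R, disc$x_c, disc$y_c - h)) / (2 * h))
}

# exhaustive normalized cross-correlation oracle (direct sums, small images)
brute_ncc <- function(image, radii) {
  best <- list(ncc = -Inf)
  nr <- nrow(image); nc <- ncol(image)
  for (r in radii) {
    half <- ceiling(1.25 * r)
    s <- 2 * half + 1
    ix <- seq_len(s) - half - 1
    tmpl <- (outer(ix^2, ix^2, "+") <= r^2) * 1
    tz <- tmpl - mean(tmpl)
    t_ss <- sum(tz^2)
    for (y in (half + 1):(nr - half)) {
      for (x in (half + 1):(nc - half)) {
        patch <- image[(y - half):(y + half), (x - half):(x + half)]
        denom <- sqrt(sum((patch - mean(patch))^2) * t_ss)
        if (denom < 1e-8 * s) next
        val <- sum(patch * tz) / denom
        if (val > best$ncc) best <- list(ncc = val, x = x, y = y, r = r)
      }
    }
  }
  best
}

# sat_map wrapping a plain vector of saturation values (single-row image)
make_satmap <- function(values) {
  v <- matrix(as.numeric(values), nrow = 1)
  structure(list(values = v, defined = !is.na(v), n_defined = sum(!is.na(v)),
                 n_clamped = 0L, n_junction = 0L),
            class = "sat_map")
}

full_mask <- function(satmap) matrix(TRUE, nrow(satmap$values), ncol(satmap$values))

# two-population saturation histogram from seeded Gaussian draws
two_gauss_hist <- function(m1 = 57.9, m2 = 92.2, sd = 2, n = 5000,
                           seed = 1, bin_width = 1) {
  set.seed(seed)
  v <- pmin(pmax(c(rnorm(n, m1, sd), rnorm(n, m2, sd)), 0), 100)
  build_histogram(make_satmap(v), matrix(TRUE, 1, 2 * n), bin_width)
}

# minimal converged disc-fit stub for ROI geometry tests
fake_fit <- function(x_c, y_c, od_radius, converged = TRUE) {
  structure(list(disc = active_disc(x_c, y_c, max(od_radius, 1e-6) * sqrt(2)),
                 od_radius = od_radius, energy = -1, energy_trace = -1,
                 n_iterations = 1L, converged = converged,
                 init = active_disc(x_c, y_c, max(od_radius, 1e-6) * sqrt(2))),
            class = "disc_fit")
}
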
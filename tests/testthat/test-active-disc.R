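test_that("energy satisfies the normalized-contrast identity and vanishes on uniform images", {
  f <- smooth_image(96, blur = 2, seed = 11)
  set.seed(5)
  for (i in 1:5) {
    disc <- active_disc(runif(1, 40, 56), runif(1, 40, 56), runif(1, 22, 30))
    e <- compute_energy(f, disc)
    expect_equal(e$E * disc$R^2, e$E1 - 2 * e$E2, tolerance = 1e-12)
  }
  u <- matrix(3.7, 80, 80)
  disc <- active_disc(40, 40, 25)
  expect_equal(compute_energy(u, disc)$E, 0, tolerance = 1e-10)
  g <- compute_gradient(u, disc)
  expect_true(all(abs(g) < 1e-10))
})

test_that("a disc outside the frame is rejected", {
  f <- matrix(0, 64, 64)
  expect_error(compute_energy(f, active_disc(10, 32, 20)),
               class = "oxiring_out_of_bounds")
  expect_error(compute_gradient(f, active_disc(32, 60, 20)),
               class = "oxiring_out_of_bounds")
})

test_that("energy attains the closed-form minimum -pi/2 on a unit-contrast disc", {
  rho <- 120
  f <- make_disc_image(c(400, 400), c(200.5, 200.5), rho)
  Rs <- seq(1.3 * rho, 1.55 * rho, by = 0.25)
  Es <- vapply(Rs, function(R) {
    compute_energy(f, active_disc(200.5, 200.5, R))$E
  }, numeric(1))
  expect_lt(abs(min(Es) + pi / 2), 1e-2)
  expect_lt(abs(Rs[which.min(Es)] - sqrt(2) * rho), 1)
})

test_that("line-integral energy agrees with brute-force pixel-membership sums", {
  for (seed in 1:5) {
    set.seed(seed)
    f <- matrix(runif(48 * 48), 48, 48)
    disc <- active_disc(runif(1, 22, 26), runif(1, 22, 26), runif(1, 10, 14))
    e <- compute_energy(f, disc)
    p <- pixel_sum_energy(f, disc)
    tol_area <- 1e-2 * max(abs(f)) * pi * disc$R^2
    expect_lt(abs(e$E1 - p$E1), tol_area)
    expect_lt(abs(e$E2 - p$E2), tol_area / 2)
    expect_lt(abs(e$E - p$E), 1e-2 * pi * max(abs(f)))
  }
})

test_that("analytic gradient matches central finite differences on smooth images", {
  for (seed in 1:5) {
    f <- smooth_image(128, blur = 3, seed = seed)
    set.seed(100 + seed)
    disc <- active_disc(runif(1, 55, 75), runif(1, 55, 75), runif(1, 25, 35))
    g <- compute_gradient(f, disc)
    fd <- fd_gradient(f, disc)
    expect_lt(sqrt(sum((g - fd)^2)) / sqrt(sum(fd^2)), 1e-3)
  }
})

test_that("translation gradient vanishes for a concentric symmetric disc", {
  f <- make_disc_image(c(257, 257), c(129, 129), 40, blur_sd = 2)
  g <- compute_gradient(f, active_disc(129, 129, sqrt(2) * 40))
  expect_lt(abs(g[["dE_dxc"]]), 1e-6)
  expect_lt(abs(g[["dE_dyc"]]), 1e-6)
})

test_that("NCC initialization finds an ideal disc at the matching radius", {
  f <- make_disc_image(c(256, 256), c(140, 120), 40)
  init <- ncc_initialize(f, c(30, 40, 50))
  expect_equal(attr(init, "ncc_radius"), 40)
  expect_lt(abs(init$x_c - 140), 1)
  expect_lt(abs(init$y_c - 120), 1)
  expect_equal(init$R, 40 * sqrt(2))
})

test_that("NCC on a uniform image is a flagged degenerate error", {
  expect_error(ncc_initialize(matrix(2, 128, 128), c(20, 30)),
               class = "oxiring_degenerate_ncc")
  expect_error(ncc_initialize(matrix(0, 128, 128), numeric(0)), "non-empty")
  expect_error(ncc_initialize(matrix(rnorm(64^2), 64, 64), c(20)),
               "min\\(image dims\\)")
})

test_that("NCC matches the exhaustive correlation oracle on a noisy disc", {
  f <- make_disc_image(c(96, 96), c(50, 46), 18, contrast = 1,
                       noise_sd = 0.1, seed = 9)
  init <- ncc_initialize(f, c(16, 20))
  oracle <- brute_ncc(f, c(16, 20))
  expect_equal(init$x_c, oracle$x, tolerance = 1e-9)
  expect_equal(init$y_c, oracle$y, tolerance = 1e-9)
  expect_equal(attr(init, "ncc_radius"), oracle$r)
  expect_equal(attr(init, "ncc"), oracle$ncc, tolerance = 1e-6)
  expect_true(attr(init, "ncc_radius") %in% c(16, 20))
  expect_lt(abs(init$x_c - 50), 3)
  expect_lt(abs(init$y_c - 46), 3)
})

test_that("gradient descent recovers an ideal disc from a perturbed start", {
  f <- make_disc_image(c(256, 256), c(120.3, 132.8), 40)
  init <- active_disc(125.3, 137.8, sqrt(2) * 44)
  fit <- fit_active_disc(f, init)
  expect_true(fit$converged)
  expect_lt(abs(fit$disc$x_c - 120.3), 1)
  expect_lt(abs(fit$disc$y_c - 132.8), 1)
  expect_lt(abs(fit$od_radius - 40) / 40, 0.02)
  expect_true(all(diff(fit$energy_trace) <= 1e-12))
})

test_that("an already-optimal start terminates immediately without moving", {
  f <- make_disc_image(c(256, 256), c(128, 128), 40)
  opt <- fit_active_disc(f, active_disc(128, 128, sqrt(2) * 40))
  refit <- fit_active_disc(f, opt$disc)
  expect_true(refit$converged)
  expect_lte(refit$n_iterations, 2)
  expect_lt(abs(refit$disc$x_c - opt$disc$x_c), 0.5)
  expect_lt(abs(refit$disc$y_c - opt$disc$y_c), 0.5)
  expect_lt(abs(refit$disc$R - opt$disc$R) / opt$disc$R, 0.01)
})

test_that("fitted center is equivariant under integer image translation", {
  f <- make_disc_image(c(256, 256), c(110, 118), 35, blur_sd = 2,
                       noise_sd = 0.05, seed = 4)
  g <- matrix(0, 256, 256)
  g[(1:249) + 7, (1:251) + 5] <- f[1:249, 1:251]   # shift by (dx = 5, dy = 7)
  fit_f <- fit_active_disc(f, active_disc(113, 121, sqrt(2) * 38))
  fit_g <- fit_active_disc(g, active_disc(118, 128, sqrt(2) * 38))
  expect_lt(abs(fit_g$disc$x_c - fit_f$disc$x_c - 5), 0.5)
  expect_lt(abs(fit_g$disc$y_c - fit_f$disc$y_c - 7), 0.5)
})

test_that("fit is stable under contour discretization refinement", {
  sc <- make_oximetry_scene(scene_ground_truth(seed = 2))
  lum <- to_scalar_channel(sc$image)
  init <- ncc_initialize(lum, seq(40, 80, 10))
  f180 <- fit_active_disc(lum, init, optimizer_config(n_contour_samples = 180))
  f720 <- fit_active_disc(lum, init, optimizer_config(n_contour_samples = 720))
  expect_lt(sqrt((f180$disc$x_c - f720$disc$x_c)^2 +
                 (f180$disc$y_c - f720$disc$y_c)^2), 0.5)
})

test_that("a scale driven into the clamp is flagged non-converged", {
  # brightness grows with radius, so shrinking R always lowers the energy:
  # the scale runs into R_min and the fit must be flagged, not error out
  f <- outer((1:256 - 128)^2, (1:256 - 128)^2, "+") / 128^2
  fit <- fit_active_disc(f, active_disc(128, 128, 45))
  expect_false(fit$converged)
  expect_lt(fit$disc$R, 20 + 1e-6)
})

test_that("segment_optic_disc composes NCC and descent on an RGB scene", {
  sc <- make_oximetry_scene(scene_ground_truth(seed = 5))
  fit <- segment_optic_disc(sc$image)
  expect_true(fit$converged)
  expect_lt(abs(fit$od_radius - sc$truth$od_radius) / sc$truth$od_radius, 0.05)
  expect_lt(sqrt((fit$disc$x_c - sc$truth$od_center[1])^2 +
                 (fit$disc$y_c - sc$truth$od_center[2])^2), 2)
  expect_error(segment_optic_disc(array(100L, dim = c(256, 256, 3))),
               class = "oxiring_degenerate_ncc")
})
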
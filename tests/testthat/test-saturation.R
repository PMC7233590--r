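test_that("histogram counts pixels into the right bins and conserves totals", {
  sm <- make_satmap(c(rep(58.0, 500), rep(92.0, 300)))
  h <- build_histogram(sm, full_mask(sm), bin_width = 1)
  expect_equal(sum(h$counts), 800)
  expect_equal(h$n_defined, 800)
  expect_equal(h$counts[h$mids == 58.5], 500)   # [58, 59)
  expect_equal(h$counts[h$mids == 92.5], 300)
  expect_equal(sum(h$counts > 0), 2)
  # range endpoints land in the first and last bin
  h2 <- build_histogram(make_satmap(c(0, 100)), matrix(TRUE, 1, 2), 1)
  expect_equal(h2$counts[1], 1)
  expect_equal(h2$counts[100], 1)
})

test_that("empty masks and invalid bin widths are rejected", {
  sm <- make_satmap(c(50, NA, 60))
  mask <- matrix(c(FALSE, TRUE, FALSE), 1)
  expect_error(build_histogram(sm, mask, 1), class = "oxiring_insufficient_data")
  expect_error(build_histogram(sm, full_mask(sm), 3), "divide")
  expect_error(build_histogram(sm, matrix(TRUE, 2, 2), 1), "shape")
})

test_that("degree-12 polynomial fit recovers two Gaussian modes", {
  h <- two_gauss_hist(57.9, 92.2, sd = 2, n = 5000, seed = 3)
  fit <- fit_bimodal(h)
  expect_lt(abs(fit$venular_sat - 57.9), 1.5)
  expect_lt(abs(fit$arteriolar_sat - 92.2), 1.5)
  expect_lt(abs(fit$avsd - 34.3), 2)
  expect_equal(fit$avsd, fit$arteriolar_sat - fit$venular_sat)
  expect_gt(fit$arteriolar_sat, fit$venular_sat)
  expect_length(fit$poly_coefficients, 13)
  expect_true(fit$quality_flags$separation_ok)
})

test_that("unimodal data raise a flagged error carrying the single peak", {
  set.seed(8)
  v <- pmin(pmax(rnorm(8000, 60, 4), 0), 100)
  sm <- make_satmap(v)
  h <- build_histogram(sm, full_mask(sm), 1)
  err <- tryCatch(fit_bimodal(h), oxiring_unimodal = function(e) e)
  expect_s3_class(err, "oxiring_unimodal")
  expect_lt(abs(err$peak - 60), 3)
})

test_that("an under-determined histogram raises insufficient-data", {
  sm <- make_satmap(rep(c(40, 41, 42, 80, 81), each = 50))
  h <- build_histogram(sm, full_mask(sm), 1)
  expect_error(fit_bimodal(h), class = "oxiring_insufficient_data")
})

test_that("symmetric equal-mass modes are located symmetrically and order-free", {
  set.seed(21)
  a <- pmin(pmax(rnorm(4000, 40, 2), 0), 100)
  b <- pmin(pmax(rnorm(4000, 80, 2), 0), 100)
  fit_ab <- fit_bimodal(build_histogram(make_satmap(c(a, b)),
                                        matrix(TRUE, 1, 8000), 1))
  fit_ba <- fit_bimodal(build_histogram(make_satmap(c(b, a)),
                                        matrix(TRUE, 1, 8000), 1))
  expect_lt(abs(fit_ab$venular_sat - 40), 1.5)
  expect_lt(abs(fit_ab$arteriolar_sat - 80), 1.5)
  expect_equal(fit_ab$venular_sat, fit_ba$venular_sat)
  expect_equal(fit_ab$arteriolar_sat, fit_ba$arteriolar_sat)
})

test_that("mode estimates resist a 1% contamination at an extreme saturation", {
  set.seed(13)
  base <- pmin(pmax(c(rnorm(5000, 57.9, 2), rnorm(5000, 92.2, 2)), 0), 100)
  contaminated <- c(base, rep(5, 100))
  f0 <- fit_bimodal(build_histogram(make_satmap(base),
                                    matrix(TRUE, 1, length(base)), 1))
  f1 <- fit_bimodal(build_histogram(make_satmap(contaminated),
                                    matrix(TRUE, 1, length(contaminated)), 1))
  expect_lt(abs(f1$venular_sat - f0$venular_sat), 0.5)
  expect_lt(abs(f1$arteriolar_sat - f0$arteriolar_sat), 0.5)
})

test_that("peak locations are stable across histogram bin widths", {
  h1 <- two_gauss_hist(57.9, 92.2, sd = 2, n = 5000, seed = 7, bin_width = 1)
  h05 <- two_gauss_hist(57.9, 92.2, sd = 2, n = 5000, seed = 7, bin_width = 0.5)
  f1 <- fit_bimodal(h1)
  f05 <- fit_bimodal(h05)
  expect_lt(abs(f1$venular_sat - f05$venular_sat), 0.5)
  expect_lt(abs(f1$arteriolar_sat - f05$arteriolar_sat), 0.5)
})

test_that("analyze_regions reports all five regions on the default scene", {
  sc <- make_oximetry_scene(scene_ground_truth(seed = 1))
  fit <- segment_optic_disc(sc$image)
  roi <- build_ring_roi(fit, "right")
  masks <- ring_and_quadrant_masks(roi, dim(sc$image)[1:2])
  sm <- decode_image(sc$image)
  rep <- analyze_regions(sm, roi, masks)
  expect_named(rep$regions, c("ring", "ST", "SN", "IN", "IT"))
  tab <- summary(rep)
  expect_true(all(tab$flag == "ok"))
  expect_true(all(abs(tab$venular - 57.9) < 2))
  expect_true(all(abs(tab$arteriolar - 92.2) < 2))
  # quadrant estimates stay close to the full-ring estimate
  ring_row <- tab[tab$region == "ring", ]
  expect_true(all(abs(tab$venular - ring_row$venular) < 3))
  expect_true(all(abs(tab$arteriolar - ring_row$arteriolar) < 3))
  # count conservation per region
  for (nm in names(rep$regions)) {
    m <- if (nm == "ring") masks$ring else masks$quadrants[[nm]]
    expect_equal(rep$regions[[nm]]$n_defined, sum(sm$defined & m))
  }
})

test_that("regions without vessels are flagged while the others succeed", {
  truth <- scene_ground_truth(seed = 6)
  # move every vessel into the superior half (angles in (5, 175) degrees)
  sup_angles <- c(20, 70, 110, 160, 35, 55, 125, 145)
  for (i in seq_along(truth$vessels)) {
    truth$vessels[[i]]$angle_deg <- sup_angles[(i - 1) %% 8 + 1]
  }
  sc <- make_oximetry_scene(truth)
  fit <- segment_optic_disc(sc$image)
  roi <- build_ring_roi(fit, "right")
  masks <- ring_and_quadrant_masks(roi, dim(sc$image)[1:2])
  rep <- analyze_regions(decode_image(sc$image), roi, masks)
  tab <- summary(rep)
  expect_equal(tab$flag[tab$region %in% c("IN", "IT")],
               c("insufficient-data", "insufficient-data"))
  expect_equal(tab$flag[tab$region == "ring"], "ok")
})
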
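test_that("identical readings give perfect agreement and collapsed limits", {
  pr <- paired_readings(1:3, c(90, 80, 70), c(90, 80, 70))
  r <- icc(pr)
  expect_equal(r$icc_single, 1)
  expect_equal(r$icc_average, 1)
  expect_warning(ba <- bland_altman(pr), "collapse")
  expect_equal(ba$bias, 0)
  expect_equal(unname(ba$loa), c(0, 0))
  expect_true(ba$collapsed)
})

test_that("ICC is centred at zero under the permutation null", {
  set.seed(101)
  vals <- rnorm(40, 70, 5)
  iccs <- replicate(200, {
    icc(paired_readings(1:40, vals, sample(vals)))$icc_single
  })
  expect_lt(abs(mean(iccs)), 0.1)
})

test_that("ICC matches the closed-form variance ratio on simulated raters", {
  # subjects ~ N(0, 5^2), two raters add N(0, 2^2): ICC = 25 / 29
  set.seed(202)
  iccs <- replicate(500, {
    truth <- rnorm(44, 70, 5)
    pr <- paired_readings(1:44, truth + rnorm(44, 0, 2), truth + rnorm(44, 0, 2))
    icc(pr)$icc_single
  })
  expect_lt(abs(mean(iccs) - 25 / 29), 0.015)
})

test_that("average-measure ICC dominates single-measure ICC and CIs bracket it", {
  set.seed(7)
  truth <- rnorm(30, 60, 4)
  pr <- paired_readings(1:30, truth + rnorm(30), truth + rnorm(30))
  r <- icc(pr)
  expect_gte(r$icc_average, r$icc_single)
  expect_lt(r$ci_single[["lower"]], r$icc_single)
  expect_gt(r$ci_single[["upper"]], r$icc_single)
  expect_lt(r$ci_average[["lower"]], r$icc_average)
  expect_gt(r$ci_average[["upper"]], r$icc_average)
  # Spearman-Brown relation between the two forms' intervals
  k <- 2
  sb <- function(x) k * x / (1 + (k - 1) * x)
  expect_equal(unname(r$ci_average), unname(sb(r$ci_single)))
})

test_that("zero between-subject variance is flagged degenerate", {
  pr <- paired_readings(1:5, rep(60, 5), rep(62, 5))
  expect_true(icc(pr)$degenerate)
})

test_that("Bland-Altman limits reproduce the sampling distribution and the arithmetic oracle", {
  set.seed(55)
  d <- rnorm(1e4, 2, 1)
  base <- rnorm(1e4, 70, 5)
  pr <- paired_readings(seq_len(1e4), base + d, base)
  ba <- bland_altman(pr)
  expect_lt(abs(ba$bias - 2), 0.05)
  expect_lt(abs(ba$loa[["lower"]] - 0.04), 0.1)
  expect_lt(abs(ba$loa[["upper"]] - 3.96), 0.1)
  # exact arithmetic oracle on any dataset
  expect_equal(ba$bias, mean(d))
  expect_equal(unname(ba$loa), mean(d) + c(-1.96, 1.96) * sd(d))
  expect_equal(ba$n_outside_loa, sum(abs(d - mean(d)) > 1.96 * sd(d)))
})

test_that("swapping rater columns negates the Bland-Altman analysis", {
  set.seed(9)
  m <- rnorm(20, 80, 4); a <- m + rnorm(20, 1, 2)
  b1 <- bland_altman(paired_readings(1:20, m, a))
  b2 <- bland_altman(paired_readings(1:20, a, m))
  expect_equal(b1$bias, -b2$bias)
  expect_equal(unname(b1$loa), -rev(unname(b2$loa)))
  expect_equal(b1$n_outside_loa, b2$n_outside_loa)
})

test_that("the fraction outside the limits matches the expected coverage", {
  set.seed(77)
  frac <- replicate(50, {
    base <- rnorm(44, 70, 5)
    ba <- bland_altman(paired_readings(1:44, base + rnorm(44, 0, 2), base))
    ba$n_outside_loa / ba$n
  })
  expect_true(all(frac >= 0 & frac <= 0.15))
})

test_that("run_agreement validates the schema and composes the module results", {
  df <- data.frame(subject = 1:44, manual = rnorm(44, 90, 5))
  expect_error(run_agreement(df), class = "oxiring_schema")

  set.seed(17)
  truth <- rnorm(44, 90, 5)
  full <- data.frame(subject = 1:44, manual = truth + rnorm(44, 0, 2),
                     algorithm = truth + rnorm(44, 0, 2),
                     measure = "arteriolar")
  rep <- run_agreement(full)
  pr <- paired_readings(full$subject, full$manual, full$algorithm, "arteriolar")
  expect_equal(rep$arteriolar$icc$icc_single, icc(pr)$icc_single)
  expect_equal(rep$arteriolar$bland_altman$bias, bland_altman(pr)$bias)
  expect_equal(rep$arteriolar$n, 44)

  # CSV round trip
  tf <- tempfile(fileext = ".csv")
  write.csv(full, tf, row.names = FALSE)
  rep2 <- run_agreement(tf)
  expect_equal(rep2$arteriolar$icc$icc_single, rep$arteriolar$icc$icc_single)
})

test_that("fewer than three complete pairs are rejected", {
  expect_error(paired_readings(1:2, c(1, 2), c(1, 2)), "3 complete pairs")
  expect_error(paired_readings(1:3, c(1, 2, NA), c(1, 2, 3)), "3 complete pairs")
})
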
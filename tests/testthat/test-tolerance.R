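test_that("frequency curve normalizes to the 0 mM baseline", {
  d <- data.frame(concentration = rep(c(0, 4), each = 3),
                  cfu = c(2e8, 2e8, 2e8, 2e4, 2e4, 2e4))
  cv <- frequency_curve(d)
  expect_equal(cv$frequency[cv$concentration == 0], 1)
  expect_equal(cv$frequency[cv$concentration == 4], 1e-4)
  expect_equal(attr(cv, "baseline_cfu"), 2e8)
})

test_that("frequency at 0 mM is 1 even with replicate scatter", {
  d <- data.frame(concentration = rep(c(0, 2), each = 3),
                  cfu = c(1e8, 2e8, 3e8, 1e6, 2e6, 3e6))
  cv <- frequency_curve(d)
  expect_equal(cv$frequency[cv$concentration == 0], 1)
  expect_gt(cv$frequency_sd[cv$concentration == 0], 0)
})

test_that("fully censored concentrations become frequency 0 and flagged", {
  d <- data.frame(concentration = rep(c(0, 6), each = 2),
                  cfu = c(2e8, 2e8, 0, 0),
                  censored = c(FALSE, FALSE, TRUE, TRUE))
  cv <- frequency_curve(d)
  expect_equal(cv$frequency[cv$concentration == 6], 0)
  expect_true(cv$censored[cv$concentration == 6])
  expect_error(frequency_curve(data.frame(concentration = 0, cfu = 0)),
               "baseline")
  expect_error(frequency_curve(data.frame(concentration = 2, cfu = 1e5)),
               "0 mM")
})

test_that("frequencies are invariant to a constant factor on all estimates", {
  d <- data.frame(concentration = rep(c(0, 2, 4), each = 3),
                  cfu = c(2e8, 1.9e8, 2.1e8, 5e6, 6e6, 4e6, 2e4, 3e4, 1e4))
  d2 <- d; d2$cfu <- d2$cfu * 7.3
  expect_equal(frequency_curve(d)$frequency, frequency_curve(d2)$frequency)
})

test_that("detection limit reproduces the 3 x 10 uL plating threshold", {
  dl <- detection_limit(0.010, 3, 2e8)
  expect_identical(dl$min_density, 34)
  expect_equal(dl$min_frequency, (1 / 0.030) / 2e8)
  expect_equal(detection_limit(0.010, 3, 2e8, "floor")$min_frequency,
               33 / 2e8)
  expect_equal(detection_limit(0.010, 3, 2e8, "ceiling")$min_frequency,
               34 / 2e8)
})

test_that("detection limit is monotone in volume and population density", {
  base <- detection_limit(0.010, 3, 2e8)
  expect_lte(detection_limit(0.020, 3, 2e8)$min_density, base$min_density)
  expect_lte(detection_limit(0.010, 3, 4e8)$min_frequency,
             base$min_frequency)
  # before the ceiling, doubling volume exactly halves the raw threshold
  expect_equal(1 / (0.020 * 3), (1 / (0.010 * 3)) / 2)
})

test_that("decline slope is exact on log-linear input and flat input", {
  d <- data.frame(concentration = 1:4, frequency = 10^-(1:4))
  fit <- decline_slope(d)
  expect_equal(fit$slope, -1)
  expect_equal(fit$slope_se, 0)
  expect_equal(fit$n_points, 4L)

  flat <- decline_slope(data.frame(concentration = 1:4,
                                   frequency = rep(1e-2, 4)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$slope_se, 0)
})

test_that("point-selection rules behave as documented", {
  d <- data.frame(concentration = 0:6,
                  frequency = c(1, 1, 1e-1, 1e-2, 1e-3, 1e-4, 0),
                  censored = c(rep(FALSE, 6), TRUE))
  fit <- decline_slope(d, selection = "last_k_nonzero", k = 4)
  expect_equal(fit$points_used, 2:5)
  expect_equal(fit$slope, -1)
  expect_error(decline_slope(d, selection = "last_k", k = 4),
               "last_k_nonzero")
  ex <- decline_slope(d, selection = "explicit", points = c(3, 4, 5))
  expect_equal(ex$n_points, 3L)
  expect_equal(ex$slope, -1)
})

test_that("decline slope recovers the generating slope from noise-free models", {
  for (sl in c(-4.112, -1.482, -0.5)) {
    m <- tolerance_model(2, sl)
    cv <- model_curve(m, 0:6)
    expect_equal(decline_slope(cv, k = 4)$slope, sl, tolerance = 1e-12)
  }
})

test_that("decline slope from Poisson-level plating is nearly unbiased", {
  m <- tolerance_model(2, -1)
  slopes <- vapply(1:120, function(i) {
    spots <- sim_tolerance_counts(m, 0:6, base_density = 2e8,
                                  n_replicates = 3, seed = 9000 + i)
    decline_slope(frequency_curve(cfu_table_from_spots(spots)), k = 4)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-1)), 0.05)
})

test_that("slope comparison: identical fits give p = 1, degenerate fits warn", {
  d <- data.frame(concentration = 1:4,
                  frequency = 10^(-(1:4) + c(0.1, -0.05, 0.02, -0.07)))
  a <- decline_slope(d)
  expect_equal(compare_slopes(a, a)$p_value, 1)

  exact1 <- decline_slope(data.frame(concentration = 1:4,
                                     frequency = 10^-(1:4)))
  exact2 <- decline_slope(data.frame(concentration = 1:4,
                                     frequency = 10^(-2 * (1:4))))
  expect_warning(res <- compare_slopes(exact1, exact2), "degenerate")
  expect_equal(res$p_value, 0)
  expect_equal(compare_slopes(exact1, exact1)$p_value, 1)
})

test_that("slope comparison holds its nominal type-I error", {
  withr::with_seed(11, {
    pvals <- replicate(2000, {
      compare_slopes(null_slope_fit(), null_slope_fit())$p_value
    })
  })
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("slope comparison detects a genuinely different decline", {
  withr::with_seed(5, {
    a <- null_slope_fit(true_slope = -4.1, sd_log10 = 0.15)
    b <- null_slope_fit(true_slope = -1.5, sd_log10 = 0.15)
  })
  expect_lt(compare_slopes(a, b)$p_value, 0.05)
  expect_error(compare_slopes(a, list()), "slope_fit")
})
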
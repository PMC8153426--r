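test_that("every generator is byte-identical under a fixed seed", {
  expect_identical(sim_spot_series(2e8, seed = 42), sim_spot_series(2e8, seed = 42))
  m <- tolerance_model(2, -1)
  expect_identical(sim_tolerance_counts(m, 0:4, seed = 42),
                   sim_tolerance_counts(m, 0:4, seed = 42))
  expect_identical(sim_competition(0.5, 76.8, 51.2, seed = 42),
                   sim_competition(0.5, 76.8, 51.2, seed = 42))
  hm <- hill_model(850, 900, 8.01)
  expect_identical(sim_mst_curve(hm, 100 / 2^(0:15), seed = 42),
                   sim_mst_curve(hm, 100 / 2^(0:15), seed = 42))
  expect_identical(sim_itc_thermogram(Kd = 8, dH = -22.65, seed = 42),
                   sim_itc_thermogram(Kd = 8, dH = -22.65, seed = 42))
  expect_identical(sim_growth_curve(5, 0.25, 1, noise_sd = 0.01, seed = 42),
                   sim_growth_curve(5, 0.25, 1, noise_sd = 0.01, seed = 42))
  # generators never disturb the global RNG stream
  set.seed(9); before <- stats::runif(1)
  set.seed(9); invisible(sim_spot_series(2e8, seed = 1))
  expect_identical(stats::runif(1), before)
})

test_that("seeds are mandatory for every generator", {
  expect_error(sim_spot_series(2e8), "seed")
  expect_error(sim_competition(0.5, 2, 2), "seed")
  expect_error(sim_growth_curve(5, 0.25, 1), "seed")
})

test_that("spot counts are Poisson with the dilution-scaled mean", {
  # 1,000 draws at the 10^-5 spot of a 2e8 CFU/mL sample: mean 20
  reps <- sim_spot_series(2e8, dilution_exponents = -5L, spot_volume = 0.010,
                          n_replicates = 1000, seed = 21)
  counts <- vapply(reps, function(s) s$counts, numeric(1))
  # the Monte-Carlo SE of the mean is ~0.14; a band of 1 catches any real
  # miscalibration of the mean without failing on a tail draw of the
  # fixed-seed sample
  expect_lt(abs(mean(counts) - 20), 1)
  expect_true(all(counts >= 0 & counts == round(counts)))
  # variance consistent with Poisson (chi-square interval, df = n - 1)
  expect_lt(abs(stats::var(counts) / 20 - 1), 0.2)

  zero <- sim_spot_series(0, seed = 1)
  expect_true(all(vapply(zero, function(s) all(s$counts == 0), logical(1))))
})

test_that("tolerance model frequencies follow the flat-then-decline form", {
  m <- tolerance_model(2, -1, floor_frequency = 1e-9)
  expect_equal(tolerance_frequency(m, c(0, 1, 2)), c(1, 1, 1))
  expect_equal(tolerance_frequency(m, 4), 1e-2)
  expect_equal(tolerance_frequency(m, 100), 1e-9)  # clipped at the floor
  expect_error(tolerance_model(2, 0.5), "decline_slope")
  expect_error(sim_tolerance_counts(tolerance_model(2, -1), 1:4, seed = 1),
               "0 mM")
  expect_error(sim_tolerance_counts(tolerance_model(2, -1), c(0, 2, 1),
                                    seed = 1), "ascending")
})

test_that("tolerance counts reflect the model frequency and base density", {
  m <- tolerance_model(2, -1)
  spots <- sim_tolerance_counts(m, 0:4, base_density = 2e8,
                                n_replicates = 50, seed = 77)
  # at 0 mM the 10^-5 spot has mean 20; at 4 mM frequency 1e-2 -> mean 20
  # on the 10^-3 spot
  c0 <- vapply(spots[["0"]], function(s) s$counts[s$dilution_exponents == -5],
               numeric(1))
  c4 <- vapply(spots[["4"]], function(s) s$counts[s$dilution_exponents == -3],
               numeric(1))
  expect_lt(abs(mean(c0) - 20), 3 * stats::sd(c0) / sqrt(50))
  expect_lt(abs(mean(c4) - 20), 3 * stats::sd(c4) / sqrt(50))
})

test_that("competition generator honours its documented algebra", {
  raw <- sim_competition(0.5, 76.8, 51.2, n_events = 10000, seed = 5)
  expect_equal(attr(raw, "true_F1"), 0.5 * 76.8 / (0.5 * 76.8 + 0.5 * 51.2))
  expect_equal(attr(raw, "true_F1"), 0.6)
  expect_equal(attr(raw, "true_W"), log(76.8) / log(51.2))
  neutral <- sim_competition(0.37, 64, 64, seed = 5)
  expect_equal(attr(neutral, "true_F1"), 0.37)
  expect_equal(attr(neutral, "true_W"), 1)
  expect_error(sim_competition(1.2, 64, 64, seed = 1), "F0")
  expect_error(sim_competition(0.5, 64, 64, n_events = 500, seed = 1),
               "n_events")
})

test_that("MST generator is noiseless at noise_sd = 0 and noisy otherwise", {
  hm <- hill_model(850, 900, 8.01)
  concs <- 100 / 2^(0:15)
  d0 <- sim_mst_curve(hm, concs, noise_sd = 0, seed = 1)
  expect_equal(d0$F_norm, hill_response(hm, concs))
  d1 <- sim_mst_curve(hm, concs, noise_sd = 1, n_replicates = 3, seed = 1)
  expect_equal(nrow(d1), 48L)
  expect_gt(stats::sd(d1$F_norm - hill_response(hm, d1$concentration)), 0.5)
})

test_that("ITC generator embeds the forward model plus dilution heat", {
  e <- sim_itc_thermogram(Kd = 8, dH = -22.65, dilution_heat = -2,
                          noise_sd = 0, seed = 1)
  pure <- itc_forward(attr(e, "true_model"), e$protocol)
  # regular injections carry the full dilution heat; the 0.3 uL throw-away
  # carries 0.3/2 of it
  expect_equal(e$sample_heats[-1], pure[-1] - 2)
  expect_equal(e$sample_heats[1], pure[1] - 2 * 0.3 / 2)
  expect_equal(e$blank_heats[-1], rep(-2, 19))
  expect_true(e$protocol$excluded[1])
  expect_error(sim_itc_thermogram(Kd = 0, dH = -20, seed = 1), "Kd")
})

test_that("growth generator honours lag, asymptote and sorting", {
  g <- sim_growth_curve(lag = 5, rate = 0.25, K = 1, od0 = 0.02,
                        times = seq(0, 100, by = 1), noise_sd = 0, seed = 1)
  expect_true(all(g$od[g$time <= 5] == 0.02))
  expect_equal(g$od[g$time == 100], 1, tolerance = 1e-6)
  expect_error(sim_growth_curve(lag = 5, rate = -1, K = 1, seed = 1),
               "rate")
  expect_error(sim_growth_curve(lag = 5, rate = 0.2, K = 0.01, od0 = 0.02,
                                seed = 1), "K")
})
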
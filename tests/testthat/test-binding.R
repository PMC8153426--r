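paper_protocol <- itc_protocol()  # 20 x 2 uL of 25 mM into 400 uL of 50 uM

test_that("forward isotherm limits: zero enthalpy and saturation", {
  expect_equal(itc_forward(itc_model(1, Kd = 5, dH = 0), paper_protocol),
               rep(0, 20))

  # saturation: with ligand far beyond n*Mt and tight binding, the
  # cumulative heat approaches n * dH * Mt * V0
  p <- paper_protocol
  h <- itc_forward(itc_model(1, Kd = 1e-9, dH = -22.65), p)
  tot <- formstress:::itc_totals(p)
  dV <- p$injection_volumes / p$cell_volume
  # undo the perfusion terms to recover cumulative Q from per-injection heats
  Q <- 0
  for (i in seq_along(h)) {
    Q <- (Q * (1 - dV[i] / 2) + h[i] * 1e-6) / (1 + dV[i] / 2)
  }
  n_inj <- p$n_injections
  expect_equal(Q, -22.65 * 4184 * tot$Mt[n_inj] * 400e-6, tolerance = 1e-6)
})

test_that("tight-binding limit: pre-equivalence heat is dH x moles injected", {
  # 2 mM syringe ligand keeps the first several injections pre-equivalence
  p <- itc_protocol(syringe_ligand = 2)
  h <- itc_forward(itc_model(1, Kd = 1e-9, dH = -22.65), p)
  moles_inj2 <- 2e-3 * 2e-6            # syringe mol/L x injection litres
  expect_equal(h[2], -22.65 * 4184 * moles_inj2 * 1e6, tolerance = 1e-3)
})

test_that("tight-binding equivalence point sits at molar ratio = n_sites", {
  # fine 0.4 uL injections resolve the knee to ~0.05 molar-ratio units
  p <- itc_protocol(n_injections = 100, injection_volume = 0.4,
                    first_volume = 0.3, syringe_ligand = 2)
  tot <- formstress:::itc_totals(p)
  ratio <- tot$Lt / tot$Mt
  for (n_sites in c(1, 2)) {
    h <- itc_forward(itc_model(n_sites, Kd = 1e-6, dH = -22.65), p)
    drop <- which.min(diff(abs(h)))  # steepest fall-off of |heat|
    expect_lte(ratio[max(drop - 1L, 1L)], n_sites)
    expect_gte(ratio[drop + 1L], n_sites)
  }
})

test_that("blank subtraction removes dilution heat and the throw-away", {
  exp0 <- sim_itc_thermogram(paper_protocol, Kd = 8, dH = -22.65,
                             dilution_heat = -3, noise_sd = 0, seed = 1)
  corr <- subtract_blank(exp0)
  expect_equal(nrow(corr), 19L)
  expect_false(1L %in% corr$injection)
  pure <- itc_forward(attr(exp0, "true_model"), paper_protocol)
  expect_equal(corr$heat, pure[-1])

  same <- exp0; same$sample_heats <- same$blank_heats
  expect_true(all(subtract_blank(same)$heat == 0))

  bad <- exp0; bad$blank_heats <- bad$blank_heats[-1]
  expect_error(subtract_blank(bad), "match the protocol")
  mixed <- exp0; mixed$units <- c("uJ", "ucal")
  expect_error(subtract_blank(mixed), "different units")
})

test_that("zero-enthalpy thermograms leave sample and blank identical in law", {
  exp0 <- sim_itc_thermogram(paper_protocol, Kd = 8, dH = 0,
                             dilution_heat = -2, noise_sd = 0.25, seed = 3)
  d <- exp0$sample_heats - exp0$blank_heats
  expect_gt(stats::t.test(d)$p.value, 0.01)
})

test_that("one-site fit inverts the forward model exactly on noise-free data", {
  exp0 <- sim_itc_thermogram(paper_protocol, n_sites = 1, Kd = 8,
                             dH = -22.65, dilution_heat = -2, noise_sd = 0,
                             seed = 1)
  corr <- subtract_blank(exp0)
  fit_fixed <- fit_itc(corr, paper_protocol, fix_n = 1)
  expect_equal(fit_fixed$estimate$Kd, 8, tolerance = 1e-6)
  expect_equal(fit_fixed$estimate$dH, -22.65, tolerance = 1e-6)

  fit_free <- fit_itc(corr, paper_protocol)
  expect_equal(fit_free$estimate$n_sites, 1, tolerance = 1e-5)
  expect_equal(fit_free$estimate$Kd, 8, tolerance = 1e-5)
  expect_equal(fit_free$estimate$dH, -22.65, tolerance = 1e-5)
})

test_that("all-zero heats produce a near-zero enthalpy and a warning", {
  p <- paper_protocol
  corr <- data.frame(injection = 2:20, heat = rep(0, 19))
  expect_warning(fit <- fit_itc(corr, p, fix_n = 1), "unidentifiable")
  expect_equal(fit$estimate$dH, 0, tolerance = 1e-8)
})

test_that("enthalpy recovery bias over noisy simulations is small", {
  fits <- vapply(1:100, function(i) {
    e <- sim_itc_thermogram(paper_protocol, Kd = 8, dH = -22.65,
                            dilution_heat = -2, noise_sd = 0.25,
                            seed = 400 + i)
    f <- fit_itc(subtract_blank(e), paper_protocol, fix_n = 1)
    c(f$estimate$dH, f$estimate$Kd)
  }, numeric(2))
  expect_lt(abs(mean(fits[1, ]) / -22.65 - 1), 0.05)
  expect_lt(abs(mean(fits[2, ]) / 8 - 1), 0.05)
})

test_that("hill response has the documented fixed points", {
  m <- hill_model(850, 900, Kd = 8.01, n = 1)
  expect_equal(hill_response(m, 0), 850)
  expect_equal(hill_response(m, 8.01), 875)  # midpoint at c = Kd
  expect_equal(hill_response(m, 1e9), 900, tolerance = 1e-6)
  m2 <- hill_model(850, 900, Kd = 8.01, n = 2.5)
  expect_equal(hill_response(m2, 8.01), 875)
  expect_error(hill_model(850, 900, Kd = 0), "Kd")
})

test_that("hill fit inverts the forward model exactly on noise-free data", {
  concs <- 100 / 2^(0:15)
  for (n_true in c(1, 1.8)) {
    m <- hill_model(850, 900, Kd = 8.01, n = n_true)
    fit <- fit_hill(concs, hill_response(m, concs))
    expect_equal(fit$estimate$Kd, 8.01, tolerance = 1e-6)
    expect_equal(fit$estimate$n, n_true, tolerance = 1e-6)
    expect_equal(fit$estimate$F_min, 850, tolerance = 1e-6)
    expect_equal(fit$estimate$F_max, 900, tolerance = 1e-6)
  }
})

test_that("hill fit handles decreasing responses and rejects flat curves", {
  concs <- 100 / 2^(0:15)
  m_dec <- hill_model(900, 850, Kd = 8.01, n = 1)
  fit <- fit_hill(concs, hill_response(m_dec, concs))
  expect_equal(fit$estimate$Kd, 8.01, tolerance = 1e-6)
  expect_lt(fit$estimate$F_max, fit$estimate$F_min)

  expect_error(fit_hill(concs, rep(875, length(concs))), "flat")
  expect_error(fit_hill(c(1, 2, 4), c(1, 2, 3)), "5 distinct")
})

test_that("strict no-baseline form forces a zero response at c = 0", {
  concs <- c(0, 100 / 2^(0:14))
  m <- hill_model(0, 40, Kd = 8.01, n = 1)
  y <- hill_response(m, concs)
  fit <- fit_hill(concs, y, baseline = FALSE)
  expect_equal(fit$estimate$F_max - fit$estimate$F_min, 40, tolerance = 1e-5)
  expect_equal(fit$estimate$Kd, 8.01, tolerance = 1e-5)
})

test_that("noisy MST curves recover Kd within the assay's uncertainty", {
  m <- hill_model(850, 900, Kd = 8.01, n = 1)
  kds <- vapply(1:100, function(i) {
    d <- sim_mst_curve(m, 100 / 2^(0:15), noise_sd = 1, n_replicates = 3,
                       seed = 600 + i)
    fit_hill(d$concentration, d$F_norm)$estimate$Kd
  }, numeric(1))
  expect_lt(abs(mean(kds) / 8.01 - 1), 0.05)
  expect_gt(mean(abs(kds - 8.01) <= 3.5), 0.95)
})
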
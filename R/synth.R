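# Seeded synthetic-data generators emulating each assay's statistical
# structure: Poisson colony counts, binomial flow-cytometry fractions, and
# additive Gaussian instrument noise on binding and growth signals.
# Every generator takes an explicit seed and never touches global RNG state.

#' Flat-then-log-linear tolerance model
#'
#' Parametric stand-in for a population's formaldehyde tolerance
#' distribution: every cell tolerates concentrations up to a breakpoint
#' `c0`, beyond which the frequency of tolerant cells declines log-linearly
#' at `decline_slope` (log10 frequency per mM, negative) down to a floor:
#' `f(c) = 1` for `c <= c0`, else
#' `max(10^(decline_slope * (c - c0)), floor_frequency)`.
#' The form mirrors the summary statistic used on real curves (an OLS slope
#' over the declining tail); it is an operational choice, not a mechanistic
#' claim.
#'
#' @param breakpoint_c0 Concentration (mM) up to which all cells grow.
#' @param decline_slope log10-frequency decline per mM, < 0.
#' @param floor_frequency Lower bound on the frequency, in `[0, 1]`.
#' @return Object of class `tolerance_model`.
#' @export
tolerance_model <- function(breakpoint_c0, decline_slope,
                            floor_frequency = 0) {
  check_number(breakpoint_c0, "breakpoint_c0", lower = 0)
  check_number(decline_slope, "decline_slope", upper = 0)
  if (decline_slope >= 0) stop("`decline_slope` must be < 0", call. = FALSE)
  check_number(floor_frequency, "floor_frequency", lower = 0, upper = 1)
  structure(list(breakpoint_c0 = breakpoint_c0,
                 decline_slope = decline_slope,
                 floor_frequency = floor_frequency),
            class = "tolerance_model")
}

#' Tolerant-cell frequency under a tolerance model
#'
#' @param model A [tolerance_model()].
#' @param concentrations Concentrations in mM.
#' @return Frequencies in `[0, 1]`.
#' @export
tolerance_frequency <- function(model, concentrations) {
  stopifnot(inherits(model, "tolerance_model"))
  ifelse(concentrations <= model$breakpoint_c0, 1,
         pmax(10^(model$decline_slope *
                    (concentrations - model$breakpoint_c0)),
              model$floor_frequency))
}

#' Simulate replicate serial-dilution spot series
#'
#' Each spot's colony count is Poisson with mean
#' `true_density * spot_volume * 10^exponent` -- the sampling model implied
#' by plating a small volume of a well-mixed dilution.
#'
#' @param true_density True density, CFU/mL (>= 0).
#' @param dilution_exponents Base-10 dilution exponents, strictly
#'   decreasing.
#' @param spot_volume Spot volume in mL.
#' @param n_replicates Number of replicate series.
#' @param seed RNG seed (required).
#' @param sample_id Identifier stamped on the series.
#' @return List of [spot_series()], length `n_replicates`.
#' @examples
#' sim_spot_series(2e8, seed = 1)
#' @export
sim_spot_series <- function(true_density, dilution_exponents = 0:-6,
                            spot_volume = 0.010, n_replicates = 3,
                            seed, sample_id = "sim") {
  check_number(true_density, "true_density", lower = 0)
  check_number(spot_volume, "spot_volume", lower = 0, strict_lower = TRUE)
  check_count(n_replicates, "n_replicates", lower = 1L)
  mu <- true_density * spot_volume * 10^dilution_exponents
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      spot_series(stats::rpois(length(mu), mu),
                  dilution_exponents = dilution_exponents,
                  spot_volume = spot_volume,
                  sample_id = sample_id,
                  replicate_id = sprintf("r%d", r))
    })
  })
}

#' Simulate a tolerance plating assay across a concentration series
#'
#' For each plate concentration the density of tolerant cells is
#' `base_density * tolerance_frequency(model, c)` and replicate spot series
#' are drawn as in [sim_spot_series()].  The concentration list must include
#' the 0 mM baseline plate.
#'
#' @param model A [tolerance_model()].
#' @param concentrations Ascending mM series including 0.
#' @param base_density Density of the whole population, CFU/mL.
#' @param dilution_exponents,spot_volume,n_replicates Plating geometry.
#' @param seed RNG seed (required).
#' @return Named list (one element per concentration) of lists of
#'   [spot_series()].
#' @export
sim_tolerance_counts <- function(model, concentrations, base_density = 2e8,
                                 dilution_exponents = 0:-6,
                                 spot_volume = 0.010, n_replicates = 3,
                                 seed) {
  stopifnot(inherits(model, "tolerance_model"))
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("`concentrations` must be strictly ascending", call. = FALSE)
  }
  if (!any(concentrations == 0)) {
    stop("`concentrations` must include the 0 mM baseline", call. = FALSE)
  }
  check_number(base_density, "base_density", lower = 0)
  freqs <- tolerance_frequency(model, concentrations)
  check_seed(seed)
  out <- lapply(seq_along(concentrations), function(i) {
    sim_spot_series(base_density * freqs[i],
                    dilution_exponents = dilution_exponents,
                    spot_volume = spot_volume,
                    n_replicates = n_replicates,
                    seed = seed + i,
                    sample_id = sprintf("c%g", concentrations[i]))
  })
  names(out) <- as.character(concentrations)
  attr(out, "concentrations") <- concentrations
  out
}

#' Simulate a pairwise competition read by flow cytometry
#'
#' The mixed culture starts with test-strain fraction `F0`; the test strain
#' expands `fold_test`-fold and the reference `fold_ref`-fold, so the end
#' fraction is `F1 = F0 * fold_test / (F0 * fold_test + (1 - F0) * fold_ref)`
#' and the true Malthusian fitness is `log(fold_test) / log(fold_ref)`.
#' Flow-cytometry counting draws the observed positives binomially at each
#' time point.  Positives are counted on the *test* strain here; pair with
#' `gate_fractions(..., test_is_nonfluorescent = FALSE)` or use the
#' fractions directly.
#'
#' @param F0 Starting test-strain fraction in (0, 1).
#' @param fold_test,fold_ref Fold expansions over the cycle (> 1).
#' @param n_events Events counted per time point (>= 1000, the assay's
#'   counting floor).
#' @param seed RNG seed (required).
#' @return Data frame of class `competition_raw` with observed counts, the
#'   implied overall expansion, and attributes `true_F1` / `true_W`.
#' @export
sim_competition <- function(F0, fold_test, fold_ref, n_events = 10000,
                            seed) {
  check_number(F0, "F0", lower = 0, upper = 1)
  if (F0 <= 0 || F0 >= 1) stop("`F0` must be inside (0, 1)", call. = FALSE)
  check_number(fold_test, "fold_test", lower = 1, strict_lower = TRUE)
  check_number(fold_ref, "fold_ref", lower = 1, strict_lower = TRUE)
  check_count(n_events, "n_events", lower = 1000L)
  F1 <- F0 * fold_test / (F0 * fold_test + (1 - F0) * fold_ref)
  out <- with_seed(seed, data.frame(
    positives_t0 = stats::rbinom(1, n_events, F0),
    total_t0 = n_events,
    positives_t1 = stats::rbinom(1, n_events, F1),
    total_t1 = n_events,
    expansion = F0 * fold_test + (1 - F0) * fold_ref
  ))
  attr(out, "true_F1") <- F1
  attr(out, "true_W") <- log(fold_test) / log(fold_ref)
  class(out) <- c("competition_raw", "data.frame")
  out
}

#' Simulate an MST dose-response curve
#'
#' Hill-model response plus additive Gaussian instrument noise, on a
#' user-supplied concentration series (a 2-fold serial dilution of the
#' titrant is the usual design).
#'
#' @param model A [hill_model()].
#' @param concentrations Titrant concentrations (>= 0).
#' @param noise_sd Gaussian noise SD, in normalized-fluorescence units.
#' @param n_replicates Replicate curves.
#' @param seed RNG seed (required).
#' @return Data frame with `concentration`, `replicate`, `F_norm`.
#' @export
sim_mst_curve <- function(model, concentrations, noise_sd = 1,
                          n_replicates = 1, seed) {
  stopifnot(inherits(model, "hill_model"))
  check_number(noise_sd, "noise_sd", lower = 0)
  check_count(n_replicates, "n_replicates", lower = 1L)
  mu <- hill_response(model, concentrations)
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(concentration = concentrations,
                 replicate = r,
                 F_norm = mu + stats::rnorm(length(mu), 0, noise_sd))
    }))
  })
}

#' Simulate an ITC thermogram with matching buffer blank
#'
#' Sample heats are the one-site forward model ([itc_forward()]) plus a
#' per-injection dilution heat plus Gaussian noise; blank heats (the
#' buffer:ligand titration) are the dilution heat plus independent noise of
#' the same SD.  Dilution heat scales with injected volume, so the
#' throw-away first injection carries a proportionally smaller blank heat.
#'
#' @param protocol An [itc_protocol()].
#' @param n_sites,Kd,dH One-site model parameters ([itc_model()]); `Kd` in
#'   mM, `dH` in kcal/mol.
#' @param dilution_heat Heat of ligand dilution per regular injection, uJ
#'   (applied pro rata by injection volume).
#' @param noise_sd Gaussian instrument noise SD per injection, uJ.
#' @param seed RNG seed (required).
#' @return Object of class `itc_experiment` with `protocol`,
#'   `sample_heats`, `blank_heats`, `units` and attribute `true_model`.
#' @export
sim_itc_thermogram <- function(protocol = itc_protocol(), n_sites = 1,
                               Kd, dH, dilution_heat = -2, noise_sd = 0.25,
                               seed) {
  stopifnot(inherits(protocol, "itc_protocol"))
  model <- itc_model(n_sites = n_sites, Kd = Kd, dH = dH)
  check_number(dilution_heat, "dilution_heat")
  check_number(noise_sd, "noise_sd", lower = 0)
  binding_heats <- itc_forward(model, protocol)
  vol_scale <- protocol$injection_volumes /
    protocol$injection_volumes[protocol$n_injections]
  dil <- dilution_heat * vol_scale
  k <- protocol$n_injections
  out <- with_seed(seed, {
    list(protocol = protocol,
         sample_heats = binding_heats + dil + stats::rnorm(k, 0, noise_sd),
         blank_heats = dil + stats::rnorm(k, 0, noise_sd),
         units = "uJ")
  })
  attr(out, "true_model") <- model
  class(out) <- "itc_experiment"
  out
}

#' Simulate a lagged-logistic growth curve
#'
#' OD stays at `od0` until `lag`, then follows logistic growth
#' `OD(t) = K * od0 * e^(r (t - lag)) / (K + od0 * (e^(r (t - lag)) - 1))`
#' toward carrying capacity `K`, plus Gaussian read noise.
#'
#' @param lag Lag time, h (>= 0).
#' @param rate Exponential rate, per h (> 0).
#' @param K Maximum OD (> `od0`).
#' @param times Sorted time grid, h.
#' @param od0 Initial OD.
#' @param noise_sd Gaussian noise SD in OD units.
#' @param seed RNG seed (required).
#' @return Data frame with `time` and `od`.
#' @export
sim_growth_curve <- function(lag, rate, K, times = seq(0, 48, by = 0.25),
                             od0 = 0.02, noise_sd = 0, seed) {
  check_number(lag, "lag", lower = 0)
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  check_number(od0, "od0", lower = 0, strict_lower = TRUE)
  check_number(K, "K", lower = od0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (is.unsorted(times)) stop("`times` must be sorted", call. = FALSE)
  g <- exp(rate * pmax(times - lag, 0))
  od <- K * od0 * g / (K + od0 * (g - 1))
  with_seed(seed, {
    data.frame(time = times,
               od = od + stats::rnorm(length(times), 0, noise_sd))
  })
}
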
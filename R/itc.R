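# Isothermal titration calorimetry: single-set-of-sites (independent
# binding) isotherm, blank subtraction, and nonlinear least-squares fitting.

KCAL_PER_MOL_TO_J <- 4184  # 1 kcal = 4184 J

#' ITC injection protocol
#'
#' Describes a low-volume ITC run.  Defaults reproduce a standard protein
#' titration: 20 injections of 2 uL of 25 mM ligand into a 400 uL cell of
#' 50 uM protein every 200 s at 25 C, with the first injection a 0.3 uL
#' throw-away whose heat is flagged and excluded from fitting (syringe-tip
#' diffusion makes it unreliable, per universal ITC practice).
#'
#' @param cell_volume Cell volume, uL.
#' @param n_injections Total number of injections, including the throw-away.
#' @param injection_volume Volume of each regular injection, uL.
#' @param first_volume Volume of the first (throw-away) injection, uL.
#' @param interval Spacing between injections, s.
#' @param syringe_ligand Syringe ligand concentration, mM.
#' @param cell_protein Cell protein concentration, uM.
#' @param temperature Cell temperature, degrees C.
#' @return Object of class `itc_protocol`; `$injection_volumes` holds the
#'   per-injection volumes and `$excluded` flags the throw-away.
#' @export
itc_protocol <- function(cell_volume = 400, n_injections = 20,
                         injection_volume = 2, first_volume = 0.3,
                         interval = 200, syringe_ligand = 25,
                         cell_protein = 50, temperature = 25) {
  check_number(cell_volume, "cell_volume", lower = 0, strict_lower = TRUE)
  check_count(n_injections, "n_injections", lower = 2L)
  check_number(injection_volume, "injection_volume", lower = 0,
               strict_lower = TRUE)
  check_number(first_volume, "first_volume", lower = 0, strict_lower = TRUE)
  check_number(syringe_ligand, "syringe_ligand", lower = 0,
               strict_lower = TRUE)
  check_number(cell_protein, "cell_protein", lower = 0, strict_lower = TRUE)
  structure(
    list(cell_volume = cell_volume, n_injections = as.integer(n_injections),
         injection_volumes = c(first_volume,
                               rep(injection_volume, n_injections - 1L)),
         excluded = c(TRUE, rep(FALSE, n_injections - 1L)),
         interval = interval, syringe_ligand = syringe_ligand,
         cell_protein = cell_protein, temperature = temperature),
    class = "itc_protocol"
  )
}

#' One-site binding model parameters
#'
#' @param n_sites Stoichiometry (sites per protein), > 0.
#' @param Kd Dissociation constant, mM, > 0.
#' @param dH Molar binding enthalpy, kcal/mol.
#' @return Object of class `itc_model`.
#' @export
itc_model <- function(n_sites = 1, Kd, dH) {
  check_number(n_sites, "n_sites", lower = 0, strict_lower = TRUE)
  check_number(Kd, "Kd", lower = 0, strict_lower = TRUE)
  check_number(dH, "dH")
  structure(list(n_sites = n_sites, Kd = Kd, dH = dH), class = "itc_model")
}

# Displaced-volume-corrected total concentrations (mol/L) after each
# injection: the injected volume pushes cell contents into the overfill stem,
# so protein is diluted and less ligand remains in the working volume than
# was injected.
itc_totals <- function(protocol) {
  V0 <- protocol$cell_volume                 # uL
  vcum <- cumsum(protocol$injection_volumes) # uL
  M0 <- protocol$cell_protein * 1e-6         # mol/L
  Ls <- protocol$syringe_ligand * 1e-3       # mol/L
  list(
    Mt = M0 * (1 - vcum / (2 * V0)) / (1 + vcum / (2 * V0)),
    Lt = Ls * (vcum / V0) * (1 - vcum / (2 * V0)),
    vcum = vcum
  )
}

#' Forward single-set-of-sites ITC model
#'
#' Predicted per-injection heats (uJ) for an independent-binding (one-site)
#' isotherm.  Cumulative heat after injection `i` is
#' \deqn{Q_i = \frac{n M_i \Delta H V_0}{2}\left[1 + \frac{L_i}{n M_i} +
#'   \frac{K_d}{n M_i} - \sqrt{\left(1 + \frac{L_i}{n M_i} +
#'   \frac{K_d}{n M_i}\right)^2 - \frac{4 L_i}{n M_i}}\right]}
#' with displaced-volume-corrected totals `M_i` (protein) and `L_i`
#' (ligand), and the measured heat of injection `i` corrects for the heat
#' carried out with the displaced volume:
#' `dQ_i = Q_i - Q_{i-1} + (dV_i / V_0) (Q_i + Q_{i-1}) / 2`.
#'
#' @param model An [itc_model()].
#' @param protocol An [itc_protocol()].
#' @return Numeric vector of per-injection heats in uJ, one per injection
#'   (including the throw-away, which fits later exclude).
#' @export
itc_forward <- function(model, protocol) {
  stopifnot(inherits(model, "itc_model"), inherits(protocol, "itc_protocol"))
  tot <- itc_totals(protocol)
  n <- model$n_sites
  Kd <- model$Kd * 1e-3                        # mol/L
  dH <- model$dH * KCAL_PER_MOL_TO_J           # J/mol
  V0 <- protocol$cell_volume * 1e-6            # L

  x <- tot$Lt / (n * tot$Mt)
  r <- Kd / (n * tot$Mt)
  brk <- 1 + x + r - sqrt((1 + x + r)^2 - 4 * x)
  Q <- n * tot$Mt * dH * V0 / 2 * brk          # J, cumulative
  Qprev <- c(0, Q[-length(Q)])
  dV <- protocol$injection_volumes / protocol$cell_volume
  dQ <- Q - Qprev + dV * (Q + Qprev) / 2
  dQ * 1e6                                      # uJ
}

#' Subtract the buffer:ligand blank from an ITC experiment
#'
#' The blank titration (ligand injected into buffer) measures the heat of
#' dilution of the ligand; subtracting it injection-by-injection from the
#' protein:ligand heats isolates the binding heat.  The throw-away first
#' injection is dropped from the output.
#'
#' @param experiment A list of class `itc_experiment` (see
#'   [sim_itc_thermogram()]) with `protocol`, `sample_heats`, `blank_heats`
#'   and a `units` field; sample and blank must share protocol length and
#'   units (no silent unit conversion).
#' @return Data frame with columns `injection`, `volume` (uL) and `heat`
#'   (corrected, uJ), throw-away injection excluded.
#' @export
subtract_blank <- function(experiment) {
  p <- experiment$protocol
  sh <- experiment$sample_heats
  bh <- experiment$blank_heats
  if (length(sh) != p$n_injections || length(bh) != p$n_injections) {
    stop("sample/blank heat vectors must match the protocol's injection count",
         call. = FALSE)
  }
  units <- experiment$units
  if (!is.null(units) && length(unique(units)) > 1L) {
    stop("sample and blank heats are in different units; convert first",
         call. = FALSE)
  }
  keep <- !p$excluded
  data.frame(injection = seq_len(p$n_injections)[keep],
             volume = p$injection_volumes[keep],
             heat = (sh - bh)[keep])
}

#' Fit the one-site isotherm to blank-corrected ITC heats
#'
#' Nonlinear least squares of [itc_forward()] against corrected per-injection
#' heats.  A profile search is used for robust initialization: for each trial
#' Kd on a log grid the enthalpy enters the model linearly and is solved in
#' closed form; the best pair seeds a Levenberg--Marquardt refinement on
#' (`dH`, `log Kd`) and, unless `fix_n` is given, `n_sites`.  At low Wiseman
#' `c` values (`c = n * [protein] / Kd` well below 1, as in weak-binding
#' titrations) stoichiometry and enthalpy are not separately identifiable
#' and fixing `fix_n = 1` is the standard practice.
#'
#' @param corrected Data frame from [subtract_blank()] (columns `injection`,
#'   `heat` in uJ).
#' @param protocol The matching [itc_protocol()].
#' @param fix_n Fix the stoichiometry at this value instead of estimating it
#'   (e.g. `1`); `NULL` (default) estimates it.
#' @param n_kd_grid Size of the log-spaced Kd initialization grid.
#' @return Object of class `itc_fit`: `estimate` (an [itc_model()]),
#'   `se` (named, mM / kcal/mol scale), `residuals`, `fitted`,
#'   `converged`.
#' @export
fit_itc <- function(corrected, protocol, fix_n = NULL, n_kd_grid = 60) {
  stopifnot(inherits(protocol, "itc_protocol"))
  if (!is.data.frame(corrected) ||
      !all(c("injection", "heat") %in% names(corrected))) {
    stop("`corrected` needs columns `injection` and `heat`", call. = FALSE)
  }
  idx <- corrected$injection
  y <- corrected$heat
  if (length(y) < 6L) stop("need >= 6 fitted injections", call. = FALSE)

  if (stats::sd(y) < .Machine$double.eps^0.5 &&
      max(abs(y)) < .Machine$double.eps^0.25) {
    warning("all heats ~0: enthalpy ~0 and Kd unidentifiable")
  }

  fwd <- function(n, Kd_mM, dH) {
    itc_forward(itc_model(n_sites = n, Kd = Kd_mM, dH = dH), protocol)[idx]
  }

  # profile initialization: model is linear in dH given (n, Kd)
  tot <- itc_totals(protocol)
  Lt_max_mM <- max(tot$Lt) * 1e3
  kd_grid <- exp(seq(log(Lt_max_mM * 1e-3), log(Lt_max_mM * 1e3),
                     length.out = n_kd_grid))
  n0 <- if (is.null(fix_n)) 1 else fix_n
  best <- NULL
  for (kd in kd_grid) {
    f <- fwd(n0, kd, 1)
    denom <- sum(f^2)
    if (denom == 0) next
    dh <- sum(f * y) / denom
    rss <- sum((y - dh * f)^2)
    if (is.null(best) || rss < best$rss) best <- list(kd = kd, dh = dh,
                                                      rss = rss)
  }
  if (is.null(best)) stop("initialization failed: degenerate model surface",
                          call. = FALSE)

  if (is.null(fix_n)) {
    par0 <- c(dH = best$dh, logKd = log(best$kd), n = 1)
    resid_fun <- function(p) y - fwd(p[["n"]], exp(p[["logKd"]]), p[["dH"]])
  } else {
    par0 <- c(dH = best$dh, logKd = log(best$kd))
    resid_fun <- function(p) y - fwd(fix_n, exp(p[["logKd"]]), p[["dH"]])
  }
  nls_out <- minpack.lm::nls.lm(
    par = par0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  if (nls_out$info %in% c(0, 9)) {
    stop(sprintf("ITC fit did not converge (nls.lm info %d); final RSS %.4g",
                 nls_out$info, nls_out$deviance), call. = FALSE)
  }
  p <- nls_out$par
  est_n <- if (is.null(fix_n)) p[["n"]] else fix_n
  est <- itc_model(n_sites = est_n, Kd = exp(p[["logKd"]]), dH = p[["dH"]])

  # delta-method SEs on the reporting scale (Kd back-transformed from log)
  np <- length(p)
  dof <- length(y) - np
  sigma2 <- nls_out$deviance / max(dof, 1)
  cov <- tryCatch(solve(nls_out$hessian) * sigma2,
                  error = function(e) matrix(NA_real_, np, np,
                                             dimnames = list(names(p),
                                                             names(p))))
  se <- sqrt(pmax(diag(cov), 0))
  out_se <- c(dH = unname(se["dH"]),
              Kd = unname(se["logKd"]) * est$Kd,
              n_sites = if (is.null(fix_n)) unname(se["n"]) else 0)

  fitted <- fwd(est$n_sites, est$Kd, est$dH)
  # saturated-from-start data: no curvature information left for Kd
  c_value <- est$n_sites * protocol$cell_protein * 1e-6 / (est$Kd * 1e-3)
  if (is.finite(c_value) && c_value > 1e4) {
    warning("titration saturated from the first injection: Kd unidentifiable")
  }
  structure(
    list(estimate = est, se = out_se, residuals = y - fitted,
         fitted = fitted, injections = idx, c_value = c_value,
         converged = TRUE, rss = nls_out$deviance),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  e <- x$estimate
  cat(sprintf(paste0("<itc_fit> n = %.3g +/- %.2g, Kd = %.4g +/- %.2g mM, ",
                     "dH = %.4g +/- %.2g kcal/mol (c = %.3g)\n"),
              e$n_sites, x$se[["n_sites"]], e$Kd, x$se[["Kd"]],
              e$dH, x$se[["dH"]], x$c_value))
  invisible(x)
}
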
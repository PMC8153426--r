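# Microscale thermophoresis dose-response: Hill model and fitting.

#' Hill dose-response model
#'
#' Parameters of the normalized-fluorescence dose-response curve
#' `F(c) = F_min + (F_max - F_min) * c^n / (c^n + Kd^n)`.  The baseline term
#' `F_min` makes `F(0) = F_min`, consistent with MST normalized fluorescence
#' (reported in per-mil units, typically ~800-1000); a strict form without
#' the baseline is available in [fit_hill()] for comparison with analyses
#' that fit the bare saturation term.
#'
#' @param F_min,F_max Normalized fluorescence at zero and saturating titrant
#'   (`F_max >= F_min` for a rising response).
#' @param Kd Dissociation constant in the titrant's concentration unit
#'   (mM here), > 0.
#' @param n Hill coefficient, > 0.
#' @return Object of class `hill_model`.
#' @export
hill_model <- function(F_min, F_max, Kd, n = 1) {
  check_number(F_min, "F_min")
  check_number(F_max, "F_max")
  check_number(Kd, "Kd", lower = 0, strict_lower = TRUE)
  check_number(n, "n", lower = 0, strict_lower = TRUE)
  structure(list(F_min = F_min, F_max = F_max, Kd = Kd, n = n),
            class = "hill_model")
}

#' Evaluate a Hill model
#'
#' @param model A [hill_model()].
#' @param concentrations Non-negative titrant concentrations.
#' @return Predicted normalized fluorescence.
#' @export
hill_response <- function(model, concentrations) {
  stopifnot(inherits(model, "hill_model"))
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  cn <- concentrations^model$n
  model$F_min + (model$F_max - model$F_min) * cn / (cn + model$Kd^model$n)
}

#' Fit the Hill equation to a dose-response curve
#'
#' Nonlinear least squares of normalized fluorescence on titrant
#' concentration.  Initial values follow the data: `F_min` from the response
#' at the lowest concentration, `F_max` from the highest, `Kd` from the
#' concentration nearest the half response, `n = 1`.
#'
#' @param concentrations Titrant concentrations (>= 0); at least 5 distinct
#'   values spanning the response.
#' @param response Normalized fluorescence, same length (replicate
#'   measurements at the same concentration are simply repeated rows).
#' @param baseline Include the additive `F_min` baseline (default `TRUE`).
#'   `FALSE` fits the bare saturation form
#'   `F = (F_max - F_min) * c^n / (c^n + Kd^n)`, which forces `F(0) = 0`.
#' @return Object of class `hill_fit`: `estimate` (a [hill_model()]),
#'   `se`, `residuals`, `fitted`, `r_squared`.
#' @export
fit_hill <- function(concentrations, response, baseline = TRUE) {
  if (length(concentrations) != length(response)) {
    stop("`concentrations` and `response` must have equal length",
         call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (length(unique(concentrations)) < 5L) {
    stop("need >= 5 distinct concentrations", call. = FALSE)
  }
  spread <- diff(range(response))
  if (spread <= .Machine$double.eps^0.5 * max(1, abs(mean(response)))) {
    stop("flat response curve: no dose dependence to fit", call. = FALSE)
  }

  ord_mean <- tapply(response, concentrations, mean)
  concs_u <- as.numeric(names(ord_mean))
  f_lo <- ord_mean[[which.min(concs_u)]]
  f_hi <- ord_mean[[which.max(concs_u)]]
  half <- (f_lo + f_hi) / 2
  kd0 <- concs_u[which.min(abs(ord_mean - half))]
  if (kd0 <= 0) kd0 <- min(concs_u[concs_u > 0])

  df <- data.frame(conc = concentrations, resp = response)
  if (baseline) {
    fit <- minpack.lm::nlsLM(
      resp ~ F_min + (F_max - F_min) * conc^n / (conc^n + Kd^n),
      data = df,
      start = list(F_min = f_lo, F_max = f_hi, Kd = kd0, n = 1),
      lower = c(F_min = -Inf, F_max = -Inf, Kd = 1e-12, n = 0.05),
      control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                   minFactor = 1e-10)
    )
  } else {
    # bare saturation form: only the amplitude F_max - F_min is
    # identifiable, so fit it as one parameter and report F_min = 0
    fit <- minpack.lm::nlsLM(
      resp ~ F_max * conc^n / (conc^n + Kd^n),
      data = df,
      start = list(F_max = f_hi - f_lo, Kd = kd0, n = 1),
      lower = c(F_max = -Inf, Kd = 1e-12, n = 0.05),
      control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                   minFactor = 1e-10)
    )
  }
  cf <- stats::coef(fit)
  if (!baseline) cf <- c(F_min = 0, cf)
  se <- tryCatch(summary(fit)$coefficients[, 2],
                 error = function(e) stats::setNames(rep(NA_real_,
                                                         length(cf)),
                                                     names(cf)))
  if (!baseline) se <- c(F_min = 0, se)
  est <- hill_model(F_min = cf[["F_min"]], F_max = cf[["F_max"]],
                    Kd = cf[["Kd"]], n = cf[["n"]])
  res <- stats::resid(fit)
  # monotonicity sanity check: the per-concentration means should trend the
  # way F_min -> F_max implies; gross violation suggests the wrong assay sign
  trend <- stats::cor(concs_u, as.numeric(ord_mean), method = "spearman")
  if (is.finite(trend) && sign(trend) != sign(est$F_max - est$F_min) &&
      abs(trend) > 0.5) {
    warning("response trend disagrees with fitted F_min/F_max orientation")
  }
  structure(
    list(estimate = est, se = se, residuals = res,
         fitted = stats::fitted(fit),
         r_squared = 1 - sum(res^2) / sum((response - mean(response))^2),
         baseline = baseline),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  e <- x$estimate
  cat(sprintf(paste0("<hill_fit> Kd = %.4g +/- %.2g, n = %.3g +/- %.2g, ",
                     "range %.4g-%.4g (R^2 = %.4f)\n"),
              e$Kd, x$se[["Kd"]], e$n, x$se[["n"]], e$F_min, e$F_max,
              x$r_squared))
  invisible(x)
}
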
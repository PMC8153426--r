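# Formaldehyde tolerance distributions: frequency curves, plating limit of
# detection, log-linear decline slopes and slope comparison.

#' Build a tolerance frequency curve from per-concentration CFU estimates
#'
#' The frequency of tolerant cells at concentration `c` is the CFU density
#' enumerated on medium containing `c` mM formaldehyde expressed as a
#' proportion of the CFU density on formaldehyde-free (0 mM) medium.  Each
#' replicate spot series yields one replicate frequency
#' `CFU_r(c) / mean(CFU(0))`; the curve stores their mean and sample SD.
#' Concentrations at which every replicate was censored (no colonies) get
#' frequency 0 with `censored = TRUE`, marking them as below the plating
#' limit of detection; such points never enter slope fits under the default
#' point-selection rule.
#'
#' @param cfu A data frame with columns `concentration` (mM), `cfu`
#'   (CFU/mL, one row per replicate) and optionally `censored` (logical).
#'   Must include rows at 0 mM with a positive mean.
#' @return A data frame of class `tolerance_curve` with columns
#'   `concentration`, `frequency`, `frequency_sd`, `n`, `censored`; the
#'   pooled 0 mM density is attached as attribute `baseline_cfu`.
#' @examples
#' d <- data.frame(concentration = rep(c(0, 4), each = 3),
#'                 cfu = c(2e8, 2e8, 2e8, 2e4, 2e4, 2e4))
#' frequency_curve(d)
#' @export
frequency_curve <- function(cfu) {
  if (!is.data.frame(cfu) ||
      !all(c("concentration", "cfu") %in% names(cfu))) {
    stop("`cfu` needs columns `concentration` and `cfu`", call. = FALSE)
  }
  if (is.null(cfu$censored)) cfu$censored <- FALSE
  if (!any(cfu$concentration == 0)) {
    stop("0 mM baseline missing from `cfu`", call. = FALSE)
  }
  baseline <- mean(cfu$cfu[cfu$concentration == 0])
  if (!is.finite(baseline) || baseline <= 0) {
    stop("undefined baseline: CFU at 0 mM must be positive", call. = FALSE)
  }
  concs <- sort(unique(cfu$concentration))
  rows <- lapply(concs, function(cc) {
    sub <- cfu[cfu$concentration == cc, ]
    freq <- sub$cfu / baseline
    all_cens <- all(sub$censored)
    data.frame(
      concentration = cc,
      frequency = if (all_cens) 0 else mean(freq),
      frequency_sd = if (nrow(sub) > 1L) stats::sd(freq) else NA_real_,
      n = nrow(sub),
      censored = all_cens
    )
  })
  out <- do.call(rbind, rows)
  # 0 mM frequency is 1 by construction (mean of reps over their own mean)
  attr(out, "baseline_cfu") <- baseline
  class(out) <- c("tolerance_curve", "data.frame")
  out
}

#' Limit of detection of a spot-plating tolerance assay
#'
#' With `spots_per_sample` replicate spots of `spot_volume` mL each, the
#' smallest detectable density is the density at which one colony is expected
#' across the total plated volume, rounded up to a whole CFU/mL:
#' `ceiling(1 / (spot_volume * spots_per_sample))`.  For three 10 uL spots
#' this is 34 CFU/mL.  The corresponding minimum detectable subpopulation
#' frequency divides a density threshold by the total population density;
#' because the threshold can be quoted unrounded (33.3), rounded down (33) or
#' rounded up (34), the basis is an explicit argument rather than a guess.
#'
#' @param spot_volume Volume per spot in mL (default 0.010).
#' @param spots_per_sample Number of replicate spots per dilution
#'   (default 3).
#' @param population_density Total population density in CFU/mL that the
#'   frequency refers to (e.g. 2e8 for a stationary-phase culture).
#' @param frequency_basis How to round the density threshold before forming
#'   the frequency: `"unrounded"` (1/total volume), `"floor"` or
#'   `"ceiling"`.
#' @return List with `min_density` (CFU/mL, integer ceiling) and
#'   `min_frequency`.
#' @examples
#' detection_limit(0.010, 3, 2e8)$min_density  # 34
#' @export
detection_limit <- function(spot_volume = 0.010, spots_per_sample = 3,
                            population_density = 2e8,
                            frequency_basis = c("unrounded", "floor",
                                                "ceiling")) {
  check_number(spot_volume, "spot_volume", lower = 0, strict_lower = TRUE)
  check_count(spots_per_sample, "spots_per_sample", lower = 1L)
  check_number(population_density, "population_density", lower = 0,
               strict_lower = TRUE)
  frequency_basis <- match.arg(frequency_basis)
  exact <- 1 / (spot_volume * spots_per_sample)
  basis <- switch(frequency_basis,
                  unrounded = exact,
                  floor = floor(exact),
                  ceiling = ceiling(exact))
  list(min_density = ceiling(exact),
       min_frequency = basis / population_density,
       frequency_basis = frequency_basis)
}

#' Fit the log-linear decline slope of a tolerance curve
#'
#' Quantifies the rate of decline of tolerant cells with formaldehyde
#' concentration by ordinary least squares of log10(frequency) on
#' concentration over a selected set of points.  The default selection is the
#' last `k` non-zero (non-censored) points of the curve; `"last_k"` takes the
#' last `k` points regardless and errors if any has frequency 0, and
#' `"explicit"` fits the concentrations given in `points`.
#'
#' @param curve A [frequency_curve()] result, or any data frame with columns
#'   `concentration` and `frequency` (optionally `censored`).
#' @param selection Point-selection rule: `"last_k_nonzero"` (default),
#'   `"last_k"`, or `"explicit"`.
#' @param k Number of points for the `last_k*` rules (default 4).
#' @param points Concentrations to use when `selection = "explicit"`.
#' @return An object of class `slope_fit`: `slope` and `slope_se` in log10
#'   frequency per mM, `intercept`, `n_points`, `points_used`, `r_squared`.
#' @examples
#' d <- data.frame(concentration = 1:4, frequency = 10^-(1:4))
#' decline_slope(d)$slope  # -1
#' @export
decline_slope <- function(curve,
                          selection = c("last_k_nonzero", "last_k",
                                        "explicit"),
                          k = 4, points = NULL) {
  selection <- match.arg(selection)
  if (!is.data.frame(curve) ||
      !all(c("concentration", "frequency") %in% names(curve))) {
    stop("`curve` needs columns `concentration` and `frequency`",
         call. = FALSE)
  }
  check_count(k, "k", lower = 2L)
  cv <- curve[order(curve$concentration), , drop = FALSE]
  cens <- if (is.null(cv$censored)) rep(FALSE, nrow(cv)) else cv$censored

  sel <- switch(selection,
    last_k_nonzero = {
      ok <- which(cv$frequency > 0 & !cens)
      utils::tail(ok, k)
    },
    last_k = {
      idx <- utils::tail(seq_len(nrow(cv)), k)
      if (any(cv$frequency[idx] <= 0)) {
        stop(paste0("selection `last_k` includes zero frequencies; use ",
                    "`last_k_nonzero`"), call. = FALSE)
      }
      idx
    },
    explicit = {
      if (is.null(points)) {
        stop("`points` required when selection = \"explicit\"", call. = FALSE)
      }
      idx <- match(points, cv$concentration)
      if (anyNA(idx)) stop("`points` not all present in curve", call. = FALSE)
      idx
    }
  )
  if (length(sel) < 2L) {
    stop("fewer than 2 usable points for the slope fit", call. = FALSE)
  }
  if (any(cv$frequency[sel] <= 0)) {
    stop("selected points include non-positive frequencies", call. = FALSE)
  }

  x <- cv$concentration[sel]
  y <- log10(cv$frequency[sel])
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  tss <- sum((y - mean(y))^2)
  # an exactly log-linear selection leaves only rounding noise in the
  # residuals; report it as the perfect fit it is (SE identically zero)
  if (rss < 1e-20 * max(tss, 1)) rss <- 0
  se <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NA_real_
  structure(
    list(slope = slope,
         intercept = intercept,
         slope_se = se,
         n_points = n,
         points_used = x,
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "<slope_fit> %.4g +/- %.3g log10 frequency / mM (n = %d, R^2 = %.3f)\n",
    x$slope, x$slope_se, x$n_points, x$r_squared))
  invisible(x)
}

#' Compare two decline slopes
#'
#' Two-sided Welch-type t test on the difference of two independently fitted
#' OLS slopes: `t = (slope_a - slope_b) / sqrt(se_a^2 + se_b^2)` with
#' Welch--Satterthwaite degrees of freedom built from the residual degrees
#' of freedom (`n_points - 2`) of each fit.
#'
#' @param a,b [decline_slope()] fits with at least 3 points each.
#' @return List with `t`, `df`, `p_value`, and the slope difference.
#' @export
compare_slopes <- function(a, b) {
  for (f in list(a, b)) {
    if (!inherits(f, "slope_fit")) {
      stop("`a` and `b` must be slope_fit objects", call. = FALSE)
    }
    if (f$n_points < 3L) {
      stop("slope comparison needs fits with >= 3 points", call. = FALSE)
    }
  }
  diff <- a$slope - b$slope
  se2 <- a$slope_se^2 + b$slope_se^2
  if (se2 == 0) {
    if (diff == 0) {
      return(list(t = 0, df = NA_real_, p_value = 1, slope_difference = 0))
    }
    warning("degenerate fits: both slope standard errors are zero")
    return(list(t = sign(diff) * Inf, df = NA_real_, p_value = 0,
                slope_difference = diff))
  }
  df_a <- a$n_points - 2
  df_b <- b$n_points - 2
  df <- se2^2 / (a$slope_se^4 / df_a + b$slope_se^4 / df_b)
  tstat <- diff / sqrt(se2)
  list(t = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df),
       slope_difference = diff)
}
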
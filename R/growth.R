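# Growth-curve kinetics: lag, exponential rate and maximum density from
# OD600 time series; presence/absence resistance summaries across
# formaldehyde concentration panels.

#' Fit lag, rate and maximum density to an OD time series
#'
#' The exponential rate is the maximum over sliding windows of the OLS slope
#' of `ln(OD)` versus time (default 5-point windows).  Lag is where that
#' tangent line re-crosses the initial OD level, clipped at 0.  Maximum OD is
#' the peak of a 3-point moving average.  Series that never achieve a
#' positive-slope window with OD gain above `min_gain` are flagged
#' `no_growth` with rate 0.
#'
#' @param times Time points, h (sorted, >= 5 points).
#' @param od Blank-subtracted OD600 values (a floor of `od_floor` is applied
#'   before the log transform).
#' @param window Points per sliding window (>= 3).
#' @param min_gain Minimum OD gain over the series to call growth.
#' @param od_floor Detection floor applied to OD before `log`.
#' @return Object of class `growth_fit`: `lag` (h), `rate` (per h),
#'   `max_od`, `od0`, `window` (the `[t_start, t_end]` used for the rate),
#'   `no_growth`.
#' @examples
#' fit_growth(0:10, 0.02 * exp(0.2 * (0:10)))
#' @export
fit_growth <- function(times, od, window = 5, min_gain = 0.01,
                       od_floor = 1e-4) {
  if (length(times) != length(od)) {
    stop("`times` and `od` must have equal length", call. = FALSE)
  }
  if (length(times) < 5L) stop("need >= 5 timepoints", call. = FALSE)
  if (is.unsorted(times)) stop("`times` must be sorted", call. = FALSE)
  check_count(window, "window", lower = 3L)
  if (window > length(times)) {
    stop("`window` exceeds the number of timepoints", call. = FALSE)
  }

  od_pos <- pmax(od, od_floor)
  logod <- log(od_pos)
  n <- length(times)
  nw <- n - window + 1L
  slopes <- numeric(nw)
  intercepts <- numeric(nw)
  for (i in seq_len(nw)) {
    j <- i:(i + window - 1L)
    cf <- stats::coef(stats::lm.fit(cbind(1, times[j]), logod[j]))
    intercepts[i] <- cf[1]
    slopes[i] <- cf[2]
  }
  best <- which.max(slopes)
  rate <- slopes[best]

  smooth3 <- stats::filter(od_pos, rep(1 / 3, 3), sides = 2)
  max_od <- max(smooth3, na.rm = TRUE)
  od0 <- od_pos[1]

  if (rate <= 0 || (max(od_pos) - od0) < min_gain) {
    return(structure(
      list(lag = NA_real_, rate = 0, max_od = max_od, od0 = od0,
           window = c(NA_real_, NA_real_), no_growth = TRUE),
      class = "growth_fit"))
  }
  lag <- (log(od0) - intercepts[best]) / rate
  lag <- max(lag, 0)
  structure(
    list(lag = lag, rate = rate, max_od = max_od, od0 = od0,
         window = c(times[best], times[best + window - 1L]),
         no_growth = FALSE),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$no_growth) {
    cat(sprintf("<growth_fit> no growth (max OD %.3g)\n", x$max_od))
  } else {
    cat(sprintf(
      "<growth_fit> lag %.2f h, rate %.4g /h (window %.4g-%.4g h), max OD %.3g\n",
      x$lag, x$rate, x$window[1], x$window[2], x$max_od))
  }
  invisible(x)
}

#' Summarize growth across a formaldehyde concentration panel
#'
#' Scores each concentration as permitting growth when the fitted OD gain
#' (`max_od - od0`) reaches `growth_threshold`, and reports the highest
#' permissive concentration.  When growth occurs at every tested
#' concentration the panel is right-censored (the true limit lies above the
#' tested range); when it occurs at none, `max_permissive` is `NA`.
#'
#' @param fits_by_conc Named list mapping concentration (mM, as names) to
#'   [fit_growth()] results; >= 2 concentrations.
#' @param growth_threshold OD gain needed to call growth (default 0.05).
#' @return List with `concentrations`, `grew` (logical), `max_permissive`
#'   (mM or `NA`), `right_censored`.
#' @export
resistance_summary <- function(fits_by_conc, growth_threshold = 0.05) {
  if (length(fits_by_conc) < 2L) {
    stop("need >= 2 concentrations", call. = FALSE)
  }
  if (is.null(names(fits_by_conc)) || anyNA(as.numeric(names(fits_by_conc)))) {
    stop("`fits_by_conc` must be named by numeric concentration",
         call. = FALSE)
  }
  check_number(growth_threshold, "growth_threshold", lower = 0)
  concs <- as.numeric(names(fits_by_conc))
  ord <- order(concs)
  concs <- concs[ord]
  fits <- fits_by_conc[ord]
  grew <- vapply(fits, function(f) {
    stopifnot(inherits(f, "growth_fit"))
    (f$max_od - f$od0) >= growth_threshold
  }, logical(1))
  list(concentrations = concs,
       grew = unname(grew),
       max_permissive = if (any(grew)) max(concs[grew]) else NA_real_,
       right_censored = all(grew))
}
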
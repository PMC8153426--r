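# Serial-dilution spot plating: CFU/mL estimation and replicate pooling.

#' Construct one replicate serial-dilution spot series
#'
#' A spot series is the set of colony counts obtained when one sample is
#' serially diluted (1:10 steps, base 10) and a fixed volume of each dilution
#' is spotted onto an agar plate.  Counts are recorded per dilution exponent
#' (0 for undiluted, -1 for 1:10, ... down to -6).  Spots too crowded to count
#' are recorded as `Inf` (the TNTC -- "too numerous to count" -- sentinel;
#' CSV readers map the string `"TNTC"` to `Inf`).
#'
#' @param counts Numeric vector of colony counts, one per exponent.
#'   Non-negative integers, or `Inf` for TNTC spots.
#' @param dilution_exponents Integer vector of base-10 dilution exponents,
#'   strictly decreasing (e.g. `0:-6`).  The plated dilution fraction of a
#'   spot with exponent `e` is `10^e`.
#' @param spot_volume Plated volume per spot in mL (default 0.010, a 10 uL
#'   spot).
#' @param sample_id,replicate_id Identifiers carried through to estimates.
#' @return An object of class `spot_series`.
#' @examples
#' spot_series(c(Inf, Inf, Inf, Inf, 180, 20, 2))
#' @export
spot_series <- function(counts, dilution_exponents = 0:-6,
                        spot_volume = 0.010,
                        sample_id = "sample", replicate_id = "r1") {
  if (length(counts) == 0L) {
    stop("empty spot series: at least one spot must be counted", call. = FALSE)
  }
  if (length(counts) != length(dilution_exponents)) {
    stop("`counts` and `dilution_exponents` must have equal length",
         call. = FALSE)
  }
  if (any(diff(dilution_exponents) >= 0)) {
    stop("`dilution_exponents` must be strictly decreasing", call. = FALSE)
  }
  if (any(is.na(counts)) ||
      any(is.finite(counts) & (counts < 0 | counts != round(counts)))) {
    stop("`counts` must be non-negative integers (or Inf for TNTC)",
         call. = FALSE)
  }
  check_number(spot_volume, "spot_volume", lower = 0, strict_lower = TRUE)
  structure(
    list(sample_id = as.character(sample_id),
         replicate_id = as.character(replicate_id),
         dilution_exponents = as.integer(dilution_exponents),
         counts = as.numeric(counts),
         spot_volume = spot_volume),
    class = "spot_series"
  )
}

#' @export
print.spot_series <- function(x, ...) {
  cat(sprintf("<spot_series> %s / %s, %g mL spots\n",
              x$sample_id, x$replicate_id, x$spot_volume))
  cnt <- ifelse(is.finite(x$counts), format(x$counts), "TNTC")
  print(stats::setNames(cnt, sprintf("10^%d", x$dilution_exponents)))
  invisible(x)
}

#' Estimate CFU/mL from a serial-dilution spot series
#'
#' Implements the spot-enumeration rule used for tolerance plating.  The
#' first spot (scanning from least to most dilute) whose count falls at or
#' below the crowding limit `countable_range[2]` anchors the estimate: its
#' count and the count of the next, more-dilute spot (however small) are
#' summed, and the density is the pooled count divided by
#' `1.1 * d * spot_volume`, where `d` is the plated dilution fraction of the
#' anchor.  In a 10-fold series the pair are the two most-dilute spots with
#' reliably countable colonies -- everything less dilute is crowded -- and
#' together they plate `1.1 * d * spot_volume` mL of undiluted sample, so
#' the estimator is unbiased under Poisson counting.  Anchoring at the
#' crowding boundary (a high-count spot, where Poisson noise cannot sway the
#' selection) rather than on whether a sparse terminal spot happens to clear
#' the countable minimum is what preserves that unbiasedness.  When the
#' anchor is the terminal dilution the single-spot estimate
#' `count / (d * spot_volume)` is used.  Estimates whose pooled count falls
#' below `countable_range[1]` are flagged `below_range`; a series with no
#' colonies at all is censored (reported as 0; the assay's detection limit
#' applies downstream).  Non-adjacent pairs (a gap in the series)
#' generalize the 1.1 factor to `1 + 10^(e_partner - e_anchor)`.
#'
#' @param series A [spot_series()].
#' @param countable_range Length-2 numeric, the colony-count window treated
#'   as reliably countable on one spot (default 3--150 for a 10 uL spot).
#' @param literal_1p1_multiplier Logical; if `TRUE`, apply the enumeration
#'   rule as often transcribed in protocols -- pooled count *multiplied* by
#'   1.1 times the dilution fold -- instead of the unbiased form.  The two
#'   readings differ by a constant factor of 1.21, which cancels from all
#'   frequency (ratio) statistics.
#' @return An object of class `cfu_estimate` with fields `cfu_per_ml`,
#'   `pooled_count`, `dilutions_used`, `censored`, `below_range`, `method`.
#' @examples
#' s <- spot_series(c(Inf, Inf, Inf, Inf, 180, 20, 2))
#' estimate_cfu(s)$cfu_per_ml  # 2e8
#' @export
estimate_cfu <- function(series, countable_range = c(3, 150),
                         literal_1p1_multiplier = FALSE) {
  if (!inherits(series, "spot_series")) {
    stop("`series` must be a spot_series object", call. = FALSE)
  }
  if (length(countable_range) != 2L || countable_range[1] < 1 ||
      diff(countable_range) <= 0) {
    stop("`countable_range` must be c(min, max) with min >= 1", call. = FALSE)
  }
  cnt <- series$counts
  exps <- series$dilution_exponents
  v <- series$spot_volume

  most_dilute <- which.min(exps)
  if (is.infinite(cnt[most_dilute])) {
    stop("unresolvable series: the most dilute spot is TNTC", call. = FALSE)
  }
  if (all(cnt[is.finite(cnt)] == 0) && !any(is.infinite(cnt))) {
    return(new_cfu_estimate(series, cfu = 0, pooled = 0L, used = integer(),
                            censored = TRUE, method = "censored"))
  }

  scale_fun <- function(pooled, d, pair_factor) {
    if (literal_1p1_multiplier && pair_factor != 1) {
      pooled * pair_factor / (d * v)
    } else {
      pooled / (pair_factor * d * v)
    }
  }
  ord <- order(-exps)  # least -> most dilute
  noncrowded <- is.finite(cnt) & cnt <= countable_range[2]

  if (any(noncrowded)) {
    anchor <- which(noncrowded)[which.max(exps[noncrowded])]
  } else {
    # every spot is above the crowding limit yet the terminal one is finite:
    # that terminal count is the only readable spot
    anchor <- most_dilute
  }
  pos <- match(anchor, ord)
  partner <- if (pos < length(ord)) ord[pos + 1L] else NA_integer_
  d <- 10^exps[anchor]

  if (!is.na(partner) && is.finite(cnt[partner])) {
    pooled <- cnt[anchor] + cnt[partner]
    pf <- 1 + 10^(exps[partner] - exps[anchor])  # 1.1 for adjacent spots
    est <- new_cfu_estimate(series, cfu = scale_fun(pooled, d, pf),
                            pooled = pooled,
                            used = exps[c(anchor, partner)],
                            censored = FALSE, method = "paired")
  } else {
    est <- new_cfu_estimate(series, cfu = scale_fun(cnt[anchor], d, 1),
                            pooled = cnt[anchor], used = exps[anchor],
                            censored = FALSE, method = "single")
  }
  est$below_range <- est$pooled_count < countable_range[1]
  est
}

new_cfu_estimate <- function(series, cfu, pooled, used, censored, method) {
  structure(
    list(sample_id = series$sample_id, replicate_id = series$replicate_id,
         cfu_per_ml = cfu, pooled_count = pooled, dilutions_used = used,
         censored = censored, below_range = FALSE, method = method),
    class = "cfu_estimate"
  )
}

#' @export
print.cfu_estimate <- function(x, ...) {
  cat(sprintf("<cfu_estimate> %s/%s: %.4g CFU/mL (%s%s)\n",
              x$sample_id, x$replicate_id, x$cfu_per_ml, x$method,
              if (x$censored) ", censored" else ""))
  invisible(x)
}

#' Pool replicate CFU estimates
#'
#' Technical replicates are averaged per biological replicate, and biological
#' replicates are averaged per condition: this helper does one level of that
#' pooling.  Censored members (no colonies on any spot) enter the mean as 0
#' and raise the `any_censored` flag so downstream frequency curves can mark
#' the point as below the detection limit.
#'
#' @param estimates A list of [estimate_cfu()] results, or a numeric vector
#'   of CFU/mL values.
#' @return A list with `mean`, `sd` (sample SD, `n - 1` denominator), `n`,
#'   `n_censored` and `any_censored`.
#' @export
pool_replicates <- function(estimates) {
  if (is.numeric(estimates)) {
    vals <- estimates
    cens <- rep(FALSE, length(vals))
  } else if (is.list(estimates) && length(estimates) > 0 &&
             all(vapply(estimates, inherits, logical(1), "cfu_estimate"))) {
    vals <- vapply(estimates, `[[`, numeric(1), "cfu_per_ml")
    cens <- vapply(estimates, `[[`, logical(1), "censored")
  } else {
    stop("`estimates` must be cfu_estimate objects or a numeric vector",
         call. = FALSE)
  }
  if (length(vals) == 0L) stop("empty replicate group", call. = FALSE)
  list(mean = mean(vals),
       sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
       n = length(vals),
       n_censored = sum(cens),
       any_censored = any(cens))
}
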
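# Pairwise-competition Malthusian relative fitness from flow-cytometry
# fluorescent/non-fluorescent event counts.

#' Test-strain fractions from flow-cytometry event counts
#'
#' Converts fluorescent-positive event counts at the start (`t0`) and end
#' (`t1`) of a competition into the test strain's population fraction at each
#' time.  When the reference strain carries the fluorophore (mCherry, the
#' usual setup) the test strain is the non-fluorescent population and
#' `F = 1 - positives/total`; set `test_is_nonfluorescent = FALSE` if the
#' test strain itself fluoresces.
#'
#' @param positives_t0,total_t0,positives_t1,total_t1 Event counts.  Totals
#'   below 1000 trigger a warning (the assay's counting floor), not an
#'   error.
#' @param test_is_nonfluorescent Logical, see above (default `TRUE`).
#' @return List with `F0` and `F1`, the test-strain fractions.
#' @export
gate_fractions <- function(positives_t0, total_t0, positives_t1, total_t1,
                           test_is_nonfluorescent = TRUE) {
  frac <- function(pos, tot, label) {
    check_count(pos, paste0("positives_", label))
    check_count(tot, paste0("total_", label), lower = 1L)
    if (pos > tot) {
      stop(sprintf("positives exceed total events at %s", label),
           call. = FALSE)
    }
    if (tot < 1000) {
      warning(sprintf("only %d events at %s; below the 1,000-event counting floor",
                      tot, label))
    }
    f <- pos / tot
    if (test_is_nonfluorescent) f <- 1 - f
    if (f <= 0 || f >= 1) {
      stop(sprintf("fixation at %s (fraction %g): competition is censored",
                   label, f), call. = FALSE)
    }
    if (f > 0.99 || f < 0.01) {
      warning(sprintf("near-fixation fraction %g at %s", f, label))
    }
    f
  }
  list(F0 = frac(positives_t0, total_t0, "t0"),
       F1 = frac(positives_t1, total_t1, "t1"))
}

#' Malthusian relative fitness from a pairwise competition
#'
#' Computes `W = log(F1 * E / F0) / log((1 - F1) * E / (1 - F0))`, the ratio
#' of the realized log-expansions of the test strain (fraction `F0` at the
#' start, `F1` at the end) and the reference strain, given an overall
#' `E`-fold expansion of the mixed population over the competition cycle
#' (64-fold for a 1/64 subculture on methanol; 32-fold on formaldehyde).
#' `W = 1` means neutrality; the value is independent of the logarithm base.
#'
#' @param F0,F1 Test-strain fractions in (0, 1) at start and end.
#' @param expansion Fold expansion `E` of the whole population (> 1).
#' @return The fitness `W` (dimensionless).
#' @examples
#' malthusian_fitness(0.5, 0.6, 64)  # log(76.8)/log(51.2)
#' @export
malthusian_fitness <- function(F0, F1, expansion = 64) {
  check_number(F0, "F0", lower = 0, upper = 1)
  check_number(F1, "F1", lower = 0, upper = 1)
  if (F0 <= 0 || F0 >= 1 || F1 <= 0 || F1 >= 1) {
    stop("F0 and F1 must lie strictly inside (0, 1)", call. = FALSE)
  }
  check_number(expansion, "expansion", lower = 1, strict_lower = TRUE)
  if (F1 == F0) return(1)
  num_arg <- F1 * expansion / F0
  den_arg <- (1 - F1) * expansion / (1 - F0)
  if (num_arg <= 1 || den_arg <= 0) {
    stop("impossible-growth configuration: log arguments out of domain",
         call. = FALSE)
  }
  if (den_arg == 1) {
    stop("reference strain shows zero net log-expansion; W undefined",
         call. = FALSE)
  }
  log(num_arg) / log(den_arg)
}

#' Fitness for a table of competitions
#'
#' Vectorized convenience wrapper: one row per competition with event counts
#' and expansion factor, as produced by [read_competition_csv()] or
#' [sim_competition()].
#'
#' @param data Data frame with columns `positives_t0`, `total_t0`,
#'   `positives_t1`, `total_t1`, `expansion`.
#' @param test_is_nonfluorescent Passed to [gate_fractions()].
#' @return `data` with columns `F0`, `F1` and `W` appended.
#' @export
competition_fitness <- function(data, test_is_nonfluorescent = TRUE) {
  need <- c("positives_t0", "total_t0", "positives_t1", "total_t1",
            "expansion")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop("`data` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  res <- lapply(seq_len(nrow(data)), function(i) {
    fr <- gate_fractions(data$positives_t0[i], data$total_t0[i],
                         data$positives_t1[i], data$total_t1[i],
                         test_is_nonfluorescent = test_is_nonfluorescent)
    c(F0 = fr$F0, F1 = fr$F1,
      W = malthusian_fitness(fr$F0, fr$F1, data$expansion[i]))
  })
  cbind(data, do.call(rbind, res))
}
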
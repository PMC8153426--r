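# Colorimetric formaldehyde quantification (Nash 432 nm, Purpald 550 nm),
# intracellular normalization, and the heavy-methionine translation ratio.

#' Fit a colorimetric standard curve
#'
#' Ordinary least squares of absorbance on standard concentration, for the
#' Nash (432 nm) or Purpald (550 nm) formaldehyde assays.  Standards are
#' prepared fresh and run alongside every sample batch, so a curve object is
#' expected per batch.
#'
#' @param concentration Standard concentrations, mM (>= 3 distinct values).
#' @param absorbance Measured absorbances, same length.
#' @param assay `"nash"` or `"purpald"` (label only).
#' @return Object of class `calibration` with `slope` (absorbance per mM),
#'   `intercept`, `r_squared`, `n_standards`, `assay`.
#' @examples
#' fit_standard_curve(0:2, c(0, 0.5, 1.0))
#' @export
fit_standard_curve <- function(concentration, absorbance,
                               assay = c("nash", "purpald")) {
  assay <- match.arg(assay)
  if (length(concentration) != length(absorbance)) {
    stop("`concentration` and `absorbance` must have equal length",
         call. = FALSE)
  }
  if (length(unique(concentration)) < 3L) {
    stop("need >= 3 distinct standard concentrations", call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) {
    warning("standard-curve slope is not positive; check assay orientation")
  }
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((absorbance - mean(absorbance))^2)
  structure(
    list(assay = assay, slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         n_standards = length(concentration)),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %s: A = %.4g * mM + %.4g (R^2 = %.4f, n = %d)\n",
              x$assay, x$slope, x$intercept, x$r_squared, x$n_standards))
  invisible(x)
}

#' Back-calculate concentration from absorbance
#'
#' Inverts a standard curve: `conc = dilution_factor * (A - intercept) /
#' slope`.  Absorbances below the blank (intercept) back-calculate negative;
#' those are floored at 0 and flagged, since a concentration cannot be
#' negative.
#'
#' @param cal A [fit_standard_curve()] result.
#' @param absorbance Sample absorbances.
#' @param dilution_factor Fold dilution applied to the sample before the
#'   assay (>= 1; e.g. 10 for a 0.1X supernatant).
#' @return Data frame with `concentration` (mM) and `below_blank` flags.
#' @export
conc_from_absorbance <- function(cal, absorbance, dilution_factor = 1) {
  stopifnot(inherits(cal, "calibration"))
  if (cal$slope <= 0) {
    stop("invalid calibration: slope must be positive", call. = FALSE)
  }
  check_number(dilution_factor, "dilution_factor", lower = 1)
  conc <- dilution_factor * (absorbance - cal$intercept) / cal$slope
  below <- conc < 0
  data.frame(concentration = pmax(conc, 0), below_blank = below)
}

#' Intracellular concentration from a lysate measurement
#'
#' Normalizes the formaldehyde concentration measured in a cell lysate to
#' the total intracellular volume of the harvested cells:
#' `C_int = C_lysate * extraction_volume /
#'   (cfu_per_ml * culture_volume * cell_volume)`,
#' with `cell_volume` (fL per CFU) converted to mL.  `cfu_per_ml` is the
#' density of the culture the lysate came from (usually back-calculated
#' from OD600 with a per-strain CFU-per-OD calibration constant).
#'
#' @param lysate_conc Formaldehyde concentration of the lysate, mM.
#' @param cfu_per_ml Culture density, CFU/mL.
#' @param extraction_volume Lysate extraction volume, mL (default 1.5).
#' @param culture_volume Harvested culture volume, mL (default 50).
#' @param cell_volume Mean single-cell volume, fL/CFU (default 2.63).
#' @return Intracellular concentration, mM.
#' @examples
#' intracellular_concentration(0.01, 2e8)  # ~0.570 mM
#' @export
intracellular_concentration <- function(lysate_conc, cfu_per_ml,
                                        extraction_volume = 1.5,
                                        culture_volume = 50,
                                        cell_volume = 2.63) {
  check_number(lysate_conc, "lysate_conc", lower = 0)
  check_number(cfu_per_ml, "cfu_per_ml", lower = 0)
  if (cfu_per_ml <= 0) {
    stop("zero CFU density: intracellular normalization undefined",
         call. = FALSE)
  }
  check_number(extraction_volume, "extraction_volume", lower = 0,
               strict_lower = TRUE)
  check_number(culture_volume, "culture_volume", lower = 0,
               strict_lower = TRUE)
  check_number(cell_volume, "cell_volume", lower = 0, strict_lower = TRUE)
  lysate_conc * extraction_volume /
    (cfu_per_ml * culture_volume * cell_volume * 1e-12)  # fL -> mL
}

#' Heavy-methionine incorporation ratio
#'
#' Ratio of the 222 m/z (13CD3-labeled methionine) to 218 m/z (unlabeled
#' methionine) GC/MS peak areas; the ratio rises as newly synthesized
#' protein incorporates the label, so a time series of ratios tracks
#' ongoing translation.
#'
#' @param peak_218 Unlabeled-Met peak area (> 0).
#' @param peak_222 Labeled-Met peak area (>= 0); may be a vector over
#'   timepoints paired with `peak_218`.
#' @return Labeled/unlabeled ratio(s).
#' @export
met_incorporation <- function(peak_218, peak_222) {
  if (any(peak_218 <= 0)) {
    stop("`peak_218` must be > 0: ratio undefined without the unlabeled peak",
         call. = FALSE)
  }
  if (any(peak_222 < 0)) stop("peak areas must be >= 0", call. = FALSE)
  peak_222 / peak_218
}
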
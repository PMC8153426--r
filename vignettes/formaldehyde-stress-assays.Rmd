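---
title: "Models and methods behind the formaldehyde stress-response assay panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the formaldehyde stress-response assay panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formstress)
```

# Scope

Methylotrophic bacteria such as *Methylorubrum extorquens* live on one-carbon
compounds and route all of their methanol-derived carbon through free
formaldehyde, a potently electrophilic metabolite.  Studying how such cells
sense formaldehyde, how genetically identical cells differ in the
concentration they tolerate, and how regulator proteins such as the
DUF336-family formaldehyde sensor EfgA bind the molecule requires a panel of
quantitative assays: dilution plating, spot-based tolerance distributions,
flow-cytometry competitions, calorimetric and thermophoretic binding
titrations, colorimetric formaldehyde chemistry, and growth kinetics.

`formstress` implements the estimators and model fits for that panel, plus a
seeded synthetic generator for each assay so that every estimator can be
exercised, calibrated and regression-tested without instrument data.  This
vignette records the models, the defaults and the reasoning behind the design
decisions; it states no empirical result that the package's test suite does
not itself compute.

# Dilution plating and CFU estimation

A sample is diluted in 1:10 steps (exponents 0 to −6) and a fixed
`spot_volume` (default 0.010 mL) of each dilution is spotted on agar.  Colony
counts on a spot at dilution fraction $d$ are modelled as Poisson with mean
$\lambda \, v \, d$, where $\lambda$ is the true density (CFU/mL).

`estimate_cfu()` scans from the least dilute spot and anchors at the first
spot whose count is at or below the crowding limit (`countable_range[2]`,
default 150 colonies per 10 µL spot).  The anchor count $c_a$ and the count
of the next, more-dilute spot $c_{a+1}$ are pooled and

$$\hat\lambda = \frac{c_a + c_{a+1}}{1.1 \, d_a \, v},$$

because the pair jointly plates $1.1\,d_a v$ mL of undiluted sample
($d_{a+1} = d_a/10$).  Two properties motivated anchoring at the *crowding*
boundary rather than at a lower-count threshold:

* **Unbiasedness.** $E[c_a + c_{a+1}] = 1.1 \lambda v d_a$ holds exactly
  whenever the anchor choice is independent of the counts being summed.  The
  crowding decision is made on spots carrying hundreds of colonies, where
  Poisson noise essentially never flips the comparison, so the selection is
  effectively exogenous.  Any rule that instead promotes the terminal spot to
  anchor when its (tiny, noisy) count happens to clear a minimum introduces a
  conditioning bias that simulation puts at roughly +25% at a typical
  stationary-phase density of $2\times10^8$ CFU/mL — far outside the 2%
  unbiasedness the estimator is tested to.
* **Fidelity.** In a monotone 10-fold series the anchor pair are exactly "the
  two most-dilute spots with countable colonies": everything less dilute is
  crowded, and the partner is allowed any count, however small.

The lower end of `countable_range` (default 3) only flags estimates whose
pooled count is too sparse to be individually reliable (`below_range`); a
series with no colonies at all is *censored* and reported as 0, to be
interpreted against the assay's detection limit.  The enumeration rule is
sometimes transcribed with the 1.1 factor as a multiplier; that reading is
available (`literal_1p1_multiplier = TRUE`) and differs by the constant
1.21, which cancels from every frequency because frequencies are ratios of
estimates.

`pool_replicates()` averages technical or biological replicates with a
sample (n−1) standard deviation, counting censored members as 0 and
propagating the censoring flag.

# Tolerance frequency distributions

Formaldehyde *tolerance* is a nongenetic, per-cell trait: the highest
formaldehyde concentration at which a given cell can still found a colony.
Plating a clonal population on a series of formaldehyde agar concentrations
and dividing the CFU density at each concentration by the density on
formaldehyde-free plates yields the frequency of tolerant cells,

$$f(c) = \frac{\mathrm{CFU}(c)}{\mathrm{CFU}(0)},$$

built by `frequency_curve()` with $f(0) = 1$ by construction and per-point
SDs taken across replicate spot series.

**Limit of detection.** With $k$ replicate spots of volume $v$, one cell is
expected in the plated volume at a density of $1/(k v)$ CFU/mL
(`detection_limit()`; 33.3, reported as the ceiling 34, for three 10 µL
spots).  Dividing by the total population density ($2\times10^8$ CFU/mL for
a stationary-phase culture) gives the minimum observable frequency.  Whether
the numerator is left unrounded (1.67e-7) or rounded down/up first
(1.65e-7 / 1.7e-7) is a presentation convention with no analytical
consequence, so it is an explicit argument (`frequency_basis`) rather than a
hidden choice.  Frequencies at fully censored concentrations are stored as 0
with a flag, and never enter slope fits under the default selection rule.

**Decline slope.** The summary statistic for a curve's shape is the OLS
slope of $\log_{10} f$ on concentration over a selected tail of the curve
(`decline_slope()`), in log10 frequency per mM.  Point selection follows the
conventions used on real curves — the last $k$ non-zero points (default
$k = 4$) for steep wild-type-like curves, or the last $k$ points outright
for shallower curves with no censored tail — and is a parameter, not an
automatic changepoint search, so that what was fitted is always explicit.
When the selected points are exactly collinear the residual sum of squares
is rounding noise (~1e-30); it is reported as the perfect fit it is, with a
slope SE of exactly zero, so degenerate comparisons are detected cleanly.

**Comparing slopes.** `compare_slopes()` uses a two-sided Welch-type t
statistic on two independent OLS slopes,
$t = (b_1 - b_2)/\sqrt{s_1^2 + s_2^2}$, with Welch–Satterthwaite degrees of
freedom assembled from each fit's residual degrees of freedom
($n_i - 2$).  No standard test is canonical for this design; Welch-on-slopes
is the minimal defensible choice, and its type-I error is verified by
simulation (2,000 null replicates; the observed rate sits near 0.03–0.05,
mildly conservative at these very small degrees of freedom, inside the
[0.03, 0.07] acceptance band).  Degenerate inputs (both SEs zero) return
p = 1 for equal slopes and p = 0 with a warning otherwise.

# Competition fitness

In a pairwise competition a test strain is mixed with a fluorescent
reference, the mixture is diluted 1/E into fresh medium, grown to
stationary phase (an overall E-fold expansion; 64 under the standard
subculture regime, 32 when formaldehyde is the carbon source), and the
test-strain fraction is measured by flow cytometry before ($F_0$) and after
($F_1$), counting at least 1,000 events.  Malthusian relative fitness is

$$W = \frac{\log(F_1 E / F_0)}{\log((1 - F_1) E / (1 - F_0))},$$

the ratio of the two strains' realized log expansions: `malthusian_fitness()`.
$W$ is independent of the log base (both logs scale together), equals 1
exactly at $F_1 = F_0$, and is strictly increasing in $F_1$.  Which
population the fractions refer to is a stated flag
(`test_is_nonfluorescent`, default `TRUE`, matching an mCherry-bearing
reference).  Fractions at exactly 0 or 1 (fixation) are rejected rather than
pseudo-counted: the formula is undefined there and no finite correction is
defensible from count data alone.  Totals below 1,000 events warn but do not
error — the floor is an assay convention, not a mathematical requirement.
No correction is applied for realized expansions that deviate from the
nominal E; the nominal value is part of the assay definition.

# Binding models

## Isothermal titration calorimetry

The calorimeter protocol (`itc_protocol()`) defaults to 20 injections of
2 µL of 25 mM ligand into a 400 µL cell of 50 µM protein at 25 °C, the
first injection being a 0.3 µL throw-away whose heat is flagged and excluded
from every fit, per universal ITC practice.  The forward model
(`itc_forward()`) is the single-set-of-sites ("independent binding")
isotherm: with displaced-volume-corrected totals

$$M_i = M_0\,\frac{1 - v_i/2V_0}{1 + v_i/2V_0}, \qquad
  L_i = L_{syr}\,\frac{v_i}{V_0}\left(1 - \frac{v_i}{2V_0}\right),$$

the cumulative heat after injection $i$ is

$$Q_i = \frac{n M_i \Delta H V_0}{2}\left[1 + \frac{L_i}{n M_i} +
  \frac{K_d}{n M_i} - \sqrt{\left(1 + \frac{L_i}{n M_i} +
  \frac{K_d}{n M_i}\right)^2 - \frac{4 L_i}{n M_i}}\right]$$

and the measured per-injection heat corrects for liquid displaced into the
overfill stem, $\Delta Q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2$.
This is the convention implemented by commercial ITC software; heats are
µJ internally and $\Delta H$ converts to kcal/mol (1 cal = 4.184 J) at the
interface.  The model reproduces its closed-form limits: all-zero heats at
$\Delta H = 0$, $\Delta Q_i = \Delta H \times$ (moles injected) before
equivalence as $K_d \to 0$, a saturation plateau of $n \Delta H M_i V_0$,
and a tight-binding equivalence knee at molar ratio $L/M = n$.

Blank subtraction (`subtract_blank()`) removes the measured buffer:ligand
dilution heat injection-by-injection; units must match (no silent
conversion).  `fit_itc()` does nonlinear least squares with a robust
two-stage start: because the model is linear in $\Delta H$ given $(n, K_d)$,
a log-spaced $K_d$ profile with closed-form $\Delta H$ seeds a
Levenberg–Marquardt refinement on $(\Delta H, \log K_d[, n])$.

A structural point matters at this protocol: the Wiseman parameter
$c = n M / K_d$ is ≈ 0.006 for a millimolar-affinity ligand at 50 µM
protein.  In this weak-binding regime the isotherm is nearly
$Q \propto n \Delta H \cdot L/(L + K_d)$ — stoichiometry and enthalpy enter
only as a product, so $n$ cannot be separated from $\Delta H$ by the data.
Fixing $n = 1$ (`fix_n = 1`) is the standard low-c practice and is what the
package's simulation studies use; the free-$n$ fit remains the default and
recovers all three parameters exactly on noise-free data, where the
second-order terms suffice.  Saturated-from-start titrations
($c > 10^4$) and flat thermograms raise explicit warnings because $K_d$ is
then unidentifiable.

## Microscale thermophoresis

MST reports normalized fluorescence against titrant concentration, fitted by
`fit_hill()` to

$$F(c) = F_{min} + (F_{max} - F_{min})\,\frac{c^n}{c^n + K_d^n}.$$

The additive $F_{min}$ baseline is included by default: normalized MST
fluorescence at zero titrant is a large nonzero number (per-mil units,
typically 800–1000), so a bare saturation term cannot describe the data.
The bare form is nonetheless available (`baseline = FALSE`) for comparison
with analyses that used the literal equation; in that form only the
amplitude $F_{max} - F_{min}$ is identifiable, so the fit estimates the
amplitude and reports $F_{min} = 0$.  The fitted abscissa is the *titrant*
(formaldehyde) concentration — the species being varied — not the labelled
protein, whose concentration is constant by design.  Start values come from
the data (extreme responses, the concentration nearest half-response,
$n = 1$); flat curves are rejected, and a response whose trend contradicts
the fitted orientation warns.

# Colorimetric quantification and translation ratios

Formaldehyde assays (Nash, read at 432 nm; Purpald, 550 nm) are calibrated
per batch by an OLS line of absorbance on standard concentration
(`fit_standard_curve()`, ≥3 distinct standards; weighted or curved fits are
deliberately out of scope).  `conc_from_absorbance()` inverts the line with
an explicit dilution factor; back-calculated negatives are floored at 0 and
flagged `below_blank` — per-well back-calculation happens before any
averaging, so technical replicates are averaged on the concentration scale.
Intracellular concentration normalizes a lysate measurement to total cell
volume:

$$C_{int} = \frac{C_{lysate} \times V_{extraction}}
  {\mathrm{CFU/mL} \times V_{culture} \times V_{cell}},$$

with defaults 1.5 mL extraction, 50 mL culture and 2.63 fL per CFU
(`intracellular_concentration()`; 1 fL = 10⁻¹² mL, result in mM).  The
CFU/mL of the harvested culture is an input, typically back-calculated from
OD600 with a strain-specific CFU-per-OD constant that the user supplies.
Translation activity is tracked by the GC/MS peak-area ratio of
heavy-labelled to unlabelled methionine (222/218 m/z,
`met_incorporation()`); the ratio is oriented labelled-over-unlabelled so it
rises as new protein is made.

# Growth kinetics

`fit_growth()` estimates the exponential rate as the maximum over sliding
windows (default 5 points) of the OLS slope of ln OD against time, the lag
as the time where that tangent re-crosses the initial OD (clipped at 0), and
the maximum density as the peak of a 3-point moving average.  The rate is
invariant to rescaling the OD series.  One inherent property to keep in
mind: on a logistic trajectory the window slope is depressed by the factor
$(1 - \mathrm{OD}/K)$, so when the series starts at 2% of carrying capacity
the recovered rate sits roughly 2% below the generating rate; round-trip
calibration tests therefore use a smaller initial density (0.5% of $K$),
where the bias is within 1%.  Series with no positive-slope window or less
than `min_gain` total OD gain are flagged `no_growth` rather than fitted.
`resistance_summary()` turns per-concentration fits into a presence/absence
panel with a growth threshold (default ΔOD 0.05) and reports the highest
permissive concentration, flagging right-censoring when growth occurs at
every tested concentration.

# Synthetic data: what it emulates, and what it does not

Each generator draws from the minimal noise model for its measurement class,
under a mandatory seed with no global RNG state:

* colony counts: Poisson at `density × volume × 10^exponent`
  (`sim_spot_series()`, `sim_tolerance_counts()`);
* flow-cytometry positives: binomial at the true fraction
  (`sim_competition()`, with `F1 = F0 f_t / (F0 f_t + (1-F0) f_r)` and true
  `W = log f_t / log f_r`);
* instrument signals (MST response, ITC heats, OD reads): model value plus
  additive Gaussian noise.

The tolerance model (`tolerance_model()`) is flat at frequency 1 up to a
breakpoint, then declines log-linearly (slope in log10/mM) to a floor.  This
mirrors the decline-slope statistic used on real curves; it is an
operational emulation, not a claim about the underlying single-cell
biology, whose true distribution shape is unknown.

Noise defaults are fixed study conditions, chosen once as
instrument-realistic: ITC injections carry 0.25 µJ Gaussian noise and a
−2 µJ dilution heat (sub-µJ integration error typical of modern low-volume
calorimeters with clean isotherms; blanks carry independent noise of the
same size, so blank subtraction doubles the variance); MST points carry
1 per-mil noise on a 50 per-mil response amplitude (2%); a tolerance plating
run uses triplicate 10 µL spots at a base density of 2×10⁸ CFU/mL.

Passing round-trip and recovery tests on these generators shows that the
estimators are correctly implemented and well calibrated *under the assumed
noise laws*.  It does not show robustness to what real instruments add on
top: baseline drift and peak-integration artefacts in calorimetry,
aggregation and capillary effects in MST, colony merging and counting error
on crowded spots, cytometry gating error, or condensation/evaporation on
plates.  Those failure modes must still be judged from the raw data.

# Test and simulation scales

The package's own calibration studies are sized to be decisive yet quick:
1,000 Poisson plating simulations for estimator unbiasedness (2% band),
2,000 null replicates for the slope-test type-I error ([0.03, 0.07] band at
α = 0.05), 200 noisy titrations each for MST $K_d$ and ITC $\Delta H$
recovery (≥95% within the assays' quoted uncertainties of ±3.5 mM and
±1.16 kcal/mol), and 100–500 replicates for the remaining bias checks.
Deterministic round trips (forward model → fit) are asserted to 6
significant figures or better.

# Known limitations

* No most-probable-number (MPN) likelihood across all dilutions; the
  spot-pair estimator is the assay's own rule, implemented faithfully.
* The slope comparison treats the two fitted slopes as independent normals;
  with 4-point fits the Welch approximation is conservative.
* ITC fitting starts from per-injection heats: raw power traces, peak
  integration and baseline correction are upstream of this package, as is
  FCS gating for cytometry and chromatogram integration for GC/MS.
* Competitions are strictly pairwise; multi-strain mixtures are out of
  scope.
* The growth model has no death phase, and the lag estimate is operational
  (tangent intersection), not mechanistic: under formaldehyde stress an
  apparent lag can conflate killing with regrowth of tolerant
  subpopulations.
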
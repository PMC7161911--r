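---
title: "Cassava growth simulation and its global sensitivity analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cassava growth simulation and its global sensitivity analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cassim)
```

This vignette is the package's own account of the science it implements:
the crop model and its assumptions, the probability layer over the
genotype-specific parameters (GSPs), the screening and variance-based
sensitivity machinery, and — most importantly for a re-implementation —
the places where the design was genuinely open and what we chose there.

## 1. The crop model

Cassava is an indeterminate crop: no grain filling phase, no physiological
maturity. The simulator therefore has no phenological stages beyond
germination and a sequence of branching events, and it runs day by day
from 30 days before planting (soil water spin-up at field capacity) to a
fixed harvest at planting + 300 days.

**Thermal time.** All development is driven by
`max(0, (tmax + tmin)/2 − Tb)` with process-specific base temperatures:
leaf development uses the genotype's `TBLSZ` (a GSP, uniform 11–17 °C);
branching, node growth and leaf aging use a species default of 13 °C. We
deliberately use the daily-mean-minus-base form with no optimum or ceiling
temperature: the sources give base temperatures only, and an upper cardinal
would be invented structure. The form is isolated in one exported function
(`thermal_time()`) so a cardinal-curve refinement stays local.

**Branching and cohorts.** The crop forks from level L to L+1 when
cumulative branching thermal time reaches `B01ND + L·B12ND` (at most four
levels), multiplying the apex count by the rounded `BR(L+1)F`. Each day all
apices jointly produce a node cohort at the rate
`LNSLP · r0 / (1 + age/h)` nodes per °Cd per apex — a saturating decay
capturing the slowdown of leaf appearance with crop age. The reference
curve (`r0` = 0.025 nodes/°Cd, `h` = 900 °Cd) is a package constant: the
external data behind the published reference curve are not available, so
the curve's *shape* is fixed and `LNSLP` scales it, which is all the
sensitivity analysis requires.

**Leaves.** A cohort's leaf has a potential size given by the crop age at
its creation: a linear ramp from `f0·LAXS` (f0 = 0.2) at planting to
`LAXS` at 900 °Cd, then an exponential decline of 5% per 100 °Cd,
continuous at the peak. The leaf expands for a fixed thermal window
(100 leaf-development °Cd); under assimilate shortage or drought it simply
ends up smaller. Once the window closes the leaf is fully expanded and
senesces when a further `LLIFA` °Cd (leaf-aging base) have accumulated —
a strict threshold. An earlier design started the aging clock only when
the realized area reached its target; that made senescence timing depend
on assimilate supply and produced non-monotone maximum-LAI responses to
radiation use efficiency, contradicting the directional behaviour the
model family is documented to have. The fixed window restores
monotonicity and matches how cohort-based DSSAT crop modules age leaves.

**Stems, roots and allocation.** Node mass follows a logistic curve with
asymptote `NODWT`, steepness 0.02 °Cd⁻¹ and midpoint
`250 + 2·(leaf number at creation)` °Cd. The steepness was set to 0.02
(not 0.01) so that the integrated growth rate actually delivers `NODWT`
to within 1% — with 0.01 the logistic's left tail would leave ~8% of the
node mass unrealized. Daily assimilation is Beer's-law interception times
`PARUE` (PAR taken as half of global radiation). Demands — leaf
(lamina + petiole via `LPEFR`, mass = area/`SLAS`), stem, and a 10%
fibrous-root gross-up — are served first; if supply falls short every
organ is scaled by the same ratio and the storage roots get nothing;
only surplus spills over into storage-root mass, whose dry weight is the
yield. `SLAS` (cm² g⁻¹) converts area to mass by division; the alternative
reading (multiplication) is dimensionally inconsistent.

**Stake reserves.** A freshly germinated crop has almost no leaf area, so
a purely supply-driven canopy cannot bootstrap. Real cassava is planted as
a stem cutting that fuels early growth from its reserves. The simulator
gives the crop a stake reserve pool (15 g m⁻², a species constant) that
tops up assimilate whenever early demand exceeds supply. The reserve is
part of the initial biomass, so mass conservation — cumulative
assimilation equals total biomass increment — holds exactly and is tested
to 10⁻⁶ relative.

**Drought.** The stress factor is computed from soil water content, not
from a transpiration ratio: a linear ramp `clamp(paw/s, 0, 1)` on the
root-zone plant-available-water fraction `paw = (θ − LL)/(DUL − LL)`
(thickness-weighted). Germination has its own sensitivity (`s_g` = 0.6,
more drought-tolerant); all other affected processes — leaf appearance,
branching, leaf growth, biomass increase — share `s` = 1.0. The functional
form is not published; the linear ramp is the simplest monotone choice
honouring the stated two-sensitivity structure. "Unlimited water" is
implemented by forcing the factor to 1 rather than by irrigation events,
which removes any scheduler ambiguity.

**Outputs.** Six variables: aboveground dry biomass (senesced leaves
*included*, matching usual DSSAT accounting; they leave the LAI but not
the biomass), storage-root dry yield (no fresh-weight conversion — no
water content is published), maximum LAI, cumulative leaves per plant at
harvest (live + senesced; the alternative "live leaves" reading is noted
as ambiguous), and days to first and second branching (NA when never
reached; the analysis pipeline censors these at the 300-day season so
sensitivity statistics stay finite).

**Two engines.** The daily loop exists twice: an Rcpp implementation used
for the tens of thousands of runs a sensitivity design needs (~2 ms per
season), and a pure-R reference engine composed from the exported
component operations (`update_branching()`, `compute_demand()`,
`allocate_spillover()`, `senesce()`, ...). A property test drives both
with random genotypes and asserts agreement below 10⁻⁹ relative, so the
compiled path never silently diverges from the documented semantics.

## 2. Parameter distributions

The 16 GSPs ship as a plain-text configuration
(`inst/extdata/gsp_distributions.csv`) with family, parameters and
truncation per parameter. Truncation bounds come in two kinds — a value on
the parameter scale, or a probability level of the untruncated
distribution — and may be mixed (e.g. leaf life: left value 100 °Cd, right
at the 0.9 quantile). Bare interval notations like "0.1–0.9" are read as
probability bounds; the explicit value-form used elsewhere shows the
notation distinguishes the two. Triangular distributions are never
additionally truncated (they are bounded by construction). Truncated
sampling is exact inverse-cdf on a rescaled uniform — no rejection.

Fitting (`fit_distribution()`) is maximum likelihood: closed forms for
uniform/normal/lognormal, Nelder–Mead on log-parameters with
method-of-moments starts for gamma and Weibull, and profile likelihood
over the mode for the triangular (its min/max MLE sits on the data
boundary where the likelihood is improper, so they are pinned 2.5% outside
the observed range). Candidates are ranked by AIC (= 2k − 2logLik), with
the one-sample Kolmogorov–Smirnov statistic and its asymptotic p-value
reported per fit. The p-values are *not* corrected for estimated
parameters (no parametric bootstrap), matching common practice of the
standard fitting packages; they are therefore approximate and documented
as such. Parameters with fewer than 10 observations get a uniform fallback
over the observed (or a configured) range, flagged `fallback = TRUE`.

## 3. Synthetic environments

No measured weather or soil is shipped; both study environments are
emulated. Two site profiles (cool highland: 18 °C, 16 MJ m⁻² d⁻¹, 890 mm
per 300-day season; warm lowland: 28 °C, 17 MJ m⁻² d⁻¹, 1130 mm) drive a
stochastic generator: temperature is the site mean plus a weak tropical
seasonal cycle (±0.5 °C) and AR(1) noise, with tmax/tmin placed
symmetrically at a noisy diurnal range; rain occurrence is a two-state
Markov chain at the profile's stationary wet-day frequency (persistence
0.35) with gamma amounts (shape 0.9) whose mean is set so the *expected*
season total equals the target; radiation is AR(1) noise around a mean
pre-compensated for the 15% cloud reduction applied on wet days. Values
not stated anywhere (diurnal ranges 12/10 °C, wet-day frequencies
0.50/0.40) were chosen once as climatologically plausible for highland and
lowland Colombia and are not tuned. Tests check 30-season means: mean
temperature within ±0.5 °C, season rainfall within ±15%.

What the generator does **not** emulate: monthly seasonality of rainfall
(both sites have distinct wet/dry seasons in reality), inter-annual modes
(ENSO), and temperature–radiation covariance beyond the wet-day cloud
factor. A green weather test therefore establishes that the *mean growing
environment* matches the targets, not that any real year is reproduced.
Likewise the two packaged soil profiles are labelled synthetic: plausible
layered stand-ins (clayey highland, sandier lowland), not measured pedons,
so absolute yields are not comparable to field trials — only the
sensitivity structure is meaningful, which is the package's purpose.

The planting day of year defaults to 115 ("late April"); the exact date is
unpublished and the default is configurable.

## 4. Screening (elementary effects)

`build_esu_design()` constructs Morris trajectories on a p-level grid with
step Δ = p/(2(p−1)) — 8 levels, hence Δ = 4/7 — where each trajectory
perturbs every parameter exactly once. The "enhanced sampling uniformity"
idea is realized as an oversampled pool (default 500 random trajectories)
from which the r kept trajectories are chosen by greedy max–min selection
under the Campolongo trajectory-spread distance (sum of pairwise
point-to-point Euclidean distances). The original eSU algorithm's exact
objective is described only in external references, so this documented
stand-in provides the intended property — well-spread, non-clustered
trajectories — without claiming bit-compatibility. Elementary effects are
signed slopes across each step; per parameter the screening reports μ
(signed mean, direction), μ* (mean absolute, importance) and σ
(interaction/non-linearity). Normalization divides μ* (and σ) by their
maxima over all parameters *and all four treatments* per output;
selection takes parameters with normalized μ* or σ strictly greater than
0.5 for at least one output in at least one location (ties at exactly 0.5
are excluded — a documented boundary convention).

At the desk scale the packaged model selects 11 of 16 GSPs; the size-14
selection reported at full scale is a soft, form-dependent expectation and
is surfaced, not asserted.

## 5. Sobol analysis

`build_sobol_design()` uses the radial layout A, B, A_B^(i), B_A^(i) —
the only layout consistent with the stated 2n(k+1) run count. Base points
come from a digitally scrambled Sobol low-discrepancy sequence implemented
in the package (31-bit Gray-code construction, direction numbers from the
published Joe–Kuo table, first 32 dimensions, random digital shift). This
mattered in practice: with Latin-hypercube or pseudo-random bases at
n = 4096 the additive-model check Σ S₁ = 1 ± 0.03 fails for roughly one
seed in five (Monte-Carlo sd ≈ 0.022), while the low-discrepancy base
brings the error below 10⁻³. First-order indices use the Saltelli-2010
estimator, total-order the Jansen estimator, both symmetrized over the two
hybrid blocks; bootstrap percentile intervals resample base indices.
Uncertainty summaries first average each parameter draw over the simulated
years, then report SD/CV and the empirical CDF across draws, with a
95% band from the pooled single-year values (weather variation).
Unselected GSPs are fixed at their distribution *medians* — defined
uniformly across families, unlike modes.

## 6. Numerical choices and degenerate inputs

* Quantile/cdf round-trips hold to 10⁻⁸ across all packaged distributions;
  truncated pdfs integrate to 1 within 10⁻⁶.
* Zero output variance in the Sobol estimator returns all-zero indices
  with a warning rather than NaN; all-zero elementary effects likewise.
* The eSU step keeps coordinates exactly on the grid (float fuzz at the
  borders is clamped); design validity — one coordinate per step, ±Δ,
  grid membership — is brute-force checked in the tests.
* Soil water closes its daily mass balance to 10⁻⁹ mm by construction
  (infiltration → cascade drainage → capped, root-weighted extraction
  with one redistribution pass).
* Branch days are NA when never reached; analysis code censors at the
  season length.
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; pipeline stages derive their seeds from the
  experiment configuration, making full reruns byte-identical (asserted
  on the written report files).

## 7. Known limitations

Photoperiod and nitrogen responses are outside scope (not implemented in
the modelled code base either); no pests, weeds or nutrient limitation;
no VPD modifier on photosynthesis (a species-wide parameter, excluded
from the analysis). The reference leaf-appearance curve, the node-growth
logistic constants, the leaf expansion window and the stake reserve are
package constants centralized in `species_constants()` — they shape
absolute output levels, and the tests deliberately assert only counts,
balances, boundaries and directions, which are form-independent. Reported
coefficients of variation and index rankings from the original field-data
study are not numeric targets here: they depend on measured weather,
soils and unpublished species constants, and this package's synthetic
environments reproduce their qualitative structure (warm > cool output
ranges, branching CVs far below yield CVs, rainfed ≈ unlimited
sensitivity rankings) rather than their values.
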
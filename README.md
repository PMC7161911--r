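# cassim

Desk-scale mechanistic simulation of cassava (*Manihot esculenta*) growth,
together with the complete global sensitivity and uncertainty analysis
(GSUA) toolchain needed to study which genotype-specific parameters (GSPs)
drive the model's outputs.

## Who this is for

Crop modellers and agronomists who want to (i) run a daily-time-step
cassava simulator whose genotype parameters carry literature-derived
probability distributions, and (ii) quantify — by elementary-effects
screening and Sobol variance decomposition — how much each parameter
contributes to the uncertainty of simulated biomass, yield, leaf area
index (LAI), leaf counts and branching dates across contrasting
environments (warm/cool × rainfed/water-unlimited).

## The model in brief

Development is driven by thermal time `TT = max(0, (Tmax + Tmin)/2 − Tb)`
with different base temperatures for branching, node growth and leaf aging;
leaf development uses the genotype's base temperature `TBLSZ`. The crop
forks from branch level *L* to *L+1* when branching thermal time reaches
`B01ND + L·B12ND`, multiplying the apex count by the branches-per-fork
parameters `BR1F..BR4F`. Nodes (leaf + internode) are created in daily
cohorts at a saturating rate `LNSLP · r0 / (1 + age/h)` per apex. Potential
individual leaf size ramps up to `LAXS` at a crop age of 900 °Cd and
declines afterwards; a leaf expands for a fixed thermal window and, once
past it, senesces after a further `LLIFA` °Cd. Daily assimilation follows
Beer's law,

```
A = 0.5 · SRAD · (1 − exp(−KCAN · LAI)) · PARUE ,
```

and is allocated by *spill-over*: leaf (split lamina/petiole by `LPEFR`
through the specific leaf area `SLAS`), stem (logistic node growth toward
`NODWT`) and fibrous-root (+10%) demands are served first — scaled
proportionally when assimilate is short — and only the surplus goes to the
storage roots, whose dry mass is the yield. A tipping-bucket soil water
balance supplies a drought stress factor computed from root-zone soil water
content (a linear ramp on the plant-available-water fraction, with a
separate germination sensitivity) that slows germination, leaf appearance,
branching, leaf growth and assimilation.

The GSUA layer provides: truncated parametric distributions for the 16
GSPs (uniform, triangular, normal, lognormal, gamma, Weibull, with value-
and probability-kind truncation), maximum-likelihood fitting ranked by AIC
with Kolmogorov–Smirnov statistics, Morris-type elementary-effects
screening on enhanced-uniformity trajectory designs (μ, μ*, σ, normalized
across treatments, selection rule μ*norm or σnorm > 0.5), and Sobol
first/total-order indices (Saltelli-2010 / Jansen estimators on a scrambled
digital Sobol sequence) with bootstrap confidence intervals and
uncertainty summaries (SD, CV, empirical CDFs, year-variation bands).

## Worked example

```r
library(cassim)

# 2 years of synthetic weather for the warm lowland site profile
w <- generate_weather(default_sites()$warm, n_years = 2, seed = 42)
head(season_stats(w), 1)
#>   year mean_temp mean_srad rainfall
#> 1 2001    27.936  17.19967   1158.1

# one rainfed season for an early-branching, efficient genotype
out <- simulate_season(gsp_set(PARUE = 1.6, B01ND = 600), w,
                       load_soil("warm"))
out
#> <season_outputs>
#>   aboveground biomass:  10600.4 kg/ha
#>   yield (storage root):     1.3 kg/ha
#>   max LAI:                 0.95
#>   leaves at harvest:      263.2
#>   day of 1st branch:         44
#>   day of 2nd branch:         79
```

Aboveground dry biomass is 10.6 t/ha but the storage-root yield is nearly
zero: with a high node weight this genotype's stem demand absorbs almost
all assimilate, so the spill-over rule leaves no surplus — exactly the
partitioning behaviour the sensitivity analysis is designed to expose.

```r
# quick screening: which GSPs move aboveground biomass most?
d <- build_esu_design(k = 16, levels = 8, r = 8, pool_size = 100, seed = 1)
params <- map_to_parameters(d, gsp_distributions())
# ... evaluate the 136 rows with simulate_season(), then:
ee <- elementary_effects(d, y_biomass, params = colnames(params))
round(sort(ee$mu_star, decreasing = TRUE)[1:5])
#>  LAXS PARUE NODWT LLIFA  BR1F
#>  8066  7823  5461  4859  3905
```

Maximum leaf size, radiation use efficiency and node weight lead — the
same trio the full analysis flags as most influential. The whole
experiment (4 treatments, screening + Sobol, report tables) runs via

```r
cfg <- experiment_config("desk")          # 5 years, r = 8, n = 64
scr <- run_screening(cfg)
sb  <- run_sobol(cfg, scr$selected)
report_gsua(scr, sb, dir = "gsua_report")
```

or from the shell through the CLI wrapper
(`inst/exec/cassim`): `gen-weather`, `sample-esu`, `sample-sobol`,
`simulate`, `analyze-esu`, `analyze-sobol`, `report`.

## Layout

- `R/distributions.R`, `R/gsp.R` — truncated distributions, K–S/AIC fitting,
  packaged GSP table (`inst/extdata/gsp_distributions.csv`)
- `R/weather.R` — stochastic generator, DSSAT-style `.wth` exchange,
  thermal time
- `R/soil.R` — tipping-bucket water balance, drought stress factor,
  packaged synthetic soil profiles
- `R/crop.R`, `R/simulate.R`, `src/season.cpp` — the crop model: exported
  component operations, R reference engine, compiled fast engine (the two
  engines are tested for agreement)
- `R/esu.R`, `R/sobol.R`, `R/lowdiscrepancy.R` — screening and
  variance-based sensitivity analysis
- `R/pipeline.R`, `R/cli.R` — experiment orchestration, reports, CLI
- `vignettes/gsua-methods.Rmd` — model description, assumptions, design
  choices and limitations
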
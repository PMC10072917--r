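# codiversity

Cause-of-death (CoD) diversity analysis for epidemiologists and demographers
studying how the composition of mortality changes along the epidemiological
transition. The package measures how concentrated or spread-out deaths are
across cause categories, tracks that diversity over time and across
populations, and attributes its changes to specific causes and age groups.

## What it computes

**Fractionalization index.** For death shares *p₁, …, p_k* over *k* mutually
exclusive causes,

&nbsp;&nbsp;&nbsp;&nbsp;*F = 1 − Σᵢ pᵢ²*

is the probability that two randomly chosen deaths are attributable to
different causes. *F = 0* when every death has the same cause and
*F = (k−1)/k* when deaths are spread uniformly (20/21 ≈ 0.95 for the default
21-cause, 3-group GBD-style hierarchy).

**Age-structure correction.** Shares are taken from life-table deaths
*d(x)* rather than observed death counts: a period life table is built from
all-cause rates (`q = n·m / (1 + (n−a)·m)`, radix 1, open terminal interval
with `L = l/m`), and deaths are partitioned by the within-age cause fractions.
This makes populations with different age pyramids comparable. The same life
table yields life expectancy at birth *e₀* and life disparity
*e† = Σ d(x)·e(x)* (the average remaining life expectancy at death).

**Decomposition.** Changes in *F* between two years are split into
cause-by-age contributions with the Horiuchi stepwise-replacement (numerical
line-integral) decomposition over the cause-age-specific rate surface, with
exact additivity after residual distribution.

**Uncertainty.** 95% intervals on every cell are propagated through the whole
pipeline by Monte-Carlo resampling (two-piece normal honouring asymmetric
bounds), yielding envelopes and a significance flag for year-to-year changes.

**Association.** Population-weighted LOESS curves (tricube kernel × population
weights) relate *F* to *e₀* and *e†* across countries, plus year-ordered
region trajectories.

A synthetic-data module generates GBD-like panels (21 causes × 21 age groups
× regions × countries × sexes × years 1990–2019) from parametric hazard
templates with a built-in epidemiological transition, so every stage is
testable with known ground truth and no data download.

## Worked example

```r
library(codiversity)

cfg <- scenario_config(n_regions = 3, countries_per_region = 3, seed = 42)
g   <- generate_panel(cfg)
g$panel
#> <mortality_panel> 238140 records: 9 location(s), 2 sex(es), 30 year(s);
#>                   21 age groups x 21 causes

lv <- run_levels(g$panel, years = c(1990, 2019), n_draws = 200, seed = 1)
lv[lv$sex == "male", ]
#>       region  sex year     F lower upper     diff significant
#> 3  region_01 male 1990 0.878 0.876 0.881       NA          NA
#> 4  region_01 male 2019 0.809 0.805 0.814 -0.06883        TRUE
#> 7  region_02 male 1990 0.830 0.827 0.833       NA          NA
#> 8  region_02 male 2019 0.821 0.818 0.825 -0.00904        TRUE
#> 11 region_03 male 1990 0.758 0.753 0.763       NA          NA
#> 12 region_03 male 2019 0.819 0.816 0.822  0.06124        TRUE

dc <- run_decomposition(g$panel, years = c(1990, 2019), n_steps = 20)
dc$decompositions[["region_01|male"]]
#> <f_decomposition> Delta F = -0.06883 (F1 = 0.8779, F2 = 0.8091);
#>                   21 ages x 21 causes
#> largest cause contributions:
#>   Cardiovascular diseases: -0.01047
#>   Other infectious diseases: -0.01037
#>   HIV/AIDS and sexually transmitted infections: -0.009177
```

Read as: male CoD diversity in `region_01` (a late-transition region in this
scenario) fell from *F* = 0.878 to 0.809 between 1990 and 2019 — deaths became
more concentrated — and the change is significant at the 5% level. The
decomposition attributes the decline chiefly to the growing cardiovascular
share and the shrinking communicable causes. `region_03`, further along its
transition, shows the opposite (rebounding) phase. `run_association()` adds
the LOESS curves of *F* against *e₀* and *e†*; `run_pipeline()` chains all
stages from a YAML config and writes CSV tables.

Real GBD-results-tool extracts load with
`read_panel(path, gbd_cause_scheme(), gbd_age_scheme())` (rates or counts,
both age-label dialects accepted).

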
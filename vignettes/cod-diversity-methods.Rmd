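---
title: "Measuring and decomposing cause-of-death diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing cause-of-death diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codiversity)
```

## The quantity of interest

As populations move through the epidemiological transition, deaths shift
from a communicable-disease-dominated pattern toward chronic disease, and
the *composition* of mortality — not just its level — carries information
about health system performance and inequality. This package measures that
composition with the fractionalization index

$$F = 1 - \sum_{i=1}^{k} p_i^2,$$

the probability that two randomly drawn deaths are attributable to different
causes. $F$ ranges from $0$ (all deaths share one cause) to $(k-1)/k$
(deaths uniform over the $k$ causes; $20/21 \approx 0.95$ for the default
21-cause scheme). $F$ is a strictly Schur-concave function of the share
vector, which gives it two properties the tests rely on: merging cause
categories can only decrease it, and appending empty categories leaves it
unchanged.

The default cause scheme mirrors the GBD hierarchy: 21 level-2 causes nested
in 3 level-1 groups (communicable/maternal/neonatal/nutritional: 7 causes;
non-communicable: 11; injuries: 3). `regroup()` collapses shares to level 1
or to any custom grouping for sensitivity analyses.

## Age-structure correction through the life table

Observed death counts confound cause composition with the age pyramid: an
old population has many cardiovascular deaths partly because it is old.
The package therefore computes cause shares from *life-table* deaths. From
all-cause rates $m_x$ on an abridged age grid (default: `<1`, `1–4`,
5-year groups to an open `95+`), probabilities are
$q_x = n m_x / (1 + (n - a_x) m_x)$, survivorship starts at radix 1, and
life-table deaths $d_x = l_x q_x$ sum to 1, so they are directly the death
distribution. Deaths at each age are then split across causes by the
within-age cause fractions $m_{xc}/m_x$, and the shares entering $F$ are the
column sums of that matrix. The uncorrected variant
(`fractionalization_observed()`) is kept for comparison.

Conventions, all configurable where they are genuinely conventional:

* $a_x = n/2$ for closed intervals; for the infant interval
  $a_0 = 0.07 + 1.7\,m_0$, clamped to $[0.01, 0.35]$ — a standard infant
  separation approximation (disable with `infant_ax = FALSE`).
* The terminal interval is open with $q = 1$ and $L = l/m$ (constant-hazard
  closure), matching the GBD convention of a `95+` group.
* Radix 1.0, so no rescaling is ever needed downstream.

Life expectancy $e_0 = T_0/l_0$ and life disparity
$e^\dagger = \sum_x d_x \bar e_x$ come from the same table. The discrete
placement of $\bar e_x$ is ambiguous in the literature; the package places
the within-interval death age at $x + a_x$ and evaluates the remaining
expectancy there by linear interpolation of $T$ and $l$. This choice
converges to the continuous $\int d(x)e(x)\,dx$ under grid refinement; the
test suite verifies agreement with a closed-form quadrature oracle for the
piecewise-linear survival model to within $10^{-6}$ relative on a
0.05-year grid, and the constant-hazard identity $e^\dagger = e_0$ to
within 2% on a 1-year grid.

## Decomposing changes in F

The change $\Delta F$ between two years is attributed to cause-age cells
with the Horiuchi stepwise-replacement method: the covariates are the
cause-age-specific rates $m_{xc}$ (so the life table responds to every
covariate through the all-cause sum), and the contribution of each cell is
the numerical line integral of $\partial F / \partial m_{xc}$ along a path
from the first year's surface to the second's. Cells move proportionally
(geometrically) between their endpoints, the standard choice when the true
time path is unknown; cells with a zero endpoint move linearly, since the
geometric path is undefined there. The integral uses midpoint central
differences over `n_steps` (default 20, the conventional setting; the
integration error at 20 vs 200 steps is below $10^{-4}$ on synthetic
surfaces). The residual — the gap between the summed contributions and the
exactly recomputed $\Delta F$ — is reported and then distributed across
cells proportionally to absolute contributions, making additivity exact.
Decomposing in the reverse direction negates every contribution.

Sex and region are strata, never covariates: decompositions run within each
(region, sex). Cause marginals give the per-cause table; summing causes
within level-1 groups by age gives the broad-group age profile.

## Uncertainty propagation

GBD-style inputs carry asymmetric 95% intervals per cell, not posterior
draws. The package resamples each cell independently from a two-piece
normal with $\sigma_{low} = (\text{val}-\text{lower})/1.96$ below the point
estimate and $\sigma_{high} = (\text{upper}-\text{val})/1.96$ above,
truncated at zero (a symmetric-normal alternative is available). Cross-cell
independence is an explicit assumption — intervals alone cannot recover the
GBD posterior correlation structure. Envelopes are empirical 2.5/97.5
percentiles of the statistic over `n_draws` (default 1000) perturbed panels;
year-to-year changes are flagged significant when the paired-draw difference
interval excludes zero. Two numerical details: the RNG sub-streams are
assigned to the two compared panels by a content-based canonical order, so
the significance flag is exactly invariant under swapping the panels; and a
difference interval within $10^{-12}$ (relative) of zero is treated as a
floating-point tie, never as significance. Calibration is verified by
simulation in the test suite: envelope coverage of known truth within
90–98% over 200 replicates, and a null rejection rate statistically
compatible with 5%.

## Population-weighted LOESS

The association between $F$ and $e_0$ (or $e^\dagger$) across countries is
summarised by local polynomial regression: at each grid point, a polynomial
of degree 0–2 (default 1) is fitted by weighted least squares with weights
tricube$(d/h) \times$ population, where $h$ is the distance to the
`ceiling(span * n)`-th nearest positively weighted observation (default
span 0.75 — the conventional setting; neither parameter has a canonical
epidemiological value, so both are exposed). Zero-weight points never count
toward the window. The curve is evaluated only inside the data range — no
extrapolation — and is invariant to rescaling all population weights. The
implementation is written against this exact contract and is tested cell by
cell against a brute-force weighted-least-squares oracle (and, loosely,
against `stats::loess`); fits are exact on linear data by construction.
Curves are fitted separately per sex and per analysis year.

## The synthetic scenario generator

`generate_panel()` produces complete GBD-like panels from parametric hazard
templates with closed-form ground truth, which is what makes the pipeline
testable without any download:

* **Communicable causes**: age shapes $e^{-x/6} + 0.02$ (general) or
  $e^{-x/0.8}$ (infancy-concentrated, for maternal/neonatal, enteric,
  nutritional and parasitic causes), declining in calendar time at 4%/year.
* **Non-communicable causes**: a Gompertz hazard $\propto e^{0.085x}$. The
  cardiovascular *share* of the block follows a rise-and-fall hump
  (Gaussian in time, default peak 2000, sd 12 years, amplitude 1.2) while
  the block's total hazard is renormalized, so the hump shifts composition
  without breaking the monotone rise of $e_0$.
* **Injuries**: age-flat hazards with a male multiplier (default 2).

Regions are phase-shifted copies of one transition (offsets $\pm 12$ years,
mortality levels 0.7–1.5×), countries jitter lognormally (sd 0.15) around
their region, and populations are drawn log-uniformly over $10^6$–$10^8$ so
population weighting is exercised non-trivially. Uncertainty bounds are
relative, $\text{val} \times (1 \mp 0.10)$ by default — a width typical of
cause-specific mortality estimates. All magnitudes were chosen once, as
plausible for a mid-transition population ($e_0 \approx 60\text{–}80$
years, infant communicable rates of a few per hundred, adult
cardiovascular rates reaching $\sim 0.1$/year by age 80); the scenario is a
qualitative analogue, not a calibration to any real extract.

With the default parameters the canonical (zero-offset) transition produces
the signature pattern: $e_0$ rises monotonically while $F$ first falls (the
cardiovascular hump concentrates deaths) and then rebounds (the hump
recedes and chronic-disease mortality diversifies) — a non-monotone
$F$-vs-$e_0$ path. What the generator does **not** emulate: cross-cell
correlation of estimation errors, country-specific cause idiosyncrasies
(wars, epidemics), migration, and real GBD magnitudes. Tests passing on
these panels therefore demonstrate the correctness of the computational
pipeline and its statistical calibration under the stated assumptions, not
agreement with any real-world estimate.

## Region aggregation and other open choices

* Regional rates are population-weighted means of country rates (weights:
  age-specific populations), computed before life-table construction; the
  alternative of pooling deaths and person-years is algebraically the same
  when the weights are the true exposures, and the weighted-mean form keeps
  the operation well-defined for rate-only inputs.
* Canonical internal unit is deaths per person-year; count inputs are
  converted on read, since life-table construction needs rates. Both GBD
  age-label dialects are normalized on read.
* Cause-fraction rows must sum to 1 within $10^{-9}$; renormalization is
  opt-in, never silent, because share rounding in real extracts is a data
  quality signal.
* `run_levels()`/`run_decomposition()`/`run_association()` are the
  orchestration surface; `run_pipeline()` drives them from a YAML config
  and writes the three CSV tables (levels, decomposition, curves).

## Problem sizes

The shipped tests run the full default scenario (7 regions × 3 countries ×
2 sexes × 30 years × 21 ages × 21 causes ≈ 556k records) for generation-level
checks, and deliberately small grids (7 ages × 6 causes, single slices) for
the Monte-Carlo calibration studies — 200 replicates × 200–400 draws — which
keeps the whole suite around a minute while leaving the statistical
conclusions unchanged; all sizes scale up by configuration only.

## Known limitations

* No cause-deleted (associated single-decrement) life tables, no cohort
  tables, and no smoothing of input rates.
* Uncertainty propagation ignores cross-cell correlation (stated above).
* The LOESS has no confidence bands; turning points of the fitted curves
  are descriptive, not formal estimates.
* $F$ treats causes as unordered categories; it does not weight by
  severity, age at death, or cause similarity.
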
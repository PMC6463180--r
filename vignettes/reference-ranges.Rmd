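---
title: "Neonatal cHb and Hct reference-range models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neonatal cHb and Hct reference-range models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoref)
```

## The problem

Hemoglobin concentration (cHb, g/dL) and hematocrit (Hct, %) in newborns
depend jointly on two independent clocks: gestational age at birth (GA,
completed weeks) and postnatal age (PNA, days of life). Both values rise
with GA and decline over the first weeks after birth, so a measurement can
only be called low, normal or high relative to a reference range evaluated
at the neonate's own (GA, PNA). Normal ranges from healthy volunteers are
not obtainable in this population; reference ranges are instead derived
from large samples of clinically stable neonates. `neoref` implements a
compact parametric model of such reference ranges over GA 22–42 weeks and
PNA 0–28 days, and everything needed to refit, select, and validate models
of that family.

## The model

The mean reference surface is a bi-quadratic polynomial in GA and PNA with
**five** free coefficients, the first of which is *tied*: \(p_1\)
multiplies both the intercept and the linear PNA term,

\[
\mathrm{mean}(GA, PNA) = p_1 (1 + PNA) + p_2\, GA + p_3\, GA^2
 + p_4\, GA \cdot PNA + p_5\, PNA^2 .
\]

The tied coefficient is deliberate parsimony, not a typographical accident:
the published model is self-consistently described as having five free
parameters, and the package implements the form exactly as printed rather
than silently introducing a sixth coefficient. With the tied term encoded
as the single regressor \(1 + PNA\), the model is *linear* in its
parameters — a fact the fitting module exploits.

The percentile surfaces are constant offsets from the mean: the 5th and
95th percentile surfaces are \(\mathrm{mean} \mp \delta\), where
\(\delta\) is 3.76 g/dL for cHb and 10.69 % for Hct. The band width
\(2\delta\) is therefore the same at every age — an assumption justified
by the age-invariant, symmetric spread of the underlying empirical value
distributions. No LMS/GAMLSS-style percentile modelling is attempted; for
this model family the constant band *is* the model.

Shipped parameter presets (`preset_model("cHb")`, `preset_model("Hct")`,
also as JSON under `inst/extdata/`):

| coefficient | cHb (g/dL) | Hct (%) | units |
|---|---|---|---|
| \(p_1\) | −0.3409 | −1.2956 | analyte units (and per day) |
| \(p_2\) | 0.8300 | 2.5369 | per week |
| \(p_3\) | −0.0093 | −0.0300 | per week² |
| \(p_4\) | 0.0003 | 0.0069 | per week·day |
| \(p_5\) | 0.0058 | 0.0190 | per day² |
| offset | 3.76 | 10.69 | analyte units |

## Design decisions

**Domain and extrapolation.** The validated domain is GA ∈ [22, 42] weeks,
PNA ∈ [0, 28] days. Queries outside it (a 21.9-week GA, a day-29 sample)
are evaluated — the surface is smooth — but flagged `extrapolated` with a
warning rather than rejected: clinicians meet such values, and a refusal
would be less safe than a labelled answer. Day 29 is treated as
extrapolation. GA and PNA are continuous; the source grid is
integer-valued but the model is a smooth surface, so fractional weeks and
days are legitimate inputs.

**Boundary classification is inclusive.** A value exactly equal to the 5th
or 95th percentile is classified `within`. Flagging an exact-boundary
value as abnormal would be clinically indefensible.

**Fitting.** Because the tied model is linear in its parameters, the
default fit is the closed-form least-squares solution by QR decomposition
(`fit_closed_form()`). A Levenberg–Marquardt route (`fit_lm()`, via
MINPACK) is kept as an independent numerical path: for a
linear-in-parameters model it must converge to the closed-form optimum
from any finite start, which makes the pair a built-in cross-check — the
test suite asserts their agreement to ≤ 10⁻⁶ per coefficient on dozens of
randomized datasets. LM defaults: zero-vector start (immaterial here),
ftol = ptol = 10⁻¹⁰, at most 200 iterations. Fitting is unweighted; no
weighting scheme is part of the model family.

**Offset estimation.** The band half-width is estimated as the pooled mean
of all available half-spreads, \((\mathrm{mean}_i - p5_i)\) and
\((p95_i - \mathrm{mean}_i)\) — the least-squares constant under the
symmetric-band model. On self-consistent data this reproduces the shipped
offsets exactly; under asymmetric band noise it averages the two sides,
and it is invariant to exchanging the roles of the two percentile columns.
Estimation is two-stage: mean surface first, then the offset (fitted means
substitute for missing mean cells).

**Model selection.** The functional form was originally discovered by a
proprietary symbolic-regression search; that step is replaced here by an
exhaustive, reproducible subset search over a 7-term quadratic library
\(\{1, PNA, (1+PNA)_{tied}, GA, GA^2, GA\cdot PNA, PNA^2\}\), where the
tied term is mutually exclusive with the separate intercept and linear-PNA
terms (79 admissible subsets). Every candidate is fitted in closed form;
"complexity" is the count of free coefficients; `pareto_front()` returns
the accuracy–complexity trade-off, breaking exact ties by the
lexicographically smallest term mask. Non-polynomial bases (exp, log,
trig) are out of scope — the target family is polynomial.

## The synthetic-data generator

No machine-readable version of the empirical reference grid (77 points per
analyte, digitized from published figures) or of the 19-neonate validation
cohort exists, so the package generates study-shaped stand-ins from the
model itself.

* **Grids** (`generate_grid()`): mean = surface + N(0, `sd_mean`);
  percentiles = mean ∓/± offset + independent N(0, `sd_band`). The default
  layout mirrors the published grid's structure and size: a GA sweep over
  integer weeks 22–42 at day 0 (21 points) plus PNA sweeps over days 1–28
  at GA 30 and GA 40 (2 × 28 points) — 77 records, a moderately preterm
  and a term trajectory. The true layout behind the published count is not
  recorded; this decomposition was chosen because it matches the published
  figure panels (one GA-trend, PNA-trends) and the printed point count,
  and it is configurable (`layout =`, or `ga_values`/`pna_values` for a
  full lattice). If band noise inverts a record's ordering, the
  (p5, mean, p95) triple is re-sorted so the grid invariant always holds;
  re-orderings are counted and reported.
* **Cohorts** (`generate_cohort()`): GA ~ N(33.91, 1.73²) truncated to the
  model's GA domain, PNA ~ N(8.26, 7.31²) truncated at 0 (rejection
  sampling; optional rounding to whole days), value = surface mean +
  N(0, `value_sd`). The defaults reproduce the demographic profile of a
  small clinically stable preterm cohort (n = 19).

What the generator does **not** emulate: digitization error, the sampling
variability of empirical percentile estimates, capillary-versus-venous
sampling offsets, phlebotomy losses, or transfusion physiology. Passing
parameter-recovery tests on synthetic grids therefore demonstrates the
correctness and identifiability of the estimation machinery — not the
clinical accuracy of the shipped coefficients on real neonates, which can
only be established against independent measured data.

With value noise calibrated to the band (`value_sd = offset / 1.644854`,
the normal 95% quantile), generated cohorts land ~90% inside the band;
the suite checks coverage ∈ [0.88, 0.92] at n = 5000.

## Numerical choices and degenerate inputs

* Closed-form fits refuse rank-deficient designs with an error naming the
  unidentifiable basis directions (e.g. a grid sampled only at day 0
  cannot identify \(p_4\) or \(p_5\)); the subset search instead skips
  such candidates with a message.
* Non-finite ages are invalid inputs everywhere; zero offsets give a
  degenerate band with p5 = mean = p95, which classification handles.
* Model JSON is written with 17 significant digits so that
  `load_model(save_model(m))` is bit-exact; CSV uses "." decimals
  regardless of locale, and the `--round` display option of the export
  never touches stored precision.
* Cohort CSV rows violating the observation invariants (GA ≤ 0, PNA < 0,
  value ≤ 0, unknown analyte) are rejected individually with line-numbered
  messages rather than failing the whole file.

## Known limitations

* **The Hct surface is not monotone in PNA at the domain edge.** With the
  shipped coefficients, \(\partial/\partial PNA = p_1 + p_4 GA + 2 p_5
  PNA\) turns positive for late PNA at high GA (beyond ~26.5 days at GA
  42; under 2% of the domain area). The cHb preset declines with PNA
  everywhere, and both presets rise with GA everywhere. This is a property
  of the published parameters, faithfully reproduced; the package reports
  it rather than hiding it, and the test suite documents the exact
  boundary of the sign change.
* The shipped coefficients inherit whatever error the original figure
  digitization introduced; the published goodness-of-fit statistics (MAE
  against the source grid, cohort band coverage) depend on data that were
  never deposited and so cannot be recomputed here. The corresponding
  operations (`mae_against_grid()`, `coverage()`) are instead verified on
  constructed inputs with known answers.
* The constant-offset band ignores any age-dependence of the spread; if
  the true percentile curves are not exactly symmetric about the mean, the
  pooled estimator returns the average half-spread (the `sd_band` noise
  knob exists precisely to probe this robustness in tests).

## Problem sizes used by the test suite

Recovery and selection tests run on the 77-point default layout and the
full 21 × 29 integer lattice (609 points); the LM-versus-closed-form
equivalence property uses 50 randomized noisy datasets of 20–60 points;
monotonicity is checked on a 0.1-step lattice (≈ 56,000 points); coverage
calibration uses one cohort of n = 5000. These sizes make every statistic
stable to well inside its asserted tolerance while keeping the whole suite
fast.
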
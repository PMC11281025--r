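---
title: "Methods: contamination indices and probabilistic health risk for heavy metals in wetland water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contamination indices and probabilistic health risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wetrisk implements the standard two-stage appraisal of heavy metal(loid)
contamination in surface water — regulatory pollution indices followed by a
US EPA-style exposure and risk model — together with Monte Carlo
uncertainty propagation, contribution-to-variance sensitivity analysis,
and a synthetic-data generator that reconstructs per-sample tables from
published group summaries. This vignette records the model, its
assumptions, and the design decisions that were genuinely open.

```{r setup}
library(wetrisk)
library(dplyr)
reg <- default_registry()
```

## Contamination indices

For each metal the single-factor pollution index is the concentration over
its evaluation threshold, $P_i = C_i / S_i$, with $S_i$ the surface-water
Class II limit stored in the registry (Hg 0.05, As 50, Cu 1000, Zn 1000,
Pb 10, Cd 5 µg/L). The Nemerow composite index
$\mathrm{NPI} = \sqrt{(P_{max}^2 + P_{ave}^2)/2}$ weights the worst
pollutant against the average; algebraically
$P_{ave} \le \mathrm{NPI} \le P_{max}$, so a single dominant metal (here
invariably Hg) drags the composite up even when the other five indices are
far below 1.

Two conventions needed fixing:

* **Boundary ties.** The published five-class table leaves a value exactly
  on a cut (e.g. $P_i = 0.7$) unassigned, writing $P_i < 0.7$ then
  $0.7 < P_i \le 1$. We close contamination intervals on the right —
  $[0, 0.7], (0.7, 1], (1, 2], (2, 3], (3, \infty)$ — so a tie joins the
  *less* severe class, consistent with the "≤" pattern of the upper rows.
  The cancer-risk scale is printed in half-open form
  ($10^{-6} \le CR < 10^{-4}$, …) and is implemented verbatim, so there a
  tie joins the *more* severe class. `classify()` returns ordered factors,
  making the mapping total and monotone on $[0, \infty)$.
* **Group-level composite.** A group's NPI is computed from the vector of
  group-average single-factor indices (equivalently, from group-mean
  concentrations — $P_i$ is linear in $C$). This is the only reading under
  which the published group averages are recovered from the published
  per-metal average indices; averaging per-sample NPIs instead is exposed
  as `group_method = "mean_of_sample_npi"` but is not the default.

## Exposure and risk model

Chronic daily intake (µg/kg/d) for a person drinking and wading in the
water is

$$\mathrm{CDI}_{ing} = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT},
\qquad
\mathrm{CDI}_{derm} = \frac{C \cdot SA \cdot K_p \cdot T_{event} \cdot EV
\cdot EF \cdot ED \cdot 10^{-3}}{BW \cdot AT},$$

where the $10^{-3}$ converts the permeated volume from cm³ to L. All
intakes, reference doses and slope factors are kept in µg/kg/d and
(µg/kg/d)⁻¹ throughout; no automatic unit conversion is attempted. The
averaging time is selected by assessment type (non-cancer: 912.5 d
children / 9490 d adults; cancer: 25550 d both), never by population, and
the intake functions take the already-selected value so the formulas stay
pure.

Non-carcinogenic risk: $HQ = \mathrm{CDI}_{ing}/RfD_{ing} +
\mathrm{CDI}_{derm}/RfD_{derm}$ per metal and $THI = \sum HQ$, with 1 as
the concern threshold. Carcinogenic risk: $CR = \mathrm{CDI}_{ing} SF_{ing}
+ \mathrm{CDI}_{derm} SF_{derm}$ and $TCR = \sum CR$. Only As and Cd have
slope factors for both routes; the remaining metals are excluded from the
carcinogenic pathway and listed as skipped in every report — missing
toxicity values are never imputed.

### Exposure parameters

| symbol | meaning | children | adults | units |
|---|---|---|---|---|
| IR | ingestion rate | N(1.25, 0.3) | N(1.95, 0.3) | L/day |
| EF | exposure frequency | Tri(180, 350, 360) | same | days/year |
| ED | exposure duration | 2.5 | 26 | years |
| BW | body weight | N(20, 0.15) | N(70, 0.15) | kg |
| SA | skin surface area | 7422 | 18182 | cm² |
| T_event | event duration | 0.58 | 1 | h/event |
| EV | event frequency | 1 | 1 | events/day |

These reproduce the source study's parameter table exactly, including the
body-weight SD of 0.15 kg, which is implausibly small for a population
(it is plausibly a transcription of a relative SD). We implement it as
printed because the registry makes every value overridable in YAML without
code changes; the consequence — body weight contributing only a fraction
of a percent of output variance for adults — is discussed under
sensitivity below.

**Point-estimate mode.** Deterministic evaluation collapses each
distribution to a point: the mean for normal/lognormal specs, the *mode*
(350 d/yr) for the triangular EF, the value for point specs. This mode is
first-class because it is the one under which the study's reproducible
printed cancer-risk numbers are recovered: with rural group-mean
concentrations (As 4.15, Cd 0.14 µg/L) it yields adult TCR 7.165×10⁻⁵ and
child TCR 1.526×10⁻⁵, within 0.5% of the published 7.13×10⁻⁵ and
1.53×10⁻⁵.

**Published values that are not recoverable.** The published
simulation-mean total hazard indices (0.46/0.57 adults, 1.02/1.25
children) sit ≈30–40% above anything Eqs above can produce from the
published concentrations and parameters (our point estimates: 0.33/0.52
adults, 0.72/1.14 children), and the published per-metal HQ severity
orderings disagree with the same arithmetic (which ranks Cu above Hg for
rural water). Likewise the published *urban* As cancer risk (6.31×10⁻⁵)
equals the *rural*-mean derivation, suggesting swapped group labels, and
the claim that Cd risks "were less than 10⁻⁶" contradicts the published
Cd values themselves (e.g. 8.26×10⁻⁶). We reproduce none of these;
validation of the stochastic machinery is property-based instead
(analytic expectations, degenerate-run equivalence, row-wise
conservation, sensitivity sign structure).

## Monte Carlo engine

Each iteration draws one parameter realization per population (IR, BW from
truncated normals, EF from the triangular; ED, SA, T_event, EV fixed) and
one concentration vector per group, shared across metals — one simulated
person in one water body — and pushes them through the full chain.
Concentration modes:

* `distribution` (default): independent lognormals moment-fitted to each
  group's published mean/SD, truncated at detection limits. The study does
  not state how concentrations entered its (Crystal Ball) simulation, nor
  its iteration count; 10,000 iterations and the lognormal choice are
  package defaults, recorded in the run configuration.
* `empirical`: whole measured rows resampled with replacement (preserves
  inter-metal correlation).
* `fixed`: group means (isolates parameter uncertainty).

Numerical contracts: a seed is mandatory; per-population and per-group
sub-streams are derived by hashing a purpose tag into a seed offset, so
adding a group never perturbs another group's draws and identical
configurations reproduce draws bit-for-bit. IR and BW are truncated at 1%
of their point value (a guard against the analytically possible negative
draw; at the study's CVs the clipped mass is ≈0 for IR and exactly 0 in
double precision for BW). EF's triangular support (≤360) already respects
the 366 d/yr ceiling that `exposure_realization()` enforces. Per
iteration, $THI - \sum HQ$ and $TCR - \sum CR$ are identically zero by
construction and asserted in tests. A `fix_ef` switch holds EF at its mode,
mirroring the point mode's convention inside the simulation.

## Sensitivity analysis

Drivers of THI and TCR are ranked by *contribution to variance*: with
Spearman correlations $\rho_k$ between each input's draws and the output,

$$\mathrm{contribution}_k = \mathrm{sign}(\rho_k)\,
\frac{100\,\rho_k^2}{\sum_j \rho_j^2} \%.$$

The source study names only its simulation software; this signed
normalized squared rank correlation is that software's documented
sensitivity statistic and is adopted here, with the raw correlations also
reported. Inputs are the sampled parameters (IR, EF, BW) plus the
concentration draws of the metals that actually enter the output (all six
for THI; As and Cd for TCR). Rank-based contributions are invariant under
strictly monotone transforms of any input and under input reordering;
zero-variance inputs report zero with a warning rather than an error.

On default runs body weight is the sole negative driver and arsenic the
dominant one, for both populations — matching the study's qualitative
findings. One quantitative caveat: with the as-printed BW SD of 0.15 kg,
the true BW–output rank correlation for adults is of order −0.005, so its
*sign* is only resolved reliably when the draw count is large; the test
suite uses 2×10⁵ iterations for these structural assertions (children,
with a 4× larger relative BW spread, resolve much sooner). The published
sensitivity percentages depend on unpublished concentration-distribution
choices and are treated as ordering targets only.

## Synthetic sample generator

The generator reconstructs per-sample tables from group-wise summary
statistics (20 urban and 16 rural samples in the shipped registry):

1. **Family.** Concentrations are positive with CVs up to 1.29, and the
   lognormal is the conventional model for environmental concentrations,
   so each metal is drawn from the lognormal whose arithmetic moments
   match the published mean/SD (`fit_lognormal_moments()`:
   $\sigma^2 = \ln(1 + (sd/mean)^2)$, $\mu = \ln(mean) - \sigma^2/2$),
   truncated below at the detection limit (Hg 0.04, As 0.30, Cu 0.08,
   Zn 0.67, Pb 0.09, Cd 0.05 µg/L). Whether and how the original data were
   censored at detection limits is unpublished; the truncation floor is a
   stand-in assumption.
2. **Moment matching.** With `moment_match = TRUE`, draws are transformed
   by $x \mapsto \exp(a + b \log x)$, where $b$ solves the sample
   second-moment ratio equation (a monotone one-dimensional root-solve)
   and $a$ rescales the mean — exact in one pass absent truncation — then
   re-clipped at the detection limit and re-solved, at most 5 times. If
   the 0.5% tolerance is still unmet the generator warns with the achieved
   moments instead of failing silently. In practice all twelve
   group–metal pairs converge within tolerance; Hg, with ≈8% truncated
   mass, is the binding case.
3. **Metadata.** pH and conductivity are drawn uniformly within the
   published field ranges purely as pass-through columns.

What passing tests show — and what they do not: the generator reproduces
group-level first and second moments, ranges above detection limits, and
standard-exceeding ratios statistically; it generates metals independently
(no published correlation structure to honor), has no spatial or seasonal
structure, and cannot reproduce per-sample extremes of the original data
(e.g. published per-sample NPI maxima of 12.62/16.22 are reproducible only
distributionally). Conclusions about real water from this package should
rest on measured samples via the `empirical` mode, with the generator
reserved for method exercise and power studies. One table inconsistency is
worth noting: the published urban Cd CV (0.73) cannot be reconciled with
the published urban Cd mean and SD (0.06/0.09 ≈ 0.67) at any rounding, so
generator validation compares CVs to the published row only up to
two-decimal rounding slack and excludes that cell.

## Problem sizes and runtime choices

The shipped defaults are the study's own conditions: 20 + 16 samples,
10,000 Monte Carlo iterations. The test suite exercises the engine at
500–10,000 iterations for numerical oracles, 200 generator replicates for
sampling-distribution checks, and one 2×10⁵-iteration run for the
sensitivity sign structure (see above); all sizes are stated in the tests
themselves.

```{r example}
samples <- generate_samples(reg, seed = 1)
assess_contamination(samples, reg)$group_npi
```

## Known limitations

* Two exposure routes only (ingestion, dermal); no inhalation or dietary
  pathways, and no dose-response beyond linear slope factors.
* Simple random sampling in the Monte Carlo engine (no Latin hypercube),
  and no two-dimensional variability/uncertainty separation.
* The registry ships constants for the six studied metals only, though
  any metal can be added through the YAML file.
* Sensitivity contributions are rank-correlation based and attribute
  shared variance proportionally; they are not Sobol indices.
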
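# wetrisk

Contamination indices and probabilistic human-health risk assessment for
heavy metal(loid)s (Hg, As, Cu, Zn, Pb, Cd) in surface water, written for
environmental scientists who have per-sample water chemistry tables — or
only published summary statistics — and need defensible contamination
classes and health-risk estimates for exposed populations.

## What it computes

**Contamination.** The single-factor pollution index compares each metal's
concentration to its regulatory threshold (surface-water Class II limit),

    P_i = C_i / S_i,

and the Nemerow composite index combines the six indices while emphasizing
the worst pollutant,

    NPI = sqrt((P_max^2 + P_ave^2) / 2),

with both classified on the standard five-level scale (no / slight / light /
moderate / high contamination).

**Health risk.** Chronic daily intake (µg/kg/d) is computed for oral
ingestion and dermal contact,

    CDI_ing  = C · IR · EF · ED / (BW · AT)
    CDI_derm = C · SA · Kp · T_event · EV · EF · ED · 10⁻³ / (BW · AT),

then aggregated into hazard quotients `HQ = CDI_ing/RfD_ing +
CDI_derm/RfD_derm` and the total hazard index `THI = Σ HQ` (non-carcinogenic
risk; values above 1 flag potential risk), and into cancer risks
`CR = CDI_ing·SF_ing + CDI_derm·SF_derm` and the total cancer risk
`TCR = Σ CR`, classified from "very low" (< 10⁻⁶) to "extremely high"
(> 0.1). Only As and Cd carry slope factors; the other metals are skipped
for the carcinogenic pathway, never imputed.

**Uncertainty.** A seeded Monte Carlo engine propagates parameter
uncertainty (ingestion rate and body weight normal, exposure frequency
triangular) and concentration uncertainty (moment-fitted lognormals
truncated at the detection limits, or resampled measured samples) through
the whole chain, yielding distributions, percentiles and exceedance
probabilities for every output, plus a Crystal-Ball-style
contribution-to-variance sensitivity analysis (signed normalized squared
Spearman correlations).

**Synthetic data.** Because raw per-sample data are rarely published, a
generator reproduces per-sample tables from group-wise max/min/mean/SD
summaries via truncated lognormals with an exact moment-matching
adjustment, so every stage is testable from printed tables alone.

All constants (thresholds, detection limits, Kp, RfD, SF, exposure
profiles, class boundaries, group summaries) ship in one editable YAML
registry (`inst/extdata/registry.yaml`).

## Worked example

```r
library(wetrisk)
library(dplyr)

reg <- default_registry()

# synthesize the study's 36 samples (20 urban + 16 rural) from its
# published summary statistics, then assess contamination
samples <- generate_samples(reg, seed = 1)
assess_contamination(samples, reg)$group_npi
#> # A tibble: 2 × 5
#>   group p_max p_ave   npi class
#>   <chr> <dbl> <dbl> <dbl> <ord>
#> 1 rural  5.02 0.931  3.61 high contamination
#> 2 urban  3.20 0.588  2.30 moderate contamination

# deterministic risk assessment at the group-mean concentrations
means <- mutate(group_profiles(reg), concentration = mean)
assess_risk(means, reg)$totals
#> # A tibble: 4 × 6
#>   population group   thi thi_class             tcr tcr_class
#>   <chr>      <chr> <dbl> <chr>               <dbl> <chr>
#> 1 children   urban 0.719 acceptable     0.00000992 low risk
#> 2 children   rural 1.14  potential risk 0.0000153  low risk
#> 3 adults     urban 0.329 acceptable     0.0000465  low risk
#> 4 adults     rural 0.519 acceptable     0.0000716  low risk

# Monte Carlo propagation and sensitivity ranking
mc <- run_mc(reg, n_iterations = 2000, seed = 7)
filter(mc$summary, output == "tcr", group == "rural", population == "adults")
#> # A tibble: 1 × 12
#>   group population output      mean        sd ...
#> 1 rural adults     tcr    0.0000612 0.0000270 ...
head(filter(mc_sensitivity(mc, registry = reg), output == "tcr",
            group == "rural", population == "adults"), 3)
#>   output input rank_correlation contribution_pct
#> 1 tcr    As               0.839           75.6
#> 2 tcr    ir               0.324           11.3
#> 3 tcr    ef               0.319           10.9
```

Read: both wetland groups are Hg-dominated (`p_max` ≈ 3.2 urban, 5.0
rural), putting the urban group at a moderate and the rural group at a high
contamination level. The total cancer risk sits in the "low" band
(10⁻⁶–10⁻⁴) for every population, the total hazard index exceeds 1 only
for rural children, and the arsenic concentration is by far the dominant
driver of the cancer-risk uncertainty.

A command-line front end over the same functions lives at
`inst/cli/wetrisk.R` (`simulate`, `assess`, `mc` subcommands; each run
writes a `manifest.json` with seed, config hash and input digests).

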
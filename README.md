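# halorisk

Analysis toolkit for urban **volatile halogenated hydrocarbon (VHH)**
monitoring campaigns: composition and background-enhancement statistics,
uncertainty-weighted positive matrix factorization (PMF) for source
apportionment, and probabilistic carcinogenic / non-carcinogenic inhalation
risk assessment with replicated Monte-Carlo convergence diagnostics and
Sobol total-order sensitivity analysis.

The intended users are atmospheric chemists and exposure scientists working
with canister-sampling campaigns of halocarbons — Montreal-Protocol-regulated
CFCs (Freon-11, Freon-12, carbon tetrachloride, ...) and unregulated
chlorinated very short-lived substances (methylene chloride, chloroform,
1,2-dichloroethane, ...) — measured as mixing ratios (pptv) over a handful of
daily sampling windows. A synthetic-campaign generator with planted source
structure supports method validation when raw data cannot be shared.

## The models

**Exposure and risk.** For each species the ambient mixing ratio is converted
to a mass concentration CA (µg m⁻³) via the molar volume (24.45 L mol⁻¹ at
25 °C, 1 atm), then:

    EC  = CA · ET · EF · ED / AT        exposure concentration (µg m⁻³)
    LCR = EC · IUR                      lifetime cancer risk
    HQ  = EC / (RfC · 1000)             hazard quotient
    HI  = Σ HQᵢ                         hazard index

with chronic residential defaults ET = 24 h d⁻¹, EF = 365 d a⁻¹,
ED = 74.8 a, AT = ED·365·24 h (so EC = CA exactly). LCR below 10⁻⁶ is
negligible, above 10⁻⁴ definite concern; HI > 1 flags potential
non-carcinogenic risk. Uncertainty is propagated by replicated Monte Carlo
(by default 100 replications × 10 000 draws) with the convergence diagnostic
MCE/SD — the standard deviation of replication means over the minimum
within-replication SD — required to stay below 5%. Input influence is ranked
by Sobol total-order indices (Jansen estimator on Saltelli blocks).

**Source apportionment.** The samples × species matrix X is factorized as
X ≈ G F with G, F ≥ 0 by minimizing the uncertainty-weighted objective

    Q = Σᵢⱼ ((xᵢⱼ − Σₖ gᵢₖ fₖⱼ) / uᵢⱼ)²

using monotone multiplicative updates with multi-start. Uncertainties follow
the standard receptor-model rules: u = √((0.1·C)² + MDL²) for quantified
values, MDL/2 substitution with u = 5/6·MDL below the detection limit, and
median imputation with 4× median uncertainty for missing cells.

## Worked example

```r
library(halorisk)
registry <- load_registry(vhh_species())     # packaged 14-species table
means   <- vhh_campaign_means()              # campaign means/SDs (pptv)

comp <- composition_summary(means, registry)
comp$grand_total
#> [1] 2924
comp$groups
#>           category total share_pct
#> 1    regulated_CFC  1038      35.5
#> 2 unregulated_VSLS  1886      64.5

enhancement_table(means, registry)[1:2, c("name", "absolute_enhancement",
                                          "percent_enhancement")]
#>       name absolute_enhancement percent_enhancement
#> 1 Freon-12                   62               12.38
#> 2 Freon-114                   1                6.25

rt <- risk_table(means, registry)
rt$cumulative_LCR; rt$HI
#> [1] 4.12e-05
#> [1] 0.243
```

The composition summary says regulated CFCs carry 35.5% of the 2924 pptv
total burden and unregulated VSLSs 64.5%; Freon-12 sits 62 pptv (12.4%)
above its hemispheric background, the signature of residual CFC banks. In
the deterministic risk table four species — 1,2-dichloroethane, chloroform,
carbon tetrachloride and 1,2-dichloropropane — exceed the 10⁻⁶ acceptable
cancer-risk level, and trichloroethylene and 1,2-dichloropropane are the two
largest hazard-index contributors.

A full pipeline run (synthetic campaign → descriptive statistics → PMF →
risk → distribution fitting → Monte Carlo → Sobol) is one call:

```r
bundle <- run_pipeline(run_config(output_dir = "out", seed = 1))
render_report(bundle)
```

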
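---
title: "Methods: halocarbon campaign statistics, source apportionment and probabilistic inhalation risk"
author: "halorisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: halocarbon campaign statistics, source apportionment and probabilistic inhalation risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halorisk)
```

## Scope and data model

`halorisk` analyses short urban canister campaigns of volatile halogenated
hydrocarbons (VHHs): a wide sample-by-species table of mixing ratios (pptv)
with a date and a diurnal window label per sample, accompanied by a species
registry of physical and toxicological constants. The packaged registry
covers 14 species — six Montreal-Protocol-regulated CFCs (with bromomethane
counted in the regulated group despite its short lifetime, because it is
Protocol-controlled) and eight unregulated chlorinated very short-lived
substances (VSLSs).

Column provenance of the packaged registry deserves care: molecular weights
are standard; lifetimes, ODP, GWP100 and hemispheric background mixing
ratios are campaign-level literature constants; inhalation unit risks (IUR)
and reference concentrations (RfC) are IRIS values supplemented by OEHHA
chronic RELs where IRIS is silent, with a provisional (HEAST-era) RfC for
1,1-dichloroethane. Per-species method detection limits are *synthetic*:
representative values placed within the 2–17 pptv range typical of TO-15
canister GC/MS work, because true MDLs are instrument-specific. Eight
species carry an IUR and ten an RfC, which fixes the carcinogenic and
non-carcinogenic assessment sets.

## Unit conventions

Mixing ratios convert to mass concentrations as
`µg m⁻³ = pptv · MW / (V_m · 1000)` with molar volume `V_m = 24.45 L mol⁻¹`
(25 °C, 1 atm). The convention is exposed as a parameter because campaign
reports are often silent about it; switching to 0 °C (22.4) rescales all
mass-based results by ~9%, which matters when comparing LCR values across
studies. The conversion is linear and round-trips to machine precision.

## Detection filtering and descriptive statistics

A species is *detected* in a sample when its value is at or above the
species MDL; missing values count as non-detections. The retention rule is
strict: a species is kept only if its detected fraction exceeds the
threshold (default 0.60), so 29 detections out of 49 samples (59.2%) drops
a species. Composition shares are computed on the per-species means of
samples (matching how campaign papers tabulate them), not as averaged
per-sample shares; the two differ under skewed concentrations. Background
enhancement is reported absolutely (mean − background, pptv) and as a
percentage of the background. Pairwise associations use Pearson correlation
with two-sided p-values from the t-transform; columns with zero variance
yield undefined (NA) pairs with a warning rather than a number.
Tracer-regression slopes (species on CO) are ordinary least squares with
intercept — the emission-ratio estimate used to compare against source
profiles.

## Positive matrix factorization

The receptor model decomposes the prepared concentration matrix as
`X ≈ G F` (contributions × profiles, both nonnegative) by minimizing

$$Q = \sum_{i}\sum_{j} \left(\frac{x_{ij} - \sum_k g_{ik} f_{kj}}{u_{ij}}\right)^2.$$

Cell uncertainties follow the standard receptor-model rules: quantified
values get `u = sqrt((0.1 c)² + MDL²)` (the 10% proportional error fraction
is configurable); values below the MDL are replaced by MDL/2 with
`u = 5/6·MDL`; missing values are imputed with the species median and
downweighted with `u = 4 × median`. The solver uses weighted multiplicative
updates, which keep all entries nonnegative and make Q nonincreasing at
every iteration — a property the test suite asserts on every trace — with
multi-start (default 20 random initializations) and lowest-Q selection,
ties going to the earliest start. `Q_expected = n·m − p·(n+m)` is reported
for diagnostics only; the factor count is user-specified. Degenerate zero
entries are floored at 1e-12 to keep the updates alive. No rotational
(Fpeak-style) exploration is performed.

### Identifiability and the limits of share recovery

Nonnegative factorizations are identifiable only up to permutation and
scale, and — without zero patterns in both factors — often not even that.
The package therefore ships `match_factors()`, an exact enumeration over
factor permutations maximizing total cosine similarity of row-normalized
profiles. Two observations from the validation suite are worth stating
plainly:

* For the `generate_pmf_testcase()` oracle, planted truths are made
  identifiable by two-sided anchoring (a marker species per source and a
  pure-plume sample per source). Without such anchors an exact noiseless
  fit can be a valid rotation of the truth, and asserting recovery would be
  meaningless.
* For the full synthetic campaign (49 samples, four sources, 10%
  multiplicative noise, standard uncertainty rules), the minimum-Q solution
  does **not** pin down factor contribution shares to better than a few
  percentage points: solutions whose Q values agree to seven significant
  digits can differ by several points in their share split, and a fit
  initialized at the planted truth converges to a nearby *local* minimum
  that recovers shares almost exactly while the *global* minimum carries a
  few points of contamination. This is a property of the weighted
  least-squares objective under proportional uncertainties computed from
  noisy observations, not of the optimizer; it persists with more samples
  and alternative generator designs. Practitioners should treat PMF share
  estimates at this campaign scale as carrying an uncertainty of several
  percentage points, which is precisely why bootstrap/displacement error
  estimation exists in production receptor-model tools (out of scope here).

## The synthetic campaign generator

`generate_campaign()` emulates the statistical structure the analysis
assumes: 7 days × 7 daily windows (49 samples) over the 14-species
registry; a near-constant "CFC bank leakage" source carrying the regulated
species (activity CV 3%); and three diurnally modulated industrial sources
carrying the VSLSs with planted mass-contribution shares of
19.9 / 27.8 / 23.7 / 28.6% (CFC banks, industrial process, solvent use,
electronics cleaning). Concentrations are `X = (G F) ∘ ε` with
multiplicative lognormal noise, which preserves nonnegativity without
truncation and keeps the planted factorization exact up to noise. Design
choices that were genuinely open:

* **Diurnal modulation sits in the sources (G), not the species.** A
  per-species multiplier applied after the product would break
  `X = G F ∘ ε` exactly; species inherit the U-shape from the sources they
  load on. The shared U-shape (morning peak, minimum in the 16 h window,
  evening peak) is meteorologically motivated — boundary-layer dilution
  acts on all surface emissions alike.
* **Per-species noise.** Regulated CFCs get 3% measurement noise and
  unregulated species 10%. A single 10% floor would contradict the
  near-constant CFC columns (coefficients of variation of a few percent)
  that long-lived, phased-out species exhibit in real campaigns.
* **Profiles are disjoint-support blocks** scaled from the campaign's
  per-species means. Real factor loadings mix species across factors, but a
  mixed CFC loading on a diurnally varying source would destroy the CFC
  low-variability constraint; with shares pinned to the planted values, the
  generated species-level composition therefore only approximates the
  campaign's.
* **Within-day draws are independent** given the window multiplier; the
  real autocorrelation of consecutive canisters is unknown and not
  simulated. Weekday/weekend source switching, meteorology-driven
  dispersion and boundary-layer physics are likewise not simulated — the
  CO tracer is a linear coupling to the solvent source plus Gaussian noise,
  sufficient to exercise tracer regressions but not a combustion model.

Passing recovery tests on these campaigns therefore demonstrates algorithmic
correctness under the assumed structure, not fidelity to any particular real
atmosphere.

## Deterministic risk chain

With the chronic defaults (ET 24 h d⁻¹, EF 365 d a⁻¹, ED 74.8 a,
AT = ED·365·24 h) the exposure factor cancels to 1 and EC equals CA — a
unit identity the tests assert exactly. Species lacking an IUR (or RfC) are
excluded from the corresponding sums. Classification thresholds: LCR below
1e-6 negligible, 1e-6 to 1e-4 potential, above 1e-4 definite; values
exactly at 1e-6 classify as *potential* (closed lower bound — the
convention had to be chosen, and the conservative side was taken). HI ≤ 1
is negligible. Published campaign point risks are generally **not**
reproducible from tabulated means plus database toxicity values: unrounded
concentrations, the exact IUR/RfC vintages and the Monte-Carlo averaging
conventions behind published numbers are rarely stated. The package reports
its own computed values; with the packaged registry, the same four species
(1,2-dichloroethane, chloroform, carbon tetrachloride, 1,2-dichloropropane)
exceed the 1e-6 level, and trichloroethylene and 1,2-dichloropropane lead
the hazard-index contributions.

## Distribution fitting

`select_distribution()` fits candidate families (default normal and
lognormal; point, uniform and triangular also supported) and ranks them by
the Anderson–Darling statistic computed against each fitted CDF:

$$A^2 = -n - \frac{1}{n}\sum_{i=1}^n (2i-1)\left[\ln F(x_{(i)}) + \ln(1 - F(x_{(n+1-i)}))\right].$$

Ranking is by the statistic, not a p-value: composite-hypothesis critical
values (Stephens corrections) differ per family, while the statistic gives
a consistent relative ordering, which is all a family selection needs. CDF
values numerically at 0 or 1 are clamped with a warning. Below-MDL values
are replaced by MDL/2 before fitting, consistent with the receptor-model
censoring. Lognormal parameters are the mean and SD of the log values
(`stats::sd`, n−1 denominator — the difference from the strict MLE is
negligible at campaign sample sizes and keeps consistency with the
reference normality test used for cross-checking).

## Replicated Monte Carlo and the MCE/SD diagnostic

`run_mc()` propagates per-species concentration distributions and exposure
parameter distributions through the risk chain in `n_rep` replications of
`n_iter` draws (defaults 100 × 10 000). Within a draw, ET/EF/ED are shared
across species; concentration draws are independent across species (no
cross-species correlation model is assumed). The convergence diagnostic is

* MCE = standard deviation of the replication means (the Monte-Carlo error),
* SD = **minimum** of the within-replication standard deviations — taken
  literally as the minimum, a conservative reading that inflates the ratio,
* ratio = 100·MCE/SD, acceptable below 5%; a zero SD makes the ratio
  undefined and it is reported as NA, never as infinity.

For i.i.d. outputs the expected ratio is ≈ 100/√n_iter (1% at 10 000), and
the suite verifies both the level and the 1/√n scaling (quadrupling the
draws halves the MCE within ±30%).

Default input specifications — assumptions, all overrideable: CA lognormal
moment-matched to the campaign mean/SD (`sdlog² = log(1+(sd/mean)²)`); ET
and EF point values (24, 365); ED normal with 10% CV truncated to (0, 100]
years; IUR/RfC point values. AT is derived as ED·365·24 *within each draw*
(fully correlated with ED, making the exposure factor insensitive to ED);
an independent-AT mode exists for sensitivity experiments. Replication
seeds are spawned deterministically from the master seed, so increasing
`n_rep` extends rather than reshuffles earlier replications, and identical
configurations are bit-reproducible.

## Sobol total-order sensitivity

`saltelli_matrices()` draws base blocks A and B plus one column-swapped
block per input; `total_order_indices()` applies the Jansen estimator
`S_T = mean((f(A) − f(AB))²) / (2·Var f)` with the variance over the
combined base evaluations. Blocks use Latin-hypercube stratified uniforms
per column mapped through the inverse CDF — marginals stay exact in
distribution while estimator variance drops relative to plain random
sampling, which is what lets closed-form test oracles (the additive
two-input model and the Ishigami function) be checked at ±0.02–0.03 with
N = 2¹⁴–2¹⁵. Inputs are treated as independent; small negative estimates
are reported raw with bootstrap standard errors, never clipped; ties in the
ranking break alphabetically. With the derived-AT rule ED cancels out of
the risk chain, so ED sensitivity is only observable in the independent-AT
mode — the same modelling fork as in the Monte-Carlo module.

## Problem sizes and numerical choices

The test suite runs the full-scale replicated Monte Carlo (100 × 10 000),
PMF with 20 restarts on the 49 × 14 campaign, and Sobol designs up to
N = 2¹⁵ — all within a few minutes on one core. PMF convergence is declared
at a relative Q change below 1e-8 per iteration (cap 5000 iterations);
multiplicative updates have slow tails, so the convergence flag signals a
stationary Q, not a certified global optimum — hence the multi-start.
Quantile summaries (p95) use the linear-interpolation convention. All
generators take explicit integer seeds and are byte-reproducible.

## Known limitations

* PMF share estimates carry several percentage points of rotational
  uncertainty at campaign scale (see above); no bootstrap/displacement
  error estimation and no Fpeak rotations.
* The risk model is inhalation-only, single-population, with no
  age stratification; toxicity values are treated as fixed unless a
  distribution is supplied.
* The synthetic generator does not emulate meteorology, weekday/weekend
  effects or autocorrelation, and its species-level composition
  approximates (not reproduces) the packaged campaign means.
* Distribution selection reports the A² ranking only, without
  composite-test p-values.
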
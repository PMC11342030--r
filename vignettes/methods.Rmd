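---
title: "Soil PAH characterization and multi-route health risk: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil PAH characterization and multi-route health risk: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahsoilrisk)
```

## The problem

Soils around automobile repair workshops accumulate polycyclic aromatic
hydrocarbons (PAHs) from spent engine oil, fuel spills and exhaust
deposition. Sixteen PAHs are USEPA priority pollutants, seven of them
(BaA, CHR, BbF, BkF, BaP, IcP, DhA) classified B2 carcinogens. Given a
table of per-compound soil concentrations (µg/g dry soil, equivalently
mg/kg), this package answers three questions:

1. **What is in the soil?** Per-compound summary statistics and
   composition profiles by aromatic ring number and molecular-weight
   class (LMW = 2–3 rings, MMW = 4 rings, HMW = 5–6 rings). HMW dominance
   is a crude marker of pyrogenic/petroleum-product input.
2. **How toxic is the mixture?** Each concentration is converted to
   benzo[a]pyrene equivalents via toxicity equivalence factors:
   $TEQ_i = C_i \times TEF_i$, summed over compounds. The package ships
   the Nisbet–LaGoy TEF scheme (BaP = DhA = 1 down to 0.001 for the light
   compounds), which is data-driven and swappable via a registry CSV.
3. **What risk does contact pose?** Incremental lifetime cancer risk
   (ILCR) by three routes, plus a non-carcinogenic hazard quotient.

## The exposure model

For a receptor with body weight $BW$ (kg), averaging time $AT$ (days),
exposure frequency $EF$ (days/yr) and duration $ED$ (yr):

$$ILCR_{ing} = \frac{C \cdot CSF_{ing} \cdot (BW/70)^{1/3} \cdot IR_{ing} \cdot EF \cdot ED}{BW \cdot AT \cdot 10^6}$$

$$ILCR_{inh} = \frac{C \cdot CSF_{inh} \cdot (BW/70)^{1/3} \cdot IR_{inh} \cdot EF \cdot ED}{BW \cdot AT \cdot PEF}$$

$$ILCR_{derm} = \frac{C \cdot CSF_{derm} \cdot (BW/70)^{1/3} \cdot SA \cdot AF \cdot ABS \cdot EF \cdot ED}{BW \cdot AT \cdot 10^6}$$

$$HQ = EDI / RfD, \qquad EDI = \frac{CS \cdot IR \cdot ED \cdot EF \cdot CF}{AT \cdot BW}$$

$(BW/70)^{1/3}$ rescales slope factors derived for a 70 kg reference
adult and appears in **all three** routes. The $10^6$ divisor converts mg
of soil to kg; the particulate emission factor $PEF$ (m³/kg) plays that
role for inhalation and, at $1.36\times 10^9$, pushes inhalation risk
about four orders of magnitude below the other routes.

### Parameters, defaults, units

| parameter | adult | child | unit |
|---|---|---|---|
| soil ingestion rate `ir_ing` | 100 | 200 | mg/day |
| inhalation rate `ir_inh` | 20 | 10 | m³/day |
| exposed skin `sa` | 5700 | 2800 | cm² |
| adherence `af` | 0.07 | 0.2 | mg/cm² |
| dermal absorption `abs` | 0.13 | 0.13 | — |
| frequency `ef` | 365 | 365 | days/yr |
| duration `ed` | 24 | 6 | yr |
| body weight `bw` | 60 | 18 | kg |
| averaging time `at` | 25550 | 25550 | days |

Slope factors: $CSF_{ing} = 7.3$, $CSF_{inh} = 3.85$, $CSF_{derm} = 25$
(per mg/kg/day, BaP-based screening values). Every default is
overridable through `exposure_profile()` / `slope_factors()`.

### Design choices that were genuinely open

- **Concentration basis.** The exposure equations are driven by the
  *summed mean* compound concentration (the site's total PAH burden), not
  by the TEQ total — reverse computation against the published
  ingestion/dermal/HQ cells confirms this convention. `run_pipeline()`
  exposes a `concentration_basis` switch (`"total"`, `"teq"`, or a single
  compound) for analysts who prefer a BaP-equivalent or compound-specific
  basis.
- **Reference dose.** No compound-specific RfD applies cleanly to a
  summed concentration. The default $RfD = 2.0\times10^{-3}$ with
  $CF = 1$ is the unique value that reproduces both receptors' published
  hazard quotients to two decimals from one shared constant — a useful
  internal-consistency anchor. Both are mandatory, swappable fields for
  real assessments with USEPA compound RfDs.
- **Averaging time.** $AT = 25550$ days (70 yr) is used for cancer *and*
  non-cancer calculations alike. Standard practice would use
  $ED \times 365$ for non-cancer; the shared value is kept because it is
  the tabulated screening convention this analysis reproduces.
- **Child inhalation rate.** Screening tables quote both 9.6 and 10
  m³/day; 10 is the default, 9.6 an override. Either changes the child
  inhalation ILCR only in the second significant figure.
- **Standard deviation.** Sample (n−1) by default, the convention for
  field replicates; population available. Single-location tables yield
  std = 0 with a warning so toy examples stay runnable.
- **Thresholds.** `classify_risk()` uses strict inequalities: a risk of
  exactly $10^{-6}$ or an HQ of exactly 1 is not flagged.
- **Non-detects.** `read_concentrations()` can substitute values below a
  detection limit with 0 (default, matching campaigns that report
  non-detects without blank correction), DL/2, or DL.

## Known irreproducibilities in the reference figures

The packaged reference summary (`reference_summary()`) carries a few
internal inconsistencies of its source, which the package documents
rather than patches:

- The printed summed mean is **98.34** µg/g while the 16 printed compound
  means sum to **98.37**. `reference_total()` returns 98.34 — the value
  the published risk figures were computed from — while
  `summarize_concentrations()` always reports the recomputed sum.
- The published child ingestion ILCR ($4.4\times10^{-4}$) and adult
  inhalation ILCR ($3.2\times10^{-8}$) are not recoverable from the
  stated equations at full precision: they recompute to
  $4.35\times10^{-4}$ and $3.0\times10^{-8}$. The first matches rounding
  the cube-root term to 0.64 before multiplying, the second matches
  omitting the cube-root term. The package keeps the equations exact and
  reports the recomputed values.
- The published child *total* ILCR ($9.8\times10^{-5}$) is an
  order-of-magnitude slip: the published child route values themselves
  sum to $\approx 9.8\times10^{-4}$, which is what `total_ilcr()`
  reports.
- The published composition percentages by ring and MW class were
  evidently computed over unpublished per-location data; from the printed
  means only the ordinal claims (5-ring class largest, HMW-dominant)
  hold, and only those are asserted in tests.

## The synthetic-site generator

`generate_site()` draws each location × compound cell independently from
a lognormal with the compound's target **arithmetic** mean: for target
$m$ and shape $\sigma$, $\mu = \log m - \sigma^2/2$ so $E[X] = m$.
Lognormal marginals capture the right skew and nonnegativity of soil
contaminant data; arithmetic-mean parameterization makes the generated
tables reproduce the "Mean" semantics of the reference summary. Defaults
(`default_profile()`): the 16 reference means as targets, global
$\sigma = 0.5$ (a moderate, realistic between-location coefficient of
variation of ~53%), 5 locations — the scale of a small field campaign.
Compounds with target mean 0, or $\sigma = 0$, generate as constants;
output is bit-identical under a fixed seed.

What the generator does **not** emulate: correlation between compounds
(real PAH profiles co-vary strongly with source), spatial
autocorrelation, censoring at detection limits, and measurement error of
the analytical chemistry. Passing recovery tests therefore shows the
computational chain is unbiased under independent lognormal sampling,
not that field campaigns of 5 locations pin down risk to a few percent.

## Numerical scale of the validation

The parameter-recovery check regenerates a 2000-location site under a
fixed seed and requires the recovered total TEQ, total ILCRs and HQs to
land within 5% of the values implied by the target means; at that sample
size the relative standard error of each column mean is ~1.2%, so 5% is
a comfortable but non-vacuous band. The whole test suite and the
reproduction script run in seconds; all heavier exploration
(`analysis/03_synthetic_validation.R`) stays under a few thousand
locations because the estimators' convergence is already visible there.

## Limitations

- The route equations are deterministic screening formulas; no
  Monte-Carlo uncertainty propagation, no age-integrated exposure.
- Dermal absorption is a single mixture-wide fraction, not
  compound-specific.
- The TEQ scheme addresses carcinogenic potency only (no mutagenic or
  dioxin-like equivalence).
- Summing a shared-RfD hazard quotient over a mixture is a screening
  convention, not a toxicological statement about additivity.
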
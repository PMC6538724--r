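---
title: "The gamma-Poisson model of nanoparticle uptake: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gamma-Poisson model of nanoparticle uptake: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlvuptake)
```

## The model and its assumptions

Endocytosis is treated as a spatial Poisson process over the cell membrane:
a cell of area $A$ forms $N_\mathrm{end} \sim \mathrm{Poisson}(\mu A t)$
endosomes during an exposure of $t$ hours, where $\mu$ is the endosome
generation rate per unit area per hour. Each forming endosome stays open
for a lifetime of roughly 40–400 s, during which arriving
nanoparticles/agglomerates are captured as a Poisson process with mean
$\Delta$ arrivals per window, $\Delta$ proportional to the administered
concentration $C$. Four assumptions carry the whole derivation:

1. **Rare capture.** At nanomolar doses particle arrival is much slower
   than membrane turnover, so $\Delta \ll 1$: the probability a forming
   endosome is loaded is $1 - e^{-\Delta} \approx \Delta \approx \kappa C$,
   and multiply-loaded vesicles are rare
   ($P(\ge 2 \mid \ge 1) \approx \Delta/2$). This is why the dose *per
   vesicle* is invariant to $C$ and $t$ while the *number* of loaded
   vesicles scales with them.
2. **Thinning.** Retaining each endosome independently with probability
   $\approx \kappa C$ thins the Poisson stream, so
   $N_\mathrm{NLV} \mid A \sim \mathrm{Poisson}(\lambda A C t)$ with
   $\lambda = \mu \kappa$.
3. **Gamma areas.** Cell areas across the population follow
   $\Gamma(\alpha, \beta)$; a Poisson count whose rate is gamma-mixed is
   marginally negative binomial with $r = \alpha$,
   $p = \beta\lambda C t / (1 + \beta\lambda C t)$, and mean
   $\nu_\mathrm{nb} = p r/(1-p) = \lambda\,\alpha\beta\,Ct$.
4. **Quasi-stationarity.** Exposures are short (0.5–2 h) relative to the
   cell cycle: area is constant during exposure, vesicle fusion and
   endosome inheritance at division are negligible.

The per-cell fluorescence law is the compound distribution of a negative
binomial number of i.i.d. per-vesicle intensities, with an atom at zero of
mass $(1-p)^r$ for cells with no NLVs. We implement the full compound
distribution and expose its mean $\nu_\mathrm{nb}\,E[I]$ as a by-product;
the mean alone would discard exactly the population heterogeneity the
model exists to describe.

## Parameters, units and defaults

| parameter | meaning | units | default / typical |
|---|---|---|---|
| `concentration` | administered dose | nM | 0.5–5 |
| `duration` | exposure time | h | 0.5–2 |
| `shape`, `scale` ($\alpha,\beta$) | gamma law of cell area | –, area units | 2, 500–1500 |
| `lam` ($\lambda$) | NLV formation rate | nM⁻¹ h⁻¹ area-unit⁻¹ | ~0.001 |
| `mu` ($\mu$) | endosome rate | area-unit⁻¹ h⁻¹ | ~1 (≫10² endosomes/cell/h) |
| `delta` ($\Delta$) | mean arrivals per forming endosome | – | ≤ 0.01 |
| `lifetime_range` | endosome formation window | s | 40–400 |

**Area units.** Published values of $\lambda$ for these cell lines are
quoted as 0.00107 (BEAS-2B) and 0.00135 (A549) per nM per h per unit area,
with areas measured on the micrometre scale of segmentation output. We
deliberately parameterise $\lambda$ "per area-unit" and never convert
between m² and µm²: segmented areas and $\lambda$ must simply share a unit,
and $\lambda \cdot \alpha\beta \cdot Ct$ must land in the observed 1–40
NLV range. No silent unit conversion is performed anywhere.

**$\Delta$ parameterisation in the simulator.** The mechanism couples
capture to dose but fixes no functional form beyond proportionality, so
the simulator uses $\Delta_i = \kappa' C \cdot L_i / 220\,\mathrm{s}$ for
an endosome with lifetime $L_i$ drawn uniform on `lifetime_range` — the
reference lifetime 220 s is the midpoint of the 40–400 s window. The
lifetime-averaged capture probability has the closed form implemented in
`effective_capture_prob()`, which is what makes the simulator's implied
negative binomial (`thinning_reference_nb()`) available analytically.
Endosome start times are taken uniform in $[0, t]$; window overhang at the
boundary is ignored since lifetimes are seconds against exposures of
hours.

**Intensity family.** Per-vesicle intensity histograms are positive,
unimodal and right-skewed; no specific parametric family is canonical. The
default is lognormal (`meanlog = log(500)`, `sdlog = 0.5`, arbitrary
fluorescence units), with gamma available; the family is pluggable behind
`intensity_model()`. The simultaneous fit pools all conditions into one
maximum-likelihood estimate and reports per-condition KS distances to the
shared curve as the dose-invariance diagnostic.

## What the synthetic generator emulates — and what it does not

`generate_population()` reproduces the statistical structure the analysis
assumes: gamma areas (G2 cells scaled by `g2_area_factor`, default 1.6),
counts Poisson in $\lambda A C t$, i.i.d. dose-invariant vesicle
intensities, bimodal G1/G2 nuclear intensity (modes $m$ and $2m$, cv 7%,
G2 fraction 0.3, truncated-normal components, no S-phase bridge). Exact
table reconciliation (counts and intensity sums) and byte-identical output
under a fixed seed are tested invariants. Optional multiplicative
lognormal measurement noise is off by default so analytic identities hold
exactly.

It does **not** emulate segmentation error, spatial field-of-view effects,
background subtraction residuals, vesicle fusion, particle depletion, or
biological rate heterogeneity beyond area. Consequently, passing tests
show the *pipeline* is correct under the model's own assumptions — they
cannot show that real cells obey those assumptions. Two places where the
idealisation is visible:

* **Cycle-coupled areas are a gamma mixture.** With `g2_area_factor > 1`
  the marginal area law is a two-component gamma mixture, so the
  single-gamma negative binomial is (slightly) mis-specified at high dose
  and a chi-squared test will detect this given enough cells. $\lambda$
  recovery is unaffected (the gamma MLE matches the sample mean exactly,
  and only the mean enters the slope quotient). Goodness-of-fit
  calibration is therefore tested on data generated from the fitted model
  itself, and grid-level recovery checks use `g2_area_factor = 1`.
* **Per-area normalisation is exactly exchangeable only without area
  coupling.** Dividing counts by area equalises the *means* of the G1 and
  G2 gates, but $\mathrm{Var}(N/A \mid A) = \lambda C t / A$, so the gate
  with larger cells has less Poisson noise per unit area: the normalised
  distributions differ by a variance ratio of `g2_area_factor`
  asymptotically (sup-CDF distance ≈ 0.05 at factor 1.6). Real data add
  shared biological dispersion that masks this; the clean generator does
  not. The package's cycle tests therefore run at a few hundred cells per
  gate — ample power for the raw-count difference (D ≈ 0.25), while the
  small-count discreteness effect stays beneath the 0.1% critical value —
  and the exact exchangeability property is asserted at
  `g2_area_factor = 1`.

## Numerical choices

* **pmf truncation.** Adaptive support `0..K` starting at mean + 12 sd,
  doubled until the negative-binomial tail mass is below 1e-12; pmfs then
  normalise to 1 within 1e-9 in tests.
* **Numeric compound distribution.** The intensity density is discretised
  by CDF differences onto a uniform grid of ≥ 2048 points (default 4096)
  spanning zero to beyond the $1 - 10^{-6}$ compound quantile (mean +
  10 sd, padded for right skew), zero-padded to double length, and the
  negative-binomial pgf $G(z) = ((1-p)/(1-pz))^r$ is applied to the FFT of
  the lattice masses — equivalent to the NB-weighted sum of $N$-fold
  convolutions, with the zero atom emerging exactly as $(1-p)^r$. Negative
  round-off masses are clipped and the result renormalised (deficit
  ~1e-6). The stochastic route draws the compound sum directly; the two
  routes agree to < 0.01 sup-CDF distance in tests.
* **QC percentiles.** Linear-interpolation (type 7) percentiles; "outside"
  means strictly below the 5th or strictly above the 95th, so boundary
  ties are retained and degenerate inputs (all-equal areas, single rows)
  pass through. Percentiles are computed per condition when a
  `condition_id` column is present, matching per-experiment QC. A second
  application re-estimates percentiles and removes further rows — the
  filter is idempotent only up to that re-estimation, which is why the
  pipeline applies it exactly once.
* **Gamma MLE conditioning.** Areas are rescaled by their mean before
  `fitdistrplus` optimisation (scale ~10³ is poorly conditioned raw);
  standard errors are transformed back by the delta method. Because the
  gamma MLE reproduces the sample mean, $\hat\lambda =
  \mathrm{slope}/\hat\alpha\hat\beta$ is insensitive to the QC truncation:
  both numerator and denominator refer to the same filtered population.
  The refitted gamma is not literally the truncated density, so
  chi-squared prediction checks develop a small detectable bias at very
  large $n$; predictions are compared against the QC-filtered population.
* **Line fit.** Ordinary least squares with a free intercept (the model
  predicts intercept 0, and the intercept with its CI is reported as a
  model-adequacy diagnostic); inverse-variance weighting by per-condition
  standard errors is available but off by default.
* **Chi-squared binning.** Integer count bins pooled from the upper tail
  (then the lower end) until every expected count is ≥ 5, never below two
  bins; observed mass on a zero-expectation bin yields an unconditional
  rejection. Intensity histograms for display use Freedman–Diaconis
  binning; distribution comparisons use KS on the continuous values.
* **KS tests.** `ks_two_sample()` uses the asymptotic Kolmogorov p-value
  at effective size $n_x n_y/(n_x + n_y)$. For integer counts the
  continuous approximation is conservative in D and approximate in p; the
  normalised (count/area) comparisons are effectively tie-free.
* **Gating.** The mixture route fits a two-component Gaussian mixture to
  log nuclear intensity and places windows at mode ± 1.5 sd (capturing
  ~87% of each mode with < 2% cross-contamination for cv 7%); a fitted mode
  ratio outside [1.5, 2.5] (DNA doubling, with slack for staining
  non-linearity) raises an error
  advising manual gates, and touching windows are clipped at the log-scale
  midpoint. Cells between windows (S phase) belong to neither gate.

## Problem sizes

The test suite and acceptance script run at the scale the analysis is
designed for while staying desk-sized: rate-constant recovery uses the
full 12-condition design (0.5–5 nM × 0.5–2 h) at 5000 cells per condition;
thinning validation simulates 10⁴ cells at ~10³ endosomes each; the
dose-per-vesicle invariance check compares ≥ 10⁴ vesicles per condition
across a 16-fold dose–time range; cycle-normalisation behaviour is
replicated 100× at 1000 cells per replicate. Each of these completes in
seconds on one core.

## Known limitations

* One $\lambda$ per cell line: no per-condition refits, by design.
* No transport modelling of particles in the medium
  (diffusion/sedimentation), no vesicle fusion, no endosome inheritance at
  division, no toxicity-driven area change — all outside the short-exposure
  regime the model targets.
* The asymptotic KS p-value is approximate for heavily tied small-count
  data; compare raw counts at moderate gate sizes or rely on D directly.
* The intensity family is an empirical convenience, not a mechanistic
  claim; refit with `family = "gamma"` (or extend the family switch) if
  your vesicle histograms disagree with a lognormal.
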
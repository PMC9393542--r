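---
title: "Methods: probabilistic dietary risk assessment of potentially toxic elements in wheat grain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic dietary risk assessment of potentially toxic elements in wheat grain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainrisk)
```

## The problem

Wheat grown on soils affected by mining, sewage irrigation and agrochemical
use accumulates potentially toxic elements (PTEs). Because wheat is a staple,
chronic dietary exposure to even moderate grain concentrations of Cr, Ni, As,
Cd, Pb and F can be a public-health concern. `grainrisk` implements the
standard USEPA ingestion-route risk model for a sample-by-element
concentration table, both deterministically and with Monte Carlo uncertainty
propagation, together with the descriptive and multivariate screening stages
that normally precede it.

## The exposure model

The chronic daily intake of element *e* for population group *g* is
`C * EF * IR * ED / (BW * AT)` where `C` is the grain concentration (mg/kg
dry weight), `EF` the exposure frequency (days/year), `IR` the daily grain
intake (kg/day), `ED` the exposure duration (years), `BW` the body weight
(kg) and `AT` the averaging time (days).

* **Non-carcinogens**: the hazard quotient is intake divided by the oral
  reference dose, `HQ = C EF IR ED / (BW AT RfD)` with `AT = ED * 365`.
  Since `EF = 365`, HQ reduces algebraically to `C IR / (BW RfD)` and is
  independent of ED; the package exploits and tests this identity. The
  hazard index `HI` is the sum of HQs over co-occurring elements.
* **Carcinogens** (Cr, As, Cd, Pb): `CR = C EF IR ED / (BW AT) * SF` with
  `AT = 70 * 365`. The package uses `ED = 70` years (the lifetime) for the
  carcinogenic endpoint in *all* groups, so `EF ED / AT = 1` and
  `CR = C IR / BW * SF`. This convention is adopted because it alone
  reproduces the published mean CR values for As, Cd and Pb in every group,
  including children, for whom a nominal ED of 6 years combined with a
  lifetime AT would scale CR down by a factor of ~11.7 and contradict the
  published table. `TCR` is the within-draw sum of element CRs.

Tier boundaries are strict: HQ/HI above 1 flags risk; CR/TCR below 1e-6 is
negligible, within [1e-6, 1e-4] cautionary, above 1e-4 unacceptable. A value
exactly on a boundary goes to the lower tier, except that exactly 1e-6 is
cautionary (negligible requires strictly less), matching the conventional
phrasing of the band.

## Packaged configuration

Toxicity (`pte_toxicity()`): RfD in mg/kg/day — Cr 1.5, Ni 0.02, As 0.0003,
Cd 0.001, Pb 0.0035, F 0.06; SF in (mg/kg/day)^-1 — Cr 0.5, As 1.5, Cd 0.38,
Pb 0.0085; FAO grain limits in mg/kg — Cr 1.0, Ni 1.0, As 0.5, Cd 0.2,
Pb 0.2 (no current limit for F). The Cr reference dose is the conventional
oral value for trivalent chromium in food-ingestion work; it is a package
default, exposed in the JSON configuration, because published RfD
compilations for total Cr in grain vary. Zn (RfD 0.3) is accepted in user
configurations but is not part of the default element set, which contains
only measured elements.

Populations (`pte_populations()`): children BW 16.88 kg, IR 0.094 kg/day,
ED 6 y; adult females 57.03 kg, 0.160 kg/day, 70 y; adult males 66.2 kg,
0.160 kg/day, 70 y; EF 365 days/year for all. IR is interpreted as kg of dry
grain per day — the only reading under which these magnitudes give
plausible intakes.

## Descriptive stage

`summarize_concentrations()` reports mean, median, sample SD (n−1
denominator — survey convention; recorded in the output metadata because
printed tables cannot discriminate), min/max, CV and standard-limit
exceedance. CV classes: below 10% weak (natural control), 10–90% moderate,
above 90% strong (anthropogenic control); boundary values are moderate.
Exceedance is strict — a sample exactly at the FAO maximum meets it. An
element with mean zero gets an absent CV rather than an infinite one.

## Source identification

`spearman_matrix()` gives rank correlations with average-rank ties and
two-sided p-values; numeric p-values are reported rather than significance
stars. `kmo_measure()` computes the Kaiser–Meyer–Olkin adequacy index from
the anti-image of the Pearson correlation matrix
(`KMO = Σr² / (Σr² + Σq²)` over off-diagonal entries, with partial
correlations `q` from the inverse correlation matrix); it returns 0 for an
exactly diagonal correlation matrix (no shared variance).
`bartlett_sphericity()` uses `χ² = −(n−1−(2k+5)/6)·ln det(R)` on
`k(k−1)/2` degrees of freedom. `pca_concentrations()` performs unrotated
correlation-matrix PCA on z-scored columns (a log-transform switch is
provided but off by default — z-scoring is the minimal assumption for
correlation-based PCA); loadings are eigenvector × √eigenvalue, so entries
are variable–component correlations, with each component's sign fixed so its
largest-magnitude loading is positive; the component count defaults to the
Kaiser rule (eigenvalues > 1) with explicit override. Both diagnostics are
tested against closed forms on equicorrelation matrices, whose inverse and
leading eigenvalue `1 + (k−1)r` are analytic.

## Monte Carlo engine

`fit_concentration_distribution()` fits a lognormal by log-moment matching;
a bimodality screen (one- vs two-component Gaussian mixture on the log
scale, EM via mclust) switches to a two-component lognormal mixture when the
deviance improves by more than 15 — roughly a chi-square rejection at
p ≪ 0.01 on the three extra parameters, conservative enough that unimodal
columns never trip it. Fits are truncated to `[min/2, 2·max]` of the
observed sample so simulated tails stay physical. Zeros are treated as
non-detects and imputed at half the minimum positive value. A fitted mean
straying more than 10% from the sample mean attaches a warning.

`run_simulation()` draws every stochastic variable from its own substream,
deterministically derived from the root seed, so results are bit-reproducible
and adding an element leaves the other elements' draws untouched. Two
exposure configurations are provided:

* **A (point exposure, default)** — BW, IR, ED at their point values; Monte
  Carlo means then converge to the deterministic risks evaluated at the
  fitted concentration means, which is the tested convergence property.
* **B (full probabilistic)** — truncated-normal BW (CV 0.15, ±3σ),
  lognormal IR (CV 0.25, moment-matched), uniform ED (±20%). These spreads
  are conventional exposure-factor assumptions, used to exercise the
  sensitivity stage; the published study did not disclose its parameter
  distributions.

Element concentrations are sampled independently by default, or jointly
through a Gaussian copula on the table's Spearman matrix
(`conc_sampling = "joint"`). Percentiles use the linear-interpolation
convention (type 7), recorded in the output because percentile summaries are
convention-sensitive. Because the non-carcinogenic AT is tied to ED, ED
cancels within every HQ draw; its sensitivity contribution is therefore
structurally near zero in this model — a consequence of the stated
averaging-time rule, not a numerical artefact.

## Sensitivity analysis

`contribution_to_variance()` implements the spreadsheet-MC sensitivity
measure: signed squared Spearman correlation between each input and the
output, normalized so absolute contributions sum to 100%. A raw
rank-correlation mode is available as a switch. Constant inputs get zero
contribution with a warning; a constant output is an error.
`aggregate_concentration_sensitivity()` pools the per-element concentration
terms into a single C factor by summing squared rank correlations before
normalization.

`sensitivity_report()` runs this against a configuration-B simulation using
**joint** concentration sampling. This is a deliberate choice: the survey
elements are correlated, and sampling them independently splits what is
physically one co-varying concentration signal into six orthogonal inputs,
understating the pooled C term relative to IR (whose CV of 0.25 is
comparable to the effective concentration CV of the HI mix). With the
measured dependence retained, the concentration factor dominates both HI
(~50%) and TCR (~90%) in all groups and BW's contribution is negative, the
expected qualitative pattern; the exact percentages depend on the assumed
exposure spreads and are not asserted.

## Synthetic data generator

`generate_concentrations()` emulates the survey the analysis expects:
n = 149 samples of Cr, Ni, As, Cd, Pb, F. Marginals are lognormals
moment-matched to the survey mean/SD; Cr is a two-component lognormal
mixture (the survey's Cr histogram is plainly bimodal) whose constants were
calibrated by moment matching the clipped mixture to the survey mean, SD,
median and share above the 1 mg/kg limit — they live in the packaged spec
file, not in code. Dependence is a Gaussian copula: target Spearman entries
are mapped to latent Pearson correlations via `2 sin(π r/6)`, repaired to
the nearest positive-semidefinite correlation when needed; entries below
0.05 in magnitude are set to zero to keep the target well-conditioned.
Draws are clipped to the observed min/max (physical bounds of the survey);
the Ni minimum of exactly zero (non-detects) is floored at 0.0005 mg/kg.

Clipping bookkeeping: for a continuous variable, about 2/(n+1) of new draws
fall outside the extremes observed in n samples, so clipping alters ~1.5% of
draws under the defaults; the generator records the fraction and warns above
1% as a calibration guard. What the generator does **not** emulate: spatial
sampling structure, wheat-variety effects, measurement error, or the exact
PCA loadings of the original data — tests that pass on synthetic tables
certify the pipeline's statistics, not any property of the real region.

## Problem sizes and numerical choices

The test suite and acceptance checks use n = 149 generated samples
(10,000 for copula-consistency checks), 10,000 Monte Carlo iterations for
convergence and sensitivity assertions and 300–5,000 for structural ones;
Monte Carlo means are compared to analytic fitted means within three Monte
Carlo standard errors. Mixture quantiles are inverted numerically
(`uniroot`, tolerance 1e-10) on a bracket spanning both components; the
truncated lognormal mean uses the closed partial-expectation form. Risk-tier
comparisons are exact floating-point comparisons against the stated
boundaries.

## Known limitations

* Ingestion route only; no dermal or inhalation exposure.
* No Cr speciation (III vs VI) or bioavailability correction; total
  concentrations are treated as bioaccessible.
* The published Cr probabilistic risk rests on an unpublished distribution
  fit whose mean exceeds the sample mean by ~36%; the package reproduces
  the published means for the other elements and the Cr tier verdict, and
  makes no attempt to chase the Cr point values.
* Exposure-parameter spreads in configuration B are conventional defaults,
  not survey-derived; sensitivity magnitudes (as opposed to rankings and
  signs) depend on them.
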
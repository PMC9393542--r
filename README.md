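# grainrisk

Probabilistic human-health risk assessment of potentially toxic elements
(PTEs) in wheat grain, for exposure scientists and food-safety analysts.
Given a sample-by-element concentration table (mg/kg dry weight) of Cr, Ni,
As, Cd, Pb and F, the package runs the full assessment pipeline:

1. **Descriptive screening** — per-element summary statistics, coefficient
   of variation with weak/moderate/strong classification, and strict
   exceedance counts against FAO grain limits.
2. **Source identification** — Spearman correlation matrix with p-values,
   Kaiser–Meyer–Olkin sampling adequacy, Bartlett sphericity, and
   unrotated correlation-matrix PCA with variable–component correlation
   loadings.
3. **Risk computation** — deterministic and Monte Carlo evaluation of the
   USEPA ingestion-route model for children, adult females and adult males:

       HQ = C·EF·IR·ED / (BW·AT·RfD)        (AT = ED·365)       HI  = Σ HQ
       CR = C·EF·IR·ED / (BW·AT) · SF       (AT = 70·365)       TCR = Σ CR

   with tier classification (HQ/HI boundary 1; CR/TCR boundaries 1e-6 and
   1e-4).
4. **Sensitivity analysis** — signed contribution-to-variance (normalized
   squared Spearman correlation) of concentrations, intake rate, exposure
   duration and body weight on HI and TCR.
5. **Synthetic data** — a Gaussian-copula generator that emulates the
   survey's marginal statistics (including the bimodal Cr distribution) and
   rank-correlation structure, so the whole pipeline is testable without
   field data.

## Worked example

```r
library(grainrisk)

tab <- generate_concentrations(seed = 1)      # 149 synthetic samples
summarize_concentrations(tab)
#>   element   mean median     sd cv_percent cv_class exceeding_ratio_percent
#> 1      Cr 3.1918 1.3492 2.9382       92.1   strong                   60.40
#> 2      Ni 0.7083 0.5205 0.6672       94.2   strong                   20.13
#> 3      As 0.0552 0.0536 0.0107       19.4 moderate                    0.00
#> 4      Cd 0.1490 0.1140 0.1112       74.6 moderate                   22.15
#> 5      Pb 0.0364 0.0240 0.0387      106.3   strong                    1.34
#> 6       F 4.6177 4.2776 2.0446       44.3 moderate                      NA
```

Strong CV (>90%) for Cr, Ni and Pb points to anthropogenic control of those
elements; 60% of samples exceed the 1 mg/kg Cr limit.

```r
sim <- run_simulation(tab, n_iterations = 10000, seed = 7)
subset(sim$summary, group == "children")
#>  element endpoint     mean   median       sd      p95
#>       Cr       HQ 1.21e-02 5.27e-03 1.09e-02 2.86e-02
#>       Ni       HQ 1.95e-01 1.39e-01 1.84e-01 5.47e-01
#>       As       HQ 1.02e+00 1.00e+00 2.02e-01 1.38e+00
#>       Cd       HQ 8.25e-01 6.57e-01 6.16e-01 2.03e+00
#>       Pb       HQ 5.83e-02 3.90e-02 6.30e-02 1.71e-01
#>        F       HQ 4.32e-01 3.94e-01 1.99e-01 8.15e-01
#>    total       HI 2.55e+00 2.41e+00 7.07e-01 3.86e+00
#>       Cr       CR 9.06e-03 3.95e-03 8.17e-03 2.15e-02
#>       As       CR 4.61e-04 4.51e-04 9.10e-05 6.21e-04
#>       Cd       CR 3.14e-04 2.50e-04 2.34e-04 7.73e-04
#>       Pb       CR 1.74e-06 1.16e-06 1.88e-06 5.10e-06
#>    total      TCR 9.83e-03 4.75e-03 8.17e-03 2.23e-02
```

For children the mean arsenic HQ exceeds 1 (potential non-cancer risk) and
the mean TCR of 9.8e-3 is far above the 1e-4 unacceptable-risk boundary,
driven almost entirely by Cr. Which inputs drive the spread:

```r
simB <- run_simulation(tab, n_iterations = 10000, seed = 7,
                       exposure = "probabilistic", conc_sampling = "joint")
sensitivity_report(simB, "children", "TCR")
#>   variable    rho contribution
#> 1        C  1.022        90.05
#> 2       BW -0.172        -2.56
#> 3       IR  0.293         7.38
#> 4       ED -0.011        -0.01
```

The pooled grain-concentration factor contributes ~90% of the TCR variance;
body weight acts protectively (negative sign).

Deterministic point estimates from mean concentrations use
`point_estimate_risk()`, and single equations are available directly
(`hazard_quotient()`, `carcinogenic_risk()`, `classify_risk()`, ...).

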
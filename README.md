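# hepafat

Liver fat quantification from MR data, validated the way a diagnostic
imaging study validates it. The package implements three estimators of the
**proton-density fat fraction** (PDFF) of liver tissue at 3 T —
triple-echo and multi-echo spoiled gradient-echo imaging, and multi-TE
single-voxel PRESS spectroscopy — plus the histology reference standard
(NASH-CRN steatosis grading) and the statistical layer used to compare MR
against biopsy: Spearman correlation, ROC analysis with Youden thresholds,
DeLong paired AUC comparison, the Obuchowski AUC for an ordinal gold
standard, and linear models with steatohepatitis/fibrosis covariates. A
synthetic phantom and cohort generator, calibrated to a 73-patient
diabetic NAFLD population, stands in for patient data so every stage is
reproducible and testable.

It is intended for researchers in quantitative body MRI and for anyone who
needs a transparent, fully scriptable reference implementation of
magnitude-based fat–water separation and T2-corrected MRS fat
quantification.

## The models in brief

**Imaging.** An ROI's magnitude signal at echo time *TE* is

S(TE) = | W + F·c(TE) | · exp(−TE/T2\*),  c(TE) = Σₚ aₚ·exp(i·2π·Δfₚ·TE)

with W, F the water and fat proton densities and c(TE) the dephasing of a
six-peak fat spectrum. Bounded nonlinear least squares with multi-start
(both fat- and water-dominant basins) recovers (W, F, T2\*);
PDFF = F/(W+F). Rician noise bias is removed per echo via the
second-moment relation E[m²] = s² + 2σ².

**Spectroscopy.** Water and three measurable fat resonances are fitted in
the time domain as damped complex sinusoids with prior-knowledge
constraints (AMARES-style). Each peak's area is corrected for T2 decay
using the eight-echo TE series (40–110 ms), the hidden fat under the water
peak (8.6% of fat signal) is restored multiplicatively, and
PDFF = fat/(fat+water).

## Worked example

Simulate the default 73-subject cohort, quantify every subject with all
three MR methods, and evaluate against histology:

```r
library(hepafat)

cohort     <- simulate_cohort(cohort_spec(), seed = 42)
quantified <- quantify_cohort(cohort, snr = 50, seed = 43)
report     <- evaluate_cohort(quantified)

report$correlations
#> # A tibble: 3 × 3
#>   method   rho     n
#>   <chr>  <dbl> <int>
#> 1 triple 0.904    73
#> 2 multi  0.922    73
#> 3 mrs    0.918    73
```

All three methods track the biopsy percentage tightly (Spearman rho about
0.9 at acquisition SNR 50). Diagnostic accuracy for detecting *any*
steatosis (≥ mild, the clinically central cutpoint), with the
Youden-optimal PDFF threshold from the smoothed robust ROC:

```r
dplyr::filter(report$accuracy, cutpoint == "mild")
#>   method   auc threshold sensitivity specificity
#> 1 triple 0.962      3.54       0.821       0.972
#> 2 multi  0.995      2.63       0.914       0.988
#> 3 mrs    1          2.34       0.934       0.993
```

A threshold of about 2–4% PDFF separates normal from steatotic livers.
Grade-wise MRS medians rise monotonically with the histology grade and
the spread widens, as in real cohorts:

```r
dplyr::filter(report$group_medians, method == "mrs")
#>   method grade        n median    q25    q75
#> 1 mrs    none        10  0.189  0.108  0.248
#> 2 mrs    mild        31  5.27   3.55   6.39
#> 3 mrs    moderate    12 10.5    9.39  12.8
#> 4 mrs    severe      20 17.4   13.2   23.9
```

Single-subject estimation is just as direct:

```r
series <- simulate_gre_series(tissue_state(0.88, 0.12, t2star_ms = 22),
                              triple_echo_protocol(), snr = 100, seed = 7)
estimate_pdff_triple(series)
#> <fat_fraction_estimate 'triple'> PDFF 13.317%, T2* 17.4 ms, residual 1.11e-16, converged: TRUE
```

`run_study("out/", cohort_spec(), seed = 1)` performs the same
simulate → quantify → evaluate sequence through CSV/JSON artifacts on
disk, and `autoplot()` methods exist for ROC curves and echo series
(`plot_grade_pdff()` for cohort boxplots). The methods vignette
(`vignettes/liver-fat-quantification.Rmd`) documents the signal models,
the phantom's calibration and its limits, and every numerical convention.

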
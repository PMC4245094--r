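---
title: "Quantifying liver fat from gradient-echo MRI and PRESS MRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying liver fat from gradient-echo MRI and PRESS MRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(hepafat)
```

# The measurement problem

Hepatic steatosis is graded at biopsy by the percentage of fat-containing
hepatocytes (NASH-CRN bands: none < 5%, mild 5--33%, moderate 33--66%,
severe > 66%). MR offers a non-invasive surrogate, the **proton-density fat
fraction** (PDFF): the fat proton density divided by the total (fat + water)
proton density of the tissue. `hepafat` implements three estimators of PDFF
in a 3 T liver protocol -- triple-echo and multi-echo spoiled gradient-echo
imaging, and multi-TE single-voxel PRESS spectroscopy -- together with the
diagnostic-accuracy statistics used to validate them against biopsy, and a
synthetic phantom/cohort generator so that every stage is testable without
patient data.

The two scales are related but not equal: biopsy counts affected cells
while MR counts fat protons, so a fully steatotic liver corresponds to a
PDFF of roughly a third, not 100%. This matters for the regression models
discussed below.

# Signal models

## Multipeak fat spectrum

Both branches share one spectral model of liver triglyceride
(`default_fat_spectrum()`): six resonances at 5.3, 4.2, 2.75, 2.1, 1.3 and
0.9 ppm with relative amplitudes 0.047, 0.039, 0.006, 0.120, 0.700 and
0.088. Peaks between 0.5 and 3.0 ppm are *measurable* next to the water
line (4.7 ppm); the 5.3 and 4.2 ppm peaks lie under or against water and
are *hidden* -- 8.6% of the total fat signal that must be restored
multiplicatively (`hidden_fat_correction()`). Alternate coefficient tables
can be supplied as a small JSON document (`read_fat_spectrum()`).

## Gradient echo

A spoiled gradient-echo ROI measurement at echo time $TE$ follows

$$S(TE) = \left| W + F\,c(TE) \right| \, e^{-TE/T_2^*},
\qquad c(TE) = \sum_p a_p e^{i 2\pi \Delta f_p TE},$$

with $W, F \ge 0$ the water and fat proton densities, $c(TE)$ the complex
fat modulation of the spectral model ($\Delta f_p$ in Hz from water at the
scanner field via 42.576 MHz/T), and a single effective $T_2^*$. T1
weighting is omitted: the protocols use low flip angles (30 and 15 degrees
at TR 180 ms) precisely to suppress it. The model is magnitude-only; no
phase or field-map information is used.

The estimator (`fit_echo_model()`) is bounded nonlinear least squares over
$(W, F, T_2^*)$ with $T_2^* \in [1, 100]$ ms, run from a grid of starting
points spanning both the water-dominant and the fat-dominant basin --
magnitude data cannot distinguish them locally. The basin with the lower
residual wins; residual differences below the noise scale
($2\sigma^2\sqrt{2 n_{\text{echo}}}$) are treated as ties and resolved to
the physiological basin (PDFF < 0.5). With three echoes and three unknowns
the triple-echo fit is exactly determined; it still runs through the same
code path as the seven-echo fit so both protocols share one engine.

Magnitude noise is Rician, which inflates weak signals. When the noise SD
$\sigma$ is known (supplied, or estimated from a background region as
mean/$\sqrt{\pi/2}$), `noise_floor_correct()` applies the second-moment
relation $E[m^2] = s^2 + 2\sigma^2$, replacing each magnitude by
$\sqrt{\max(m^2 - 2\sigma^2, 0)}$. The correction is idempotent at
$\sigma = 0$. At very low fat fractions the positivity constraint
$F \ge 0$ itself induces a small upward bias that no noise-floor
correction can remove; the correction's benefit is cleanest in the
mid-range (PDFF around 10--40%).

## PRESS spectroscopy

The spectroscopy branch works in the time domain, in the spirit of AMARES:
a free-induction decay is modelled as a sum of exponentially damped
complex sinusoids with prior-knowledge constraints. Four resonances are
fitted -- water plus measurable fat at 2.1, 1.3 and 0.9 ppm (the tiny
2.75 ppm peak is unresolvable at 40--50 Hz linewidths and is absorbed by
the 2.1 ppm window). Frequencies are confined to $\pm$0.1 ppm windows and
dampings to 5--200 Hz; windows must not overlap.

Three design choices make the pipeline robust at realistic SNR:

* **One nonlinear fit per subject.** Frequencies and dampings are physical
  properties of the voxel and do not change along the TE train, so they
  are estimated once from the highest-SNR record (the 40-average
  single-echo acquisition, `fit_peaks()`) and the per-TE amplitudes of the
  eight multi-TE records are then solved by linear projection with that
  basis held fixed. Per-record nonlinear refits would let the overlapping
  fat peaks chase noise inside their windows.
* **Phase-coherent areas.** The modulus of a complex amplitude is
  positively biased for weak peaks (a Rayleigh-type floor), which flattens
  decay curves and corrupts T2 fits. All areas are therefore projected
  onto the water phase of the single-echo record, giving signed areas with
  zero-mean noise. (The protocol never suppresses water, so a strong
  water phase reference is always available; an input whose fitted water
  density falls below 5% of the total is rejected as pathological.)
* **Weak peaks borrow strength.** Each peak's T2 is fitted by
  `fit_t2_decay()` ($A(TE) = \rho e^{-TE/T_2}$, $T_2 \in [5, 500]$ ms)
  only when its areas clearly exceed their uncertainty (mean area over
  mean SE at least 5). Weaker fat peaks use the T2 of the *pooled* fat
  area, whose SE is computed from the full amplitude covariance --
  overlapping peaks have anticorrelated estimates, so the pooled signal
  is far better determined than its parts. If even the pooled signal is
  uninformative (essentially fat-free voxels) the nominal liver fat T2 at
  3 T (60 ms) is used; at that point the correction factor multiplies a
  near-zero area.

The final densities come from the single-echo areas corrected back to
TE = 0 with the fitted T2 values (`correct_single_echo()`), the measurable
fat densities are summed and divided by the measurable share (0.914) of
the spectral model, and PDFF is the density ratio. Because the hidden fat
resonances sit inside the fitted water line, a second pass subtracts the
modelled hidden-fat FID (hidden amplitudes, density-weighted fat T2 and
damping from the first pass) from every record and refits, so the water
density is free of that contamination; without this step the noiseless
end-to-end error grows to about one percentage point at PDFF 30%.

# The synthetic phantom and cohort

`simulate_cohort()` emulates the population structure of a 73-patient
diabetic NAFLD study: grade proportions 6/35/11/21, grade-conditional PDFF
medians 0.12/4.98/10.84/18.26 percent, steatohepatitis probability rising
with grade (about 37% overall), and fibrosis stage frequencies 52/12/6/2/1
over F0--F4. Within a grade, true PDFF follows a log-normal with the
stated median and log-SD 0.45, truncated to [0, 60]% -- positive,
right-skewed, and with IQRs that widen with grade, as the study reports.
The log-SD is a free calibration knob (per-grade dispersions are not
published); 0.45 reproduces interquartile ranges of the right order.
Histology is drawn inside the grade's band, rounded to the 5% increments a
pathologist scores, and coupled to true PDFF through a Gaussian copula
(correlation 0.8) so within-grade ranks agree. Per-subject $T_2^*$ is
log-normal around 20 ms (clamped to 10--35 ms); water T2 is 25 ms and fat
T2 60 ms, typical liver values at 3 T.

Acquisition simulators add complex Gaussian noise before the magnitude or
FID is formed. In both branches the noise SD is anchored to the observed
signal at the **first echo**: for imaging,
$\sigma = (W + F)e^{-TE_1/T_2^*} / \mathrm{snr}$; for spectroscopy the
single-average SD is the TE-40 FID envelope divided by `snr`, scaled by
$1/\sqrt{n_{\text{averages}}}$ per record (2 averages multi-TE, 40
single-echo). The default `snr = 50` puts the 40-average single-echo
spectrum in the comfortably clean regime a clinical 3 T scanner delivers.

What the phantom deliberately does **not** model: anatomy and partial
volume, respiratory motion, B0 inhomogeneity beyond a global 45 Hz
linewidth, eddy-current or receiver phase drift between records
(the phase-coherent estimator exploits this stability), J-coupling of the
fat multiplets, T1 weighting, and iron overload (siderosis). Passing
recovery tests on this phantom therefore demonstrates correctness of the
estimation machinery under the stated signal model, not robustness to
every artefact of in vivo data. One further caveat: the weak-signal
fallback T2 (60 ms) coincides with the generator's fat T2, so the phantom
cannot reveal errors in that literature value.

# The statistical layer

* `spearman_rho()` -- rank correlation (average ranks for ties) between
  each method's PDFF and the histology percentage.
* `roc_empirical()` -- the empirical ROC over all observed thresholds; its
  trapezoidal area equals the Mann-Whitney concordance with half-weight
  ties.
* `roc_smoothed()` -- scores are rank-transformed (the "robust" step),
  each class is smoothed with a Gaussian kernel (Silverman's rule per
  class), and thresholds are mapped back to marker units so Youden cutoffs
  are reportable PDFF values.
* `youden_threshold()` -- maximises sensitivity + specificity - 1; ties go
  to the lower threshold.
* `compare_roc_paired()` -- DeLong's correlated-AUC test (two-sided). The
  degenerate case of identical markers returns p = 1.
* `obuchowski_auc()` -- the ordinal-gold-standard AUC: pairwise
  between-grade AUCs weighted by their subject-pair counts. The standard
  error is the leave-one-subject-out jackknife, computed efficiently by
  incremental update of the pairwise AUCs.
* `group_summaries()` / `group_test()` -- per-grade medians with type-7
  (linear interpolation) quantiles, and two-sided Wilcoxon rank-sum tests
  for pairwise grade comparisons. No multiplicity correction is applied;
  raw p-values are reported.
* `fit_steatosis_models()` -- OLS of the method's PDFF (%) on the
  histology share (0--1), optionally adjusted for steatohepatitis and
  fibrosis (F0 reference; F3 and F4 merged). The orientation follows the
  magnitudes involved: a slope near 30 maps full steatosis to PDFF near
  30%. The accompanying accuracy figure is the Obuchowski AUC of the
  *measured* PDFF against the four-level grade -- fitted values would be
  monotone in the histology predictor and trivially concordant.

`evaluate_cohort()` assembles all of this into one report; `run_study()`
drives simulation, quantification and evaluation through CSV/JSON
artifacts on disk.

# Numerical choices and conventions

* Grade boundaries: the published bands overlap at their endpoints; here
  5 is mild and 33 and 66 are moderate, making the bands half-open and
  exhaustive.
* Optimiser: bounded Levenberg-Marquardt (`minpack.lm`), `ftol`/`ptol`
  near machine precision so noiseless recovery is exact to 1e-6 PDFF;
  the gradient-orthogonality stopping code counts as convergence.
* The echo-model multi-start grid spans PDFF {0.03, 0.15, 0.3, 0.5, 0.7,
  0.92} by $T_2^*$ {10, 25, 50} ms; scanning stops early on an exact fit.
* Peak-fit start values: prior frequencies, 50 Hz damping.
* All generators are pure functions of (inputs, seed); cohort files
  re-run byte-identically under the same seed.
* Degenerate inputs fail loudly and early: all-zero echo series, absent
  water, fewer than three usable T2 points, overlapping prior windows,
  malformed cohort rows (reported with their row number). Per-subject
  failures inside the batch pipeline are flagged, never fatal.

# Problem sizes in the test suite

The suite verifies exact noiseless recovery on a PDFF-by-$T_2^*$ grid for
both imaging protocols and a five-point PDFF grid for spectroscopy;
Monte-Carlo properties use 200--400 replicates (noise-floor bias at SNR
10, imaging bias at SNR 50), 100 seeded replicas of the default 73-subject
cohort for the pipeline-level envelope (Spearman rho above 0.7,
any-steatosis AUC above 0.9), and exhaustive brute-force oracles for the
AUC, Spearman and Obuchowski statistics on instances of up to 30 subjects.
These sizes keep the full suite under a few minutes on one core while
leaving the Monte-Carlo margins far from their thresholds.

# Known limitations

* ROI-level only: no voxelwise PDFF maps, by design.
* The magnitude model cannot exceed PDFF 50% reliably under noise; the
  tie-break prefers the water-dominant basin, appropriate for liver.
* Spectroscopy assumes a phase-stable receiver across records and no
  baseline distortion; eddy-current correction and baseline splines are
  out of scope.
* The Obuchowski jackknife SE assumes independent subjects.
* Thresholds from smoothed ROC curves inherit kernel-bandwidth
  sensitivity in small grade groups; confidence intervals for thresholds
  are not provided.
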
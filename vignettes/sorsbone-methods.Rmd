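---
title: "Supervised reconstruction of bone Raman spectra from transcutaneous SORS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised reconstruction of bone Raman spectra from transcutaneous SORS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorsbone)
```

## The problem

Osteoporosis is diagnosed from DXA T-scores — the number of standard
deviations by which bone mineral density differs from a healthy
young-adult reference — with WHO cutoffs at −1.0 and −2.5. DXA measures
density only; Raman spectroscopy of bone additionally reads out
biochemistry: the phosphate ν1 band (~960 cm⁻¹) against carbonate
(~1070), Amide III (~1250), CH₂ (~1450) and Amide I (~1660 cm⁻¹) yields
mineral-quality and mineral-to-matrix ratios that track mechanical
competence. Measuring bone through intact skin is the hard part: even
with spatially offset Raman spectroscopy (SORS), where the collection
zone is displaced laterally from the excitation spot so that larger
offsets sample deeper tissue, a transcutaneous finger spectrum is
dominated by skin and adipose signal plus a fluorescence baseline.

`sorsbone` treats the unmixing as supervised regression. Given pairs of
6-mm-offset transcutaneous spectra and site-matched 3-mm exposed-bone
spectra, a multi-response PLS (PLS2) model learns a direct linear map
from the mixed measurement to the bone spectrum. No soft-tissue
reference library is needed; the exposed-bone spectrum is the ground
truth.

## The model

Each measurement is a row vector on a shared wavenumber axis
(P = Q = 499 points by default). Stacking training subjects gives
$X \in \mathbb{R}^{N \times P}$ (transcutaneous) and
$Y \in \mathbb{R}^{N \times Q}$ (exposed bone). PLS2 decomposes the
mean-centered matrices as $X = T P^\top + E$, $Y = U Q^\top + F$, with
score directions chosen to maximize X–Y score covariance under
orthogonality constraints, and yields the linear predictor

$$\hat Y = \mathbf{1} b_0^\top + X B, \qquad
  \tilde B = \begin{bmatrix} b_0^\top \\ B \end{bmatrix},$$

so test predictions are $[\,\mathbf 1 \mid X_\text{test}\,]\tilde B$.
The reference algorithm is SIMPLS (de Jong 1993): components come from
the dominant singular pair of the cross-product $S = X_c^\top Y_c$,
deflated against an orthonormal basis of X-loadings so X-scores stay
mutually orthogonal. A NIPALS variant is available via
`fit_pls2(..., algorithm = "nipals")` and agrees with SIMPLS exactly in
the single-response case.

Numerical choices worth knowing:

* **Centering only.** X and Y are mean-centered, never
  variance-scaled: the model carries an explicit intercept and spectral
  channels share physical units, so autoscaling would only amplify
  empty-channel noise. Band normalization (e.g. to the phosphate peak)
  is a *display* convention and is never applied to model inputs by
  default.
* **Exact dominant singular pair via thin QR.** The top singular pair
  of $S$ is computed from thin QR factorizations of $X_d^\top$ and
  $Y_c^\top$ plus an SVD of the small core, costing
  $O(N^2 (P + Q))$ per component instead of $O(PQ\min(P,Q))$. This is
  an exact route, not an approximation; it is what keeps 499-channel
  leave-one-subject-out loops at interactive speed.
* **Degeneracy guards.** Zero-variance predictor columns are dropped
  with a warning and restored as zero coefficient rows (an all-constant
  X is an error); deflation directions with negligible norm terminate
  extraction early with a warning, capping the component count. No
  path returns silent `NaN`.
* **Determinism.** Singular-vector signs are canonicalized
  (largest-magnitude weight positive), so refitting identical data is
  bit-identical.

## Cross-validation

All evaluation is leave-one-subject-out (LOSO): every spectrum of one
subject forms the test fold while all other subjects' spectra train the
model. Repeated sites within a subject are strongly correlated, so
row-wise CV would leak; the leakage test in the suite verifies that an
intentionally leaked variant outperforms the honest pipeline. The
number of latent components is fixed at A = 10 across reconstruction
folds, the value a grouped K-fold search (`select_components`, folds
defined on subject identity, K = 5 by default, smallest-rank
tie-break) selects as stable on cohorts of this size.

For T-score regression (`fit_tscore_loso`) the response is scalar and
the representative spectrum is the D2P1 mid-shaft site (MM00). Ranks
1–15 are searched; the default `"pooled"` mode picks the single rank
minimizing the pooled RMSE of cross-validation and reports Pearson r
and RMSE_CV at that rank. A `"per_fold"` mode that re-selects the rank
inside each outer fold by an inner leave-one-out is also implemented;
pooled is the default because reporting one optimum is only
well-defined for a single rank, while per-fold re-selection is the more
conservative (fully nested) protocol — the two are worth comparing on
any new dataset.

Decision scores for ROC analysis are the negated LOSO-predicted
T-scores: a continuous score is required to trace a curve, and the
predicted T-score is the quantity the WHO thresholds act on. AUC is
computed as the normalized Mann–Whitney U with half credit for ties.

## Band metrics

Band quantification uses a local linear baseline through the window's
endpoint samples; `"area"` (trapezoidal, default) is more noise-robust
than `"height"`, and both are implemented because the convention behind
published ratios is often unstated. Default windows (cm⁻¹): PO₄³⁻
930–980, CO₃²⁻ 1050–1100, Amide III 1215–1300, CH₂ 1400–1500, Amide I
1595–1720 — standard cortical-bone assignments, fully configurable.
CH₂ FWHM is measured after the same local baseline removal, with
half-maximum crossings located by linear interpolation between grid
points.

Group summaries aggregate subject-first (mean per subject, then per
class) and report mean ± SEM with SEM = SD/√N; a single-subject class
reports SD = 0 by convention. Between-class tests default to an exact
two-sided Mann–Whitney computed by enumeration of group assignments
with mid-ranks on ties — assumption-free at the cohort sizes involved
(identical multisets give p = 1 exactly); a Welch t-test is available
by flag, and no multiple-testing correction is applied because the four
ratios are reported per-metric.

## The synthetic cohort generator

No cadaver data ships with the package, so `generate_cohort` produces
paired cohorts with known ground truth. What it emulates:

* **Class structure.** T-scores are drawn per class from Normal
  0.05 ± 0.45, Osteopenia −1.63 ± 0.38, Osteoporosis −4.19 ± 0.90
  (SD units), truncated by rejection to the class's WHO interval so
  labels are always self-consistent. The default cohort is 6/4/11
  subjects — a realistic small cadaveric study.
* **Bone biochemistry.** Bone spectra are Gaussian band sums (PO₄³⁻
  960/8, CO₃²⁻ 1070/10, Amide III 1250/25, CH₂ 1450/15, Amide I
  1665/30 cm⁻¹ center/σ). Mineral amplitudes scale as
  $e^{s\,T}$ with s = 0.10 (PO₄³⁻) and 0.05 (CO₃²⁻), so every
  mineral-to-matrix ratio *and* the PO₄³⁻/CO₃²⁻ ratio fall
  monotonically from Normal to Osteoporosis; the CH₂ width scales as
  $e^{-0.02\,T}$ so matrix heterogeneity rises with disease. The
  exponential link keeps amplitudes positive for any real T-score; the
  slopes are generator conventions chosen to give clear but not
  trivial class separation at cohort scale, not estimates of biology.
* **Transcutaneous mixing.** A measurement at offset d is
  $f(d)\,\text{bone} + (1{-}f(d))\,\text{soft} + \text{baseline} +
  \text{noise}$ with f = 0.05/0.20/0.40 at 0/3/6 mm. Only the ordering
  (deeper sampling at larger offset) is physics; the values make the
  6-mm channel informative but soft-tissue-dominated. Soft tissue is
  its own band sum (lipid CH₂, Amide I, lipid twist, broad collagen);
  the fluorescence baseline is a decaying polynomial several times the
  peak amplitudes with a lognormal per-measurement scale; noise is
  additive Gaussian (σ = 0.02 against unit-order peaks); subjects and
  sites carry lognormal amplitude jitter (σ_log = 0.05).
* **Reproducibility.** One global seed fans out to per-subject
  substreams, so extending a cohort never perturbs earlier subjects and
  identical seeds give bit-identical cohorts.

What it does **not** emulate: photon-migration physics (no Monte Carlo
radiative transfer), detector/fiber response, cosmic rays, melanin and
pigmentation effects, in vivo physiological variation, or any
instrument-specific artifact. Consequently, passing tests demonstrate
that the algorithms are correct and that the pipeline recovers known
ground truth under a plausible mixing model — they say nothing about
performance on real tissue, where the soft-tissue background is far
more heterogeneous and reconstruction correlations should be expected
to be lower.

## Degenerate inputs and conventions

* Position codes are case-insensitive; zero is written `MM00`; `MPxx`
  is proximal (negative mm), `MDxx` distal (positive).
* Pairing sorts rows canonically by (subject, site), reports unmatched
  spectra, and errors on an empty intersection.
* Baseline removal (`subtract_baseline`) is the iteratively clipped
  polynomial scheme, degree 5 and 20 iterations by default — a
  simplified generic stand-in for instrument-specific preprocessing
  chains, applied before modelling when raw spectra carry fluorescence.
* An undefined 0/0 classification ratio is reported as `NA` with a
  warning, never silently as 0.
* `classify_who` places each boundary on the sicker side: −1.0 is
  Osteopenia, −2.5 is Osteoporosis.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
default 21-subject cohort (63 paired rows, 499 channels, A = 10), the
scale the method is designed for; oracle equivalence suites use ~100
random instances up to 12×8. At these sizes the whole suite completes
in well under a minute of compute on one core — small enough to run on
every change.

## Known limitations

* The wavenumber range of the default axis (800–1800 cm⁻¹, 499 points)
  is a documented assumption; files carrying other axes are accepted.
* Generator mixing fractions and amplitude slopes are conventions.
  Conclusions about *method* behaviour transfer; conclusions about
  effect sizes do not.
* PLS2 is linear; strongly nonlinear tissue effects (e.g.
  absorption-driven distortions) are outside the model class.
* The exact Mann–Whitney enumeration is exponential in group size; the
  implementation falls back to the normal approximation beyond ~2×10⁵
  assignments.
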
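---
title: "Quantifying subtle blood-brain-barrier leakage: models, noise correction and design choices"
author: "bbbpatlak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subtle blood-brain-barrier leakage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbpatlak)
```

## The measurement problem

In cerebral small vessel disease (cSVD) the blood-brain barrier (BBB) leaks
gadolinium contrast at rates of the order of 10^-3 min^-1 — so slow that the
per-voxel enhancement over a dynamic scan is comparable to the measurement
noise. The pipeline in this package quantifies that leakage from
dual-time-resolution dynamic contrast-enhanced (DCE) MRI in two tissue
classes: normal-appearing white matter (NAWM) and white matter
hyperintensities (WMH). Its subject-level outputs are the mean leakage rate
(mean K~i~) and the fractional leakage volume (v~L~) per tissue, which then
enter a group comparison and a regression against plasma VEGFA.

Because no imaging data ship with the package, a seeded synthetic-cohort
generator produces complete subjects (4D dynamic series, T1 map, tissue
masks, ground truth, covariates). Every stage of the pipeline is tested
against that generator's ground truth.

## From signal to concentration

Dynamic frames are acquired with a spoiled gradient-echo (SPGR) readout,

$$S = M_0 \sin\alpha \,\frac{1 - E_1}{1 - \cos\alpha\, E_1},
\qquad E_1 = e^{-TR \cdot R_1},$$

with flip angle $\alpha$, repetition time $TR$ and longitudinal rate
$R_1 = 1/T_1$. Per voxel, the pre-contrast baseline $S_0$ is the mean of the
frames before bolus arrival. Given the baseline $R_1 = 1/T_1$ from the T1
map, the measured ratio $S(t)/S_0$ is inverted for $E_1(t)$ in closed form,
and concentration follows from the linear relaxivity model

$$C(t) = \frac{R_1(t) - R_1(0)}{r_1}.$$

The full inversion is used rather than the first-order
$\Delta S / S_0$ approximation: it is exact on synthetic data and the
linear variant remains available (`method = "linear"`) for sensitivity
checks. Signal ratios outside the attainable SPGR range (possible under
noise) flag the voxel as invalid; the flag — never a clamped value — is
propagated to all downstream masks, so invalid voxels simply drop out of
the analysis with a logged count.

The relaxivity $r_1$ is a protocol parameter with default
5.0 s^-1 mM^-1 (gadobutrol at 3 T); it is not identifiable from the data
and must be supplied.

The fast sequence samples the bolus (default 3.2 s spacing), the slow
sequence the baseline and the leakage tail (30 s spacing). After
conversion both are merged onto one time axis; where a slow frame falls
within half a fast interval of a fast frame, the fast frame wins, so
timestamps stay strictly increasing.

## Patlak estimation of K~i~ and v~p~

For slow, effectively unidirectional transfer, tissue concentration follows
the Patlak model

$$C_t(t) = K_i \int_0^t C_p(\tau)\, d\tau + v_p\, C_p(t),$$

with $C_p$ the plasma input sampled from the superior-sagittal-sinus mask,
$K_i$ the leakage rate and $v_p$ the intravascular fraction. Both
regressors are computed on the merged VIF grid (trapezoidal running
integral, linear interpolation to frame times) and the model is fitted per
voxel by ordinary least squares without an intercept, over all frames from
bolus arrival to the end of the slow sequence (configurable).

Two deliberate choices:

* **Untransformed coordinates.** The classical Patlak *plot*
  ($C_t/C_p$ vs $\int C_p / C_p$) divides by near-zero $C_p$ at late
  times; the untransformed linear model has the identical noiseless
  solution without that instability.
* **Negative estimates are kept.** Under the null ($K_i = 0$) the OLS
  estimate is symmetrically distributed around zero; that symmetry is the
  premise of the histogram correction below, so clipping at zero would
  bias everything that follows.

## Histogram noise correction

Within a tissue mask, the voxel-wise K~i~ estimates form a mixture of a
zero-centred noise distribution and a positive leakage component. The
correction builds a histogram with uniform half-open bins $[lo, hi)$ whose
edges sit at integer multiples of the bin width (so the negative side
mirrors exactly onto the positive side), then subtracts the mirrored
negative-side counts from the positive side, flooring each bin at zero —
a count cannot be negative, and whether the original analyses summed
signed counts instead is not determinable, so the floor is the documented
convention here. From the corrected histogram:

* mean K~i~ = count-weighted average of positive bin midpoints
  (0 when nothing survives the correction);
* v~L~ = corrected count total / number of tissue voxels — the
  "remaining area" under the corrected histogram.

The default bin width is 0.1×10^-3 min^-1, which resolves the estimation
noise of the default acquisition (noise SD ≈ 0.3-0.4×10^-3 min^-1); a
Freedman-Diaconis width computed on the mirrored negative-side values is
available by passing `bin_width = NULL`. The calibration properties are
meaningful only when the width does not exceed the noise scale: with noise
much finer than a bin the corrected mean is quantized, with noise much
coarser the mirrored subtraction under-resolves the null bulk.

Known behaviour, quantified in the tests: the correction *underestimates*
v~L~ in subjects whose true K~i~ is within ~1 SD of the estimation noise
(the leakage mass that lands below zero is cancelled) — at the default
conditions the group-mean bias is about −0.02 for patients and near zero
for controls. The corrected mean K~i~ is conversely biased slightly upward
(the surviving counts concentrate in the upper bins). These are properties
of mirror-subtraction itself, not of this implementation.

## The statistical layer

* **Outlier rule.** Plasma VEGFA values above
  $Q_3 + 1.5\,(Q_3 - Q_1)$ are excluded before the VEGFA regressions;
  quartiles use the linear-interpolation (type 7) convention. The rule is
  upper-tail only and applied once.
* **Group comparisons.** Unpaired pooled-variance Student t-test or
  Mann-Whitney U; the choice is an explicit argument, never auto-detected
  from a normality test.
* **Standardized-beta regression.** Every continuous variable is z-scored
  (n−1 denominator) before an OLS fit; the binary predictors are coded
  control = 0 / patient = 1 and male = 0 / female = 1 and left unscaled, so
  a group beta reads as an adjusted group difference in SD units of the
  outcome. In the univariable continuous case the beta equals the Pearson
  correlation. The 95% CI is $\beta \pm t_{0.975,\,df}\,SE$ with the
  classical OLS standard error (a robust covariance was considered and not
  adopted: nothing in the outputs requires heteroscedasticity protection
  at these sample sizes).
* **Report tables.** `run_table1()` relates each MRI measure to group
  (univariable and age/sex-adjusted); `run_table2()` relates each measure
  to VEGFA within one group after outlier removal.

## What the synthetic cohort emulates — and what it does not

The generator reproduces the *statistical structure* the analyses assume,
on a deliberately unrealistic geometry (box-shaped masks on a
24×24×12 grid; the pipeline is coordinate-agnostic, so anatomical realism
buys no additional coverage):

* Disjoint NAWM, WMH and sinus (VIF) masks; the WMH box is sized per
  subject to a target relative volume (≈3.5×10^-3 controls,
  ≈16×10^-3 patients, with 25% between-subject spread). The relative
  volume is reported as WMH voxels over all grid voxels.
* A gamma-variate bolus plus recirculation/washout plasma curve,
  normalized so its maximum equals the configured 5 mM peak; VIF voxels
  carry the plasma curve itself ($v_p = 1$).
* Voxel-wise true K~i~: zero outside a randomly placed leaking subset,
  zero-truncated Gaussian (SD 0.25×10^-3 min^-1) inside it. Group means of
  the subject-level K~i~ and of the leaking fraction are set to the
  clinical design targets (e.g. v~L~ in NAWM 0.276 controls vs 0.370
  patients), with between-subject SDs of 0.30×10^-3 min^-1 and 0.05
  respectively. The leak-fraction SD is kept measurement-scale (smaller
  than the clinical between-subject spread) so the 20+20 default cohort
  retains power for the group contrast; at the clinical spread the
  scaled-down cohort would be underpowered by design.
* Patients' VEGFA (mean 25.3, SD 21 pg/ml; controls 14.5, SD 10.6) shifts
  their subject-level NAWM K~i~ by 4.5×10^-6 (min^-1)/(pg/ml), giving a
  VEGFA-K~i~ correlation of ≈0.3 in patients.
* Gaussian noise with SD 2% of the voxel's baseline signal is added to the
  *signal*, not the concentration, so the nonlinearity of the SPGR
  inversion is exercised; this yields a Patlak estimation noise of
  ≈0.3-0.4×10^-3 min^-1, making the noise correction consequential
  without drowning the signal (SNR ≈ 50, typical of dynamic SPGR at 3 T).
* Per-subject RNG streams are derived from `(rng_seed, subject_index)`,
  so any subject can be regenerated independently and a fixed
  configuration yields a bit-identical cohort.

Not emulated: scanner artifacts (motion, B1 inhomogeneity), segmentation
error in the masks, partial-volume effects, hematocrit variation, and any
spatial correlation of leakage. A green test suite therefore shows the
*estimators* are correct and calibrated under the stated noise model — not
that the pipeline is robust to everything real data can do.

## Numerical conventions and degenerate inputs

* Frame layout: slow pre-contrast frames, then the fast sequence (first
  4 frames pre-contrast, bolus at 72.8 s by default), then the slow tail;
  ~13 min total. Times are seconds at acquisition, minutes inside the
  kinetic model; K~i~ is min^-1 internally and reported as 10^-3 min^-1 in
  cohort tables.
* Degenerate fits: fewer than 3 usable frames, or a rank-deficient design
  (e.g. $C_p \equiv 0$), mark the voxel invalid rather than returning
  numbers. An all-zero time-course fits to (0, 0) with undefined $R^2$.
* An empty WMH mask leaves the WMH columns `NA` and flagged; the NAWM
  columns are still produced.
* Histogram edge convention: half-open $[lo, hi)$; a value exactly at 0
  lands in the first positive bin. Exact cancellation of ±a pairs holds
  for values interior to mirrored bins, not for values sitting exactly on
  edges — one reason the edges are pinned to integer multiples of the
  width.
* Problem sizes used by the checks: 24×24×12 voxel grids, 20+20 subjects
  for the imaging cohort, 10^4 voxels for histogram calibration, 500
  tabular cohorts for the type-I sweep — sizes at which every documented
  property is comfortably resolved on a single CPU.

## A minimal run

```{r example, eval = FALSE}
protocol <- acquisition_protocol()
config <- simulation_config(n_patients = 4, n_controls = 4)
cohort <- simulate_cohort(config, protocol)     # in memory
fitted <- fit_cohort(cohort, protocol)
run_table1(fitted)$associations
```

The `analysis/` scripts run the same chain at the default cohort size and
leave their tables under `results/`.

## Limitations

* v~p~ and K~i~ are estimated jointly from a single-compartment linear
  model; for fast-leaking lesions (not the cSVD regime) Patlak's
  unidirectional assumption fails and K~i~ loses its interpretation.
* The mirror-subtract correction assumes strictly symmetric,
  zero-centred estimation noise; any baseline drift that shifts the null
  distribution translates directly into v~L~ bias.
* Group-level v~L~ recovery degrades for subjects whose true K~i~
  approaches the estimation noise (see above); interpret low-leakage
  subjects' v~L~ as a lower bound.
* The regression layer implements the classical OLS machinery only — no
  mixed effects, no multiple-testing correction — matching the analysis
  design it reproduces.
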
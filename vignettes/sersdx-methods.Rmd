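---
title: "Methods: OSC-PLS-DA classification of SERS blood spectra"
author: "sersdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OSC-PLS-DA classification of SERS blood spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersdx)
```

`sersdx` is a pipeline for two-class discrimination of SERS spectra of
blood fractions: fibromyalgia (FM) versus pooled other rheumatic disorders
(non-FM), with healthy controls (NC) carried along for descriptive
difference spectra. This vignette is the package's own account of the
models and of the design decisions that were genuinely open.

## Data model

A `spectrum` is an intensity trace on a strictly increasing wavenumber axis
(cm^-1) with a sample id, replicate index and class label; a `spectra_set`
is a cohort on one shared grid (matrix rows = spectra). The working grid is
600-2300 cm^-1 at 2 cm^-1 — the acquisition range and resolution of the
instrumentation this workflow targets. Wide-table CSV is the interchange
format (first column the axis, one column per spectrum, metadata in a
sidecar CSV or encoded as `id_replicate_label` column names); JCAMP-DX is
read-only and restricted to AFFN-encoded `(X++(Y..Y))` and `(XY..XY)`
blocks with `XFACTOR`/`YFACTOR` scaling — compressed (SQZ/DIF) encodings
are not parsed.

## Preprocessing

The fixed order is: rubberband baseline (per replicate) -> replicate
averaging -> normalization -> region selection -> Savitzky-Golay second
derivative. Mean-centering is deliberately *not* part of
`preprocess_set()`: it belongs to the model, which must center test
spectra with training means.

- **Rubberband baseline.** The background estimate is the piecewise-linear
  interpolation of the lower convex hull of the (wavenumber, intensity)
  points, computed by a monotone-chain scan. The corrected spectrum is
  exactly zero at every hull vertex and non-negative everywhere. The
  assumption is a smooth, convex-ish autofluorescence background; sharp
  negative artifacts would corrupt the hull. Whether each replicate is
  corrected before averaging, or the average afterwards, is not dictated
  by the workflow we follow; the default corrects each replicate first
  (instrument-side correction acts per acquisition), and
  `preprocess_config(baseline_before_averaging = FALSE)` flips the order.
- **Normalization.** The upstream software's "normalize" step is not
  further specified in the sources this workflow emulates; the default is
  the unit Euclidean norm (common chemometrics practice, and it makes
  predictions invariant to overall intensity rescaling); `area`, `max`
  and `none` are available.
- **Region.** Default 750-1750 cm^-1 (the model-construction choice); a
  750-1720 preset is shipped because both bounds are quoted for this
  workflow; the difference is 15 grid points at the upper edge.
- **SG second derivative.** 25-point window; the polynomial order is not
  stated in the sources, so the default is cubic (order 2 gives the same
  second derivative on interior points for symmetric windows; 2-4
  allowed). Filter weights come from `signal::sgolay`; values are scaled
  by the grid spacing^-2 so units are per (cm^-1)^2. Edge handling:
  the 12 points per side without a full window are dropped, not padded —
  padding invents data, and the fingerprint region is interior to the
  recorded range, so nothing of interest is lost. After region selection
  this leaves 477 of 501 points.

## The discriminant model

Classes are coded FM = 1, non-FM = 2; the decision threshold is the
midpoint 1.5 and ties go to class 2 (an arbitrary, probability-zero
choice). The "OPLS-DA" of this workflow is implemented as sequential
orthogonal signal correction followed by PLS-DA — the two-step formulation
— not the integrated single-step orthogonal PLS decomposition.

**OSC.** Each component seeks the direction of maximal X-variance whose
score carries no class information. We solve this in closed form: with
centered y and v = X'y, the weight w is the leading right singular vector
of X(I - vv'/v'v), re-projected and normalized, so t = Xw satisfies
corr(t, y) = 0 to machine precision. Deflation is X <- X - tp' with
p = X't/(t't). The common iterated formulations converge toward exactly
this fixed point, but iterating leaves a tolerance-sized y-correlation in
t and an inconsistency between training deflation and out-of-sample
deflation; the closed form makes both contracts exact, which the test
suite asserts at 1e-10. New data are deflated with training w and p only.

**PLS.** NIPALS PLS1 on the OSC-corrected, centered matrix; with a
univariate response the inner loop converges in one pass, but the
iteration is retained with tolerance 1e-12 and a 500-iteration cap.
Per-LV weights, loadings, scores, explained X- and Y-variance fractions
are stored; the regression vector is b = W(P'W)^-1 q. Rank exhaustion
(score norms vanishing) raises an error rather than returning degenerate
components. Defaults n_lv = 7 and n_osc = 1 follow the study design this
package replicates; `select_n_lv()` profiles SECV over nested model sizes
for those who want data-driven selection, but it is off by default.

**Reading the regression vector.** `regression_vector_report()` ranks the
local extrema of |b| and annotates each with the nearest reference-table
band within 8 cm^-1. Two lessons from the synthetic experiments are built
into its design and documentation. First, on second-derivative spectra one
band produces a cluster of extrema (centre plus dispersive flanks spanning
roughly three half-widths), so extrema within `min_sep = 30` cm^-1 of a
stronger one are merged into one feature. Second, coefficient magnitude is
only class-informative when the model is parsimonious: at 7 latent
variables the deep components model within-class variance, and |b| mixes
signal with variance directions (we verified the 7-LV vector itself against
an independent PLS implementation — they agree to machine precision; the
scrambling is a property of the statistic, not of the code). Band
attribution should therefore be read from the OSC-filtered single
predictive component (`n_lv = 1`), whose regression vector is the
class-covariance direction — the usual reading for orthogonally filtered
discriminant models. The planted-effect recovery tests do exactly this.

## Validation

- **LOOCV** refits the entire chain — centering, OSC, PLS — without the
  held-out sample, for every sample. SECV uses the 1/n denominator (the
  common standard-error-of-prediction convention; alternatives only
  rescale). R^2 is reported both as the squared Pearson correlation
  between predictions and codes (the headline convention of the workflow)
  and as 1 - SSres/SStot.
- **External validation** requires disjoint sample IDs, reports SEP,
  R^2pre, the confusion counts with FM positive, and the three rates as
  percentages.
- **ROC/AUC** sweeps all score thresholds with higher score = more
  FM-like; the trapezoid AUC equals Mann-Whitney pair counting with ties
  at one half (asserted to 1e-12 against a pair-counting oracle, and
  cross-checked against pROC). If a model were anti-oriented the curve is
  flipped and the flip recorded.
- **Outlier screening.** Leverage is h_i = 1/n + t_i'(T'T)^-1 t_i over the
  LV scores; the studentized residual defaults to the *externally
  studentized* (deletion) form, i.e. the residual of each sample when
  predicted by the chain refit without it, scaled by the cross-validation
  error. The in-model alternative (`residuals = "calibration"`) is also
  available but a 7-LV calibration model bends to fit gross artifacts:
  such samples end up with near-zero calibration residuals, which the test
  suite demonstrates with a planted 20-sigma band artifact. A sample is
  flagged when both h_i > 3(n_lv + 1)/n and |studentized residual| > 3;
  removal (`remove_flagged()`) is a separate action, largest offenders
  first, capped at 3% of samples, run once before the final calibration
  fit and never inside cross-validation folds. A caveat the synthetic
  experiments exposed: with vector-normalized spectra every sample lies
  near the unit sphere, so leverage saturates well below the 3x-mean cut
  for single-sample artifacts of any magnitude — gross artifacts manifest
  as residual outliers, not leverage points, and the conjunctive flag is
  correspondingly conservative.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes: Lorentzian bands (Gaussian available) at the union of the
major-band and regression-vector reference positions, 10 cm^-1 half-width;
a two-level amplitude hierarchy (strong bands 1014, 1222, 1354, 1448, 1586
at 1.0, others at 0.5 — free parameters reflecting a qualitative intensity
hierarchy, not measured values); an exponential fluorescence baseline
a·exp(-(nu - 600)/800) with per-sample lognormal a (meanlog log 2, sdlog
0.3); per-sample, per-band lognormal amplitude variability (sdlog 0.1);
four replicates per sample with 5% multiplicative jitter and additive
white noise (sd 0.02 in band-amplitude units, a mid-range signal-to-noise
for 20-second acquisitions); cohort sizes 83 FM / 54 non-FM / 9 NC. Class
effects are multiplicative on amplitude (so vector normalization does not
trivially erase them), applied as +-e/2 to FM/non-FM, nonzero by default
only at the eight discriminant bands, and scaled globally by
`effect_scale` (default 0.5; 0 yields an exchangeable null cohort). NC
samples share the non-FM amplitude template. Per-sample random streams are
derived from the master seed by counter, so cohorts are bit-reproducible.

What the generator does *not* emulate: SERS enhancement physics (hot
spots, nanoparticle aggregation), solvent effects, wavenumber calibration
drift, correlated (pink) noise, cosmic-ray spikes, or any quantitative
per-band intensity of real serum. Tests passing on these cohorts therefore
demonstrate the *statistical machinery* — no leakage, correct oracles,
recovery of planted structure — not clinical performance. The
photodegradation artifact (a broad 1535 cm^-1 amorphous-carbon band) can
be injected with `inject_photodegradation()` and is detected by
`qc_flag_burned()`, which compares the local prominence of the 1535 +- 10
window against 0.5x the median absolute fingerprint intensity.

## Problem sizes and numerical choices

The test suite runs the full study replica (548 replicate spectra, 109/28
split) across 20 seeds for the separation and null-leakage checks, 10
seeds for planted-band recovery and the effect-size monotonicity sweep,
and uses small matrices (n <= 30) for the exact oracle equivalences —
sizes chosen so the whole suite completes in minutes on one core while
keeping the stochastic checks well away from their thresholds. Numerical
tie-breaks and tolerances: hull points on a straight segment are treated
as interior (strict turns only); OSC/PLS component signs are fixed by the
largest-magnitude weight entry; NIPALS tolerance 1e-12; centering
contracts asserted at 1e-12, decomposition contracts at 1e-10.

## Known limitations

- Two classes only; the multi-disease labels are pooled into non-FM.
- JCAMP-DX support is the uncompressed subset.
- The 3% removal cap rounds down, so cohorts under 34 samples never
  remove a flagged sample (flags are still reported).
- SECV at desk scale is an order of magnitude larger than values reported
  for well-separated clinical cohorts; the synthetic generator makes no
  attempt to reproduce instrument-grade precision, only ordering and
  structure.
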
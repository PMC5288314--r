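---
title: "Models and methods behind nmrfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmrfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nmrfield)
```

## What the package models

`nmrfield` implements a complete chemometric workflow for detecting
tissue-class differences — including *field effects*, metabolic changes in
histologically normal tissue adjacent to a neoplasm — from 1D ^1^H-NMR
spectra of tissue extracts. The workflow has four stages:

1. **Spectral preprocessing** from phased, frequency-domain spectra to a
   model-ready matrix;
2. **Latent-variable modelling**: PCA with Q-residual outlier screening,
   orthogonal signal correction (OSC) followed by NIPALS PLS-DA, and
   multilevel (ML-)PLS-DA for paired designs;
3. **Validation**: Venetian-blinds / leave-one-out cross-validation,
   AUROC and cross-validated error rate (CVER), permutation testing, and
   double cross-validation for the multilevel path;
4. **Univariate statistics** on tracked metabolite peaks through a
   Shapiro–Wilk-gated four-way test selection.

Because the workflow is exercised without clinical data, the package ships a
first-class synthetic-cohort generator that emulates the statistical
structure such a study presents: nine tissue classes at realistic sample
sizes, paired samples within patients, pH-driven chemical-shift jitter,
baseline drift, and additive noise.

## The synthetic cohort generator

A spectrum is a sum of metabolite contributions on a ppm grid:

$$ y(x) \;=\; \sum_m e^{c_m} \sum_{k} a_{mk}\,
   \frac{h_{mk}^2}{(x - \mu_{mk} - \delta_m)^2 + h_{mk}^2}
   \;+\; b(x) \;+\; \varepsilon(x), $$

with $c_m$ the natural-log concentration, $a_{mk}$ the multiplet's relative
intensity (proportional to proton count), $h_{mk}$ the half width
(`linewidth_hz / spectrometer_mhz / 2`), $\delta_m \sim N(0,
\sigma_\text{jitter}^2)$ a per-metabolite position jitter emulating pH
differences, $b$ a smooth three-term cosine baseline with random phases, and
$\varepsilon$ i.i.d. Gaussian noise. Lineshapes are pure Lorentzians;
J-coupling fine structure is encoded only through explicit peak lists. The
packaged library (`default_metabolite_library()`) holds the ~25 metabolites
relevant to esophageal tissue work at literature chemical shifts, plus the
TSP reference singlet at 0 ppm; positions and intensities are editable YAML,
not measurements.

Per-sample log-concentrations follow a hierarchical model

$$ c_{ism} = \beta_m + \log(2)\,\Delta_{\text{class}(i),m}
           + u_{sm} + e_{ism}, $$

with $\beta_m$ the library baseline, $\Delta$ the class log2 offset,
$u_{sm} \sim N(0, \sigma_\text{subject}^2)$ a subject random effect shared
by all samples of a patient (what multilevel modelling exploits), and
$e_{ism} \sim N(0, \sigma_\text{conc}^2)$ sample noise.

**Effect tables.** Class effects are stored as per-class log2 offsets
relative to class 1 (normal squamous tissue from controls); the pairwise
fold change between any two classes is the difference of offsets. This
parameterization makes all pairwise directions mutually consistent by
construction. The default table encodes every reported direction — the
twelve-metabolite cancer signature (myoinositol, inosine, hypoxanthine,
3-hydroxybutyrate, glycerophosphocholine, phosphocholine, formate up;
glutamine, alanine, creatine, ADP, fumarate down), the field-effect
signature in histologically normal tissue of cancer patients, the
squamous-to-columnar shift, the Barrett's-with-cancer pattern, and the
chemotherapy response — with magnitudes defaulting to |log2FC| = 1 for
strongly and 0.5 for weakly altered metabolites. Magnitudes are free
parameters: the source study reports directions and significance tiers, not
quantitative fold changes.

**Default parameters.** `noise_sd = 0.02` (spectral), `shift_jitter_sd =
0.003` ppm, `sample_shift_sd = 0.01` ppm (referencing error removed by TSP
alignment), `baseline_amplitude = 0.5`, `subject_sd = 0.2` and
`concentration_sd = 0.3` on the natural-log concentration scale (~20% and
~30% coefficients of variation — "considerable intragroup variability" while
preserving a strong multivariate signature, matching the reported pattern of
near-perfect strong models alongside weak ones). The default grid is
$2^{14}$ points over $-0.5$ to $10$ ppm, a desk-scale stand-in for 32k-point
acquisitions.

**What the generator does not emulate:** correlated (pathway-level)
concentration noise, peak-shape distortions (phasing errors,
water-suppression artifacts), heteroscedastic baseline noise, and
J-coupling. Passing tests therefore demonstrate the *statistical machinery*
is correct and calibrated; they do not certify performance on real spectra,
where peak overlap and correlated variation are harsher.

## Preprocessing

The chain is applied in this order, each step logged with its parameters:

1. **TSP alignment** — integer grid shift placing the apex found in the
   reference window at 0.00 ppm; edge values are repeated into vacated
   positions (zero-filling would create spurious area steps before
   normalization).
2. **Spline baseline correction** — one anchor per window of
   `knot_spacing` (default 0.25 ppm) at the window center, valued at the
   window *median*; a natural cubic spline through the anchors is
   subtracted. A median anchor tracks the baseline wherever peaks occupy a
   minority of the window and — unlike a window minimum, which is biased
   low by the extreme-value offset of noise — re-centers peak-free noise on
   zero. Negative intensities are retained; the glog transform accepts
   them.
3. **Region exclusion** — water (4.49–5.89 ppm) and TSP (< 0.14 ppm)
   columns are removed; the surviving grid may be non-uniform.
4. **Segmental alignment** — per configured segment and spectrum, the
   integer shift (≤ `max_segment_shift` points) maximizing Pearson
   correlation with the segment of the mean spectrum; the target is the
   mean spectrum computed once, not iterated, keeping the step
   deterministic. Default segments cover the citrate, taurine/choline and
   lactate regions, where pH-driven displacement is largest. Which regions
   the original workflow aligned is not recorded; segments are user
   configuration.
5. **Total-area normalization** — each row divided by its sum.
6. **Generalized log** —
   $g(y) = \ln\!\big((y - y_0 + \sqrt{(y-y_0)^2 + \lambda})/2\big)$ with
   $y_0 = 10^{-7}$, $\lambda = 5\times10^{-4}$: logarithmic for large $y$,
   finite and smooth through zero, up-weighting weak resonances.
   The analytic inverse $y = e^g - \lambda e^{-g}/4 + y_0$ makes the
   normalize–glog round trip testable to $10^{-9}$.

Mean centering is deliberately left to the modelling stage so held-out
data can be centered with training means. Whether normalization preceded
segmental alignment in the original workflow is implied only by sentence
order; the package follows that order.

## Multivariate models

**PCA** is computed by SVD of the centered matrix. Per-sample Q-residuals
(squared reconstruction residuals) are screened against the 95%
Jackson–Mudholkar limit computed from the discarded eigenvalue spectrum;
exclusions are reported, never silent. If the residual spectrum is empty
(data of exactly the model rank) the limit is infinite and nothing is
excluded.

**OSC** uses Wold's NIPALS-OSC: the leading principal score is iteratively
orthogonalized against the class-target matrix and regressed back onto X
until convergence; the final score is *exactly* orthogonalized before
deflation, so removed variation has zero correlation with the targets up to
floating point. Weights and loadings are stored to filter held-out rows.
One component is removed by default; the number used per model in the
original study is unstated and is exposed as configuration. The package
implements OSC-then-PLS-DA as operationally described, not a formal O-PLS
decomposition.

**PLS-DA** is NIPALS PLS1 for two classes (±1 coding; no inner iteration
needed) and PLS2 for one-hot multi-class targets, with X deflated per
latent variable and Y deflated in the PLS2 case. The regression vector
$B_a = W_a (P_a^\top W_a)^{-1} Q_a^\top$ reproduces training predictions at
any component count. Class assignment takes the nearest class target (sign
for two classes, arg-max for one-hot); exact ties go to the
lexicographically first class. Multi-class AUROCs are one-vs-rest on the
per-class prediction columns.

**Multilevel split.** For paired designs,
$X = \text{grand mean} + \text{between} + \text{within}$, where *between*
holds centered subject means and *within* the deviations from subject
means. ML-PLS-DA is PLS-DA on the within part; the subject effect $u_{sm}$
cancels there, which is the designed advantage on cohorts where
between-subject spread dwarfs the within-subject class effect. No OSC is
applied inside the multilevel path (the original description couples OSC to
the ordinary models only).

**Row-space compression.** When $p > n$, validation routines first rotate
X into its $n$-dimensional row space ($X = UDV^\top \mapsto UD$). Every
downstream operation — centering, OSC, PLS, prediction of held-out rows of
the same matrix — is linear on the row space, so results are identical to
working at full width while cross-validation and permutation loops run at a
fraction of the cost.

## Validation

* **Scheme rule**: leave-one-out for models with ≤ 20 spectra, otherwise
  Venetian blinds — interleaved assignment (sample *i* → fold *i* mod
  *n*~folds~) over class-sorted order with
  $n_\text{folds} = \min(10, \lfloor n/3 \rfloor)$ (the fold count is
  unstated in the source protocol; 10 interleaved splits is conventional).
* **Latent-variable choice**: CVER is computed for 1..max components; the
  smallest count attaining the minimum wins (parsimony tie-break).
* **Leakage policy**: centering and OSC are fitted on training folds only
  and applied to test folds. A `leaky = TRUE` flag reproduces whole-matrix
  filtering for comparison with legacy chemometrics software, which likely
  filtered globally.
* **Permutation test** (default 100 cycles; 200 for multilevel models):
  labels are permuted under seeded streams, the *full* cross-validation is
  re-run, and the empirical p uses the add-one estimator
  $(k+1)/(n+1)$, never zero. Because two p-values are reported per
  two-class model in the source results, per-class one-sided two-sample
  t-tests comparing each class's observed cross-validated predictions with
  the pooled permuted predictions are reported alongside the empirical p;
  this "random t test" interpretation is documented as such.
* **Double cross-validation** (multilevel path, default 20 repeats, max 3
  latent variables): the outer loop holds out both samples of one subject;
  the inner loop over remaining subjects (subject-wise folds, reshuffled
  each repeat) picks the component count; the reported error is the mean
  outer misclassification over repeats. Held-out subjects are centered on
  their own subject mean, so no training statistic touches them. The
  multilevel permutation test permutes labels *within* subject, matching
  the paired exchangeability structure.

All randomness flows from one explicit seed through derived child-seed
streams, making every reported number bit-reproducible.

## Univariate analysis

One well-resolved reference peak per metabolite is picked in the first
spectrum (apex within ±0.03 ppm of the target; flagged unresolved if
another listed metabolite's apex of at least equal intensity lies in the
window) and tracked across all spectra as the windowed maximum.
Intensities are taken from the normalized, *pre-glog* matrix so means, SDs
and fold changes stay on a concentration-proportional scale. Picks below
five times the spectrum's noise level (median absolute first difference /
√2) are flagged, not dropped.

Test selection: unpaired data use Welch's t-test if both groups pass
Shapiro–Wilk at p ≥ .05, else the Wilcoxon rank-sum test; paired data use
the paired t-test if the *within-pair differences* pass Shapiro–Wilk, else
the Wilcoxon signed-rank test. Testing normality of the differences (rather
than of each member) is the package's reading of an ambiguous protocol: the
differences are the quantity whose normality the paired t-test assumes.
Significance tiers are reported at .05/.005/.0005 without multiple-testing
correction, as in the source convention; a Benjamini–Hochberg column is
emitted alongside, clearly labelled an extension.

## Numerical choices and degenerate inputs

* Constant (zero-variance) groups make Shapiro–Wilk undefined; they are
  treated as maximally non-normal (p = 0), routing to rank tests.
* Identical groups yield p = 1 ("no evidence"), tier `ns`.
* Non-positive total spectral area or group means raise errors naming the
  sample (normalization) or set an `undefined_ratio` flag (fold changes).
* Segment shifts that push a segment entirely off its window are skipped
  (a constant vector has no defined correlation).
* Prediction ties are broken to the lexicographically first class and this
  rule is documented and tested.
* OSC iteration caps at 50 sweeps with a $10^{-10}$ relative tolerance;
  the final orthogonalization is exact regardless of convergence.

## Problem sizes used in the test suite

The suite favours many small, seeded simulations over few large ones:
structural tests run on 512–2048-point grids; tests that depend on
lineshape fidelity (power, multilevel advantage, the acceptance script) use
4096-point grids, since grids coarser than about twice the simulated 2-Hz
linewidth undersample the Lorentzians and sub-grid jitter then acts as
multiplicative sampling noise. Calibration checks use 200 null cohorts of
n = 40 at 99 permutation cycles; power checks use 50 cohorts at the
anchor-comparison sizes (68 vs 28); the multilevel advantage uses 20 paired
cohorts of 16 subjects. These sizes are the package's own desk-scale
choices.

## Known limitations

* Lorentzian-only lineshapes and independent per-metabolite noise make the
  synthetic task somewhat easier than real tissue spectra; calibration
  results transfer, absolute power estimates do not.
* The per-class p-value ("random t test") is an interpretation of a
  tersely described procedure; the empirical permutation p is always
  reported alongside and should be preferred.
* Q-residual screening assumes the PCA model captures the bulk of benign
  variation; with very few samples the Jackson–Mudholkar limit is noisy.
* The CLI (`inst/cli/nmrfield.R`) is a thin wrapper over the exported
  functions; vendor NMR formats are out of scope (the pipeline begins at
  phased, frequency-domain spectra in the documented CSV schema).
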
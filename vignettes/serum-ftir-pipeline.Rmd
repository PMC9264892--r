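---
title: "Methods: serum ATR-FTIR diagnostic classification with serodisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum ATR-FTIR diagnostic classification with serodisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serodisc)
```

## The problem

Attenuated total reflection Fourier-transform infrared (ATR-FTIR)
spectroscopy of dried serum films is a candidate low-cost diagnostic: the
mid-infrared absorbance spectrum is a composite fingerprint of the serum
proteome and metabolome, and disease can shift the relative intensities of
protein, phosphate and carbohydrate bands. A typical study design measures
each patient nine times (three separately deposited films, each scanned
three times), classifies individual spectra, and diagnoses each patient by
the consensus of their nine spectrum-level predictions.

serodisc implements that complete analysis chain — preprocessing,
classification, patient-grouped evaluation, ROC analysis, and
permutation-null validation — together with a synthetic cohort generator
that reproduces the replicate structure, so every stage is testable without
access to any clinical data.

## Synthetic cohorts

`simulate_cohort()` draws each spectrum as

$$y(\tilde\nu) \;=\; b\,\bigl[s(\tilde\nu) + z\,\delta(\tilde\nu) +
  d_{\text{patient}}(\tilde\nu) + d_{\text{film}}(\tilde\nu)\bigr]
  + p(\tilde\nu) + \varepsilon(\tilde\nu),$$

where $s$ is a fixed "serum" profile (sum of Gaussian bands: amide A ~3300,
C–H ~2960, amide I ~1650, amide II ~1545, phosphate ~1240, carbohydrate
~1100/~1040 cm⁻¹), $\delta$ is the class-difference profile added for cases
($z = 1$), $b = e^{N(0,\sigma_b)}$ is multiplicative scatter,
$p$ is a random polynomial baseline, and $\varepsilon$ is white instrument
noise. The default class difference sits on the amide II flanks (~1570 and
~1500 cm⁻¹) with smaller phosphate (~1270) and carbohydrate (~1050)
contributions — the regions where importance profiling localizes serum
cancer signals.

Two design choices matter:

* **Scatter before baseline.** $b$ multiplies the chemical signal before
  the additive baseline, so an EMSC model (reference scale + polynomial)
  is its exact algebraic inverse. This makes the preprocessing testable as
  model inversion: with all within-class noise switched off, corrected
  spectra of one class collapse to a single curve (asserted to 1e-6).
* **Biological variation on the discriminatory bands.** Patient and film
  deviations jitter the amplitudes of *all* bands, including the effect
  bands themselves (`effect_jitter_sd`, default 0.02 absorbance at patient
  level, a third of that per film). Without this, the class-difference
  directions would be orthogonal to every noise source and any nonzero
  effect would separate perfectly — an unrealistic regime in which neither
  class imbalance nor moderate effects could be studied. With it,
  `effect_size` becomes a standardized separation: per effect band the
  case–control shift is about `effect_size` patient-level standard
  deviations. We use three named regimes throughout the package's tests:
  weak = 0.5 (patient-level AUC ≈ 0.66), moderate = 1.5 (AUC ≈ 0.89, the
  symptomatic-control analogue), strong = 3 (accuracy ≳ 0.95, AUC ≈ 0.99,
  the healthy-control analogue).

Replicate noise is ordered as a real acquisition would be:
between-patient > between-film > between-scan
(`patient_sd = 0.06`, `bio_sd = 0.02` relative; `tech_sd = 0.002`
absorbance), and this ordering is recovered empirically from the simulated
replicates in the tests. Each patient consumes an RNG substream derived
from the cohort seed and the patient counter, so any subset of patients is
reproducible in isolation.

What the generator does **not** emulate: water-vapour and CO₂ artefacts,
ATR penetration-depth dispersion, Mie scattering, detector nonlinearity,
batch/instrument drift, and any claim about true serum band intensities.
Passing tests therefore demonstrate that the *pipeline* behaves correctly
(discriminates when a class effect exists, stays calibrated when none
does), not that any particular clinical performance would be achieved.

## Preprocessing

`run_preprocess()` applies, in a fixed order that a test guards against
silent rearrangement:

1. **EMSC** (`emsc_correct()`): each spectrum $x$ is fit by least squares
   as $x \approx b\,r + \sum_k c_k P_k(t)$, with $r$ the reference
   spectrum and $P_k$ Legendre polynomials on the axis rescaled to
   $[-1, 1]$; the corrected spectrum is $(x - \sum_k c_k P_k)/b$. The
   polynomial order defaults to 2 (offset + linear + quadratic drift) and
   is configurable 0–4. The reference defaults to the **mean of the
   training spectra of the current split** — never test spectra, which a
   test asserts by tampering with test rows — with a supplied-reference
   option for parity with studies that use an external pooled serum
   spectrum. The fit is verified against an independently coded generic
   least-squares oracle on random instances to 1e-8.
2. **Fingerprint crop** (`crop_region()`): keep 1800–1000 cm⁻¹ inclusive
   (401 points on the default 2 cm⁻¹ grid).
3. **Vector normalization** (`vector_normalize()`): per-spectrum mean
   centring followed by unit-L2 scaling. The per-spectrum (rather than
   per-variable) centring was a genuinely open choice; per-spectrum was
   selected because it is the usual spectroscopic normalization and is
   invariant to residual per-spectrum affine intensity changes; plain L2
   without centring is available by configuration.
4. **Binning** (`bin_spectra()`): non-overlapping groups of 8 points are
   replaced by their mean intensity and mean wavenumber (means, not sums,
   keep magnitudes comparable across bin factors); a trailing remainder
   shorter than the factor is dropped with a warning so every feature
   averages equally many points. 401 points → 50 features.

The default full-axis chain is 1776 → 401 → 50 features.

## Classifiers

Three families sit behind one contract (`fit_model()`,
`predict_scores()`, `predict_labels()`): scores are continuous and
oriented so larger = more cancer-like.

* **PLS-DA** (`fit_plsda()`): PLS1 regression of the 0/1 class indicator
  via NIPALS deflation, written here (latent scores verified mutually
  orthogonal; predictions verified against an independent PLS
  implementation to 1e-8). Label threshold 0.5 on the predicted response;
  downstream ROC analysis makes the exact cut mostly irrelevant.
* **Random forest** (`fit_rf()`, via ranger): 500 trees, Gini splits;
  score = fraction of trees voting cancer; per-feature mean decrease in
  Gini retained for importance profiling.
* **Linear SVM** (`fit_svm_linear()`, via e1071): soft margin, score =
  signed distance to the hyperplane, sign fixed toward cancer on the
  training data.

Hyperparameters are tuned by `tune_cv()` with 5-fold cross-validation in
which folds are formed over **patients**, not spectra — replicate leakage
between folds would otherwise inflate CV accuracy. Grids: PLS-DA latent
variables 1–15; RF mtry {√p, p/4, p/2}; SVM cost {0.01, 0.1, 1, 10, 100}.
Ties break toward the simpler candidate. `smote()` (hand-implemented:
synthetic minority samples $x_i + u(x_{nn} - x_i)$, $u \sim U(0,1)$, among
the k = 5 nearest minority neighbours) runs inside each training split
only, never before splitting.

## Evaluation

`run_repeats()` is the evaluation engine: per repeat a patient-grouped,
class-stratified 70/30 split (all nine spectra of a patient stay
together), EMSC reference from the training rows, preprocessing of all
rows, optional SMOTE, grouped tuning, refit, spectrum scores on the test
set, majority consensus and mean score per patient, and patient-level
sensitivity / specificity / accuracy with cancer positive. Fifty-one
repeats is the default; metrics are reported as mean ± SD over repeats.

`pooled_roc()` computes the empirical ROC from patient mean scores pooled
over all repeats (each patient contributes once per test appearance); the
trapezoid AUC is exactly the pairwise concordance
$P(s_{\text{case}} > s_{\text{ctrl}}) + \tfrac12 P(\text{tie})$, asserted
against a brute-force oracle to 1e-12. Pooling was chosen over a
single-split ROC for stability; the per-repeat AUC mean is also reported.
`operating_points()` reports, inside the region where sensitivity and
specificity both exceed a floor (0.60 or 0.45 conventionally): maximum
sensitivity (A), maximum specificity (B), and the most balanced point (C,
minimum |sens − spec|, ties to the larger sum); boundary points are
admitted and an empty region is reported as such.

## Permutation validation

`permutation_test()` runs, per iteration, a fresh patient-grouped split;
an observed model trained on true labels and a null model trained after
permuting the patient→class map (labels permuted at patient level so all
nine spectra move together and class counts are preserved exactly). Both
accuracy distributions are retained for the familiar two-histogram
display.

The p-value is the add-one exceedance of the null distribution against a
**single** observed accuracy (the first iteration's):
$p = (1 + \#\{a^{\text{null}}_i \ge a^{\text{obs}}_1\})/(n + 1)$. An
alternative — comparing the nulls with the *mean* observed accuracy — is
tempting but provably miscalibrated: under no class effect the mean of
many observed accuracies concentrates at the centre of the null
distribution, so that estimator returns p ≈ 0.5 almost surely and its
type-I error at any usual α is ≈ 0. The single-draw form is the classic
permutation estimator: exactly valid under exchangeability, uniform when
no effect exists (verified by a 200-run calibration experiment in the
acceptance tests), never zero, and equal to the floor $1/(n+1)$ when the
distributions are disjoint.

Two honest caveats, both visible in the package's own outputs:

* **Conditional chance structure.** On one finite cohort the
  split-averaged accuracy can sit above or below 0.5 even with no class
  effect, because the realized patients carry a chance class difference
  that train and test patients share. The permutation test accounts for
  this — the null models see the same cohort — which is precisely why a
  cohort-level permutation test is needed instead of a binomial test
  against 0.5.
* **Tuning reuse.** By default hyperparameters are tuned once (first
  split, true labels) and reused across iterations for tractability
  (`retune = TRUE` restores full re-tuning). Reuse leaks a little
  cohort-level adaptivity into later observed iterations, biasing the
  *observed distribution's mean* slightly upward on null cohorts (~0.02
  at 20 vs 20 patients); the p-value is unaffected because it uses the
  first iteration, whose test patients never informed the tuning.

`gini_profile()` averages RF Gini importances over repeats onto bin-centre
wavenumbers and tabulates the top 15; equal importances rank by ascending
wavenumber (documented tie rule).

## Orchestration and problem sizes

`run_all()` ties the stages together from one `run_config()` (or YAML
file) and writes metrics tables, ROC coordinates, operating points, the
permutation result, the Gini profile, figures and a JSON manifest with all
seeds and output checksums; identical configurations reproduce every
numeric output byte-for-byte. Three shipped configurations
(`inst/extdata/configs/cohort{A,B,C}.yaml`) mirror the three canonical
designs: 100 vs 100 balanced (strong effect, no resampling), 35 vs 35
balanced (moderate effect), and 100 vs 35 imbalanced with SMOTE — each at
the study scale of 51 splits and 1000 permutation iterations. A thin
command-line front end over the same functions is installed at
`inst/cli/serodisc.R`.

The test suite exercises the same machinery at reduced problem sizes
chosen to keep a full run on one CPU comfortable while leaving every
qualitative regime intact: cohorts of 20–50 patients per class, 2–11
splits, permutation runs of 19–200 iterations, and a 200-cohort type-I
calibration experiment at 99 iterations each. The acceptance script
reports an analogue of the discovery design at 50 vs 50 patients with 11
splits and 200 permutation iterations.

## Known limitations

* The generator's band model is deliberately simple (Gaussian bands,
  polynomial baselines); real serum spectra carry correlated artefacts the
  pipeline has not been stress-tested against here.
* EMSC assumes the multiplicative factor acts on the whole chemical
  signal; wavelength-dependent scatter (Mie-type) is out of scope.
* The permutation default of reusing tuned hyperparameters trades a small
  optimistic shift in the *displayed* observed distribution for a large
  speed-up; the reported p-value does not inherit that shift.
* Binning and cropping assume a uniform axis within the fingerprint
  region; irregular grids are not resampled.
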
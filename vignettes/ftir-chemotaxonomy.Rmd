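---
title: "Methods: chemotaxonomic FTIR classification with ftirtax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemotaxonomic FTIR classification with ftirtax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `ftirtax`, the parameters that
matter and why their defaults are what they are, what the synthetic-spectrum
generator does and does not emulate, and the numerical decisions taken where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The scientific problem

Fossil organic matter in chert is kerogen: a diagenetic condensate whose
infrared absorption pattern still reflects the precursor biochemistry.
Chitin-protein walls (fungi, arthropods, oomycetes, amoebae) leave
amide I/II, nitrogen-bearing and carboxylate fossilization products;
bacterial biomass leaves a strongly aliphatic (CH~x~) fingerprint; plant
tissue and *Prototaxites* are depleted in both but retain aromatic and
carbonyl absorptions. `ftirtax` turns those contrasts into a testable
classification workflow: can a fossil's taxon be recovered from its
spectrum, and does *Prototaxites* fall inside or outside every known group?

## Data model

A `spectrum` stores a strictly ascending positive wavenumber grid (cm^-1^),
an absorbance trace, a taxon label from a closed seven-class vocabulary
(`"unknown"` is allowed only for prediction inputs), an instrument mode, and
an append-only preprocessing history. Instruments commonly emit descending
grids (4000 → 650 cm^-1^); these are normalized to ascending on load so
that derivative signs and window arithmetic are unambiguous everywhere.
Intensities are dimensionless absorbance; no transmittance conversion is
attempted. File support covers wide/long CSV and a deliberately minimal
JCAMP-DX reader (single XYDATA block, AFFN numbers) — vendor binary formats
are out of scope.

## The synthetic generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is evaluated.

* **Design.** Per-class counts default to the analysed assemblage: 37
  Plantae, 24 Fungi, 12 Arthropoda, 10 Bacteria, 4 Oomycetes, 3 Amoebae and
  12 *Prototaxites* spots — 102 samples on a 650–4000 cm^-1^ grid at
  4 cm^-1^ resolution. Each acquisition spot is one sample; no per-specimen
  averaging is performed.
* **Signal.** Each spectrum is a sum of Gaussian bands (amide I 1655,
  amide II 1545, N-products 1590, carboxylate 1560, aromatic C=C 1600,
  carbonyl 1710, CH~2~ 2925, CH~3~ 2960 cm^-1^; Gaussian σ 7–15 cm^-1^,
  i.e. FWHM roughly 15–40 cm^-1^), plus a silica matrix band at 1615 cm^-1^
  (σ 17) present in every class because all fossils are chert-hosted.
  Band shapes are Gaussian rather than Voigt: nothing downstream depends on
  the lineshape.
* **Variation.** Band heights are lognormal with CV 0.12 about class means,
  centers jitter with σ = 2 cm^-1^, a degree-2 baseline polynomial with
  N(0, 0.02) coefficients models drift, and i.i.d. Gaussian noise has
  σ = 0.01 absorbance units (all heights are relative to a silica mean
  of 1). These levels are artifact parameters of this package chosen to look
  like clean ATR data on chert; they are **not** measured fossil values.
* **Class profiles.** The defaults encode the qualitative contrasts the
  analysis relies on — chitinous classes high in amide/N/carboxylate,
  Bacteria highest in CH~x~, *Prototaxites* lowest in combined
  amide + aliphatic signal but with clear aromatic/carbonyl bands, and a
  *Prototaxites* CH~3~:CH~2~ mean ratio of 0.75. The ordering constraints
  are asserted directly in the test suite.
* **Determinism.** One master seed drives everything; per-sample seeds are
  derived by a counter so any single sample can be regenerated in
  isolation.

What the generator does **not** emulate: Mie/ATR optical artifacts,
atmospheric water/CO~2~ lines, diagenetic gradients, spatially correlated
noise, and realistic inter-band covariance beyond the class means. Passing
tests therefore demonstrate that the machinery is correct and that the
workflow recovers structure of the kind the study posits — they do not
reproduce the real-fossil headline numbers, which depend on spectra that are
not deposited in a public archive.

## Preprocessing recipes

Three named recipes mirror the three acquisition modes:

* `atr-paper` — truncate to 1445–1750 + 2760–3000 cm^-1^ (closed
  intervals), ALS baseline, Gaussian smoothing, silica-peak normalization.
* `benchtop-paper` — Gaussian smoothing, ALS baseline, Savitzky–Golay
  second derivative (window 21, order 2).
* `synchrotron-paper` — truncate to 1440–3000 cm^-1^, Savitzky–Golay
  second derivative (window 9, order 2), Gaussian smoothing, vector
  normalization; `synchrotron-ratio` swaps the derivative for a baseline
  correction, the variant used for aliphatic band-ratio work.

Open choices and how they were settled:

* **Baseline method.** The source procedure says only that baselines were
  corrected. The default is asymmetric least squares (λ = 10^5^, p = 0.01,
  10 iterations), the common chemometric default and robust for broad chert
  backgrounds; a rubberband (lower convex hull) alternative is provided.
* **"Light" Gaussian smoothing** is quantified as σ = 2 grid points.
* **Silica normalization** searches a window (default 1585–1645 cm^-1^)
  rather than exactly 1615 cm^-1^, because peak apexes shift a few cm^-1^
  between samples. (The 1615 cm^-1^ reference sits in the amide-I region;
  the package follows the established normalization procedure without
  adjudicating the band assignment.)
* **Edges.** Smoothing uses reflect padding; Savitzky–Golay endpoints are
  one-sided fits and should be excluded from derivative-based band picking.
* **Atmospheric correction** is not modelled: the synthetic data contain no
  atmospheric lines, so the step defaults off.

## Band features and the aliphatic ratio

Six bands are extracted (amide I, amide II, N-products, carboxylate, CH~2~,
CH~3~). The supplementary band table of the source study is not reprinted in
its main text, so centers and windows are literature-standard values for
kerogenised material and live in plain fields that a caller can override.
Height mode (maximum within center ± half-window) is the default; area mode
integrates above a local linear baseline drawn between the integration
window's endpoints — cheap, deterministic, and sufficient for sensitivity
analysis. Negative features are clipped to zero with a warning.

The chain-length model treats an alkane chain as two terminal CH~3~ groups
and n − 2 CH~2~ groups with a CH~2~:CH~3~ absorptivity ratio k, so
R~3/2~ = 2k/(n − 2). The original calibration mapping is not reprinted, so
k is fixed by the anchor R~3/2~ = 0.75 ↦ n = 9, giving k = 2.625, exposed
as an argument. The mapping is strictly decreasing, n → 2 as R~3/2~ → ∞ and
n → ∞ as R~3/2~ → 0⁺. Whether the original ratio used heights or integrals
is ambiguous; both modes are provided (heights by default).

## Exploration

PCA is mean-centered but not autoscaled — standard for spectra, whose
common intensity scale is meaningful; band features are standardized only
for the CCA, which is how the source workflow preprocessed them. Loadings
fix their sign so the largest-magnitude entry is positive, making bootstrap
cosines and score plots reproducible. Bootstrap stability resamples rows
with replacement (default 100 resamples) and reports |cos| between original
and resampled loadings; degenerate zero-variance resamples are skipped and
counted rather than retried, a simpler determinism contract.

Outlier screening uses Hotelling T² inside the retained subspace with the
F-distribution limit, and the Q residual with the Jackson–Mudholkar limit
computed from the residual eigenvalues. The decision rule is **OR** at 99%
confidence by default — the conservative screening choice, configurable to
AND and other confidence levels, since the source study plots T² against Q
without stating its rule; it also does not state how many samples were
removed, so the package reports counts. Flagged samples are removed and the
dataset recompiled (labels and one-hot matrix rebuilt).

A practical note on power, computed by the test suite: a narrow spike of
height 10× the noise σ in a screened dataset is reliably detected when the
model retains enough components to absorb the smooth within-class variation
(the tests use 20 PCs on ~100 preprocessed single-class spectra, at which
point the spike either dominates the residual Q or, once absorbed as its own
component, produces a T² near n − 1 that exceeds the F limit). With only a
few dozen samples, a single absorbed outlier direction yields
T² = (n−1)²/n, which sits *below* the 99% F limit — masking is a real
phenomenon at small n, and screening power should be assessed at the sample
size actually used.

CCA is implemented natively (ter Braak: chi-square standardization of the
one-hot response, row-weighted least-squares projection onto standardized
explanatory variables, SVD of the fitted matrix), with `vegan::cca` serving
as an independent cross-check in the tests. Scaling 1 (site-focused) is the
default, matching the source analysis; scaling 2 is available. Rank-deficient
explanatory matrices trigger a warning and a pseudoinverse fit.

## Discrimination

The supervised stage composes: class subset → stratified 70/30 split
(largest-remainder allocation toward the global target, so each lineage
keeps its ratio within rounding) → PCA fitted on training rows only (2 PCs
for the nearly balanced bacteria task, 4 for the others, both configurable)
→ projection of test rows → SMOTE on the training scores → LDA, escalating
to an RBF SVM when the LDA leave-one-out accuracy falls below 0.95. PCA and
SMOTE strictly follow the split to avoid leakage, and a test asserts that
altering test rows changes no fitted parameter.

Open choices: the SVM kernel is RBF, inferred from the C/γ grid-search
language of the source (configurable); grid ranges
(C ∈ {0.01, …, 100}, γ ∈ {0.001, …, 1}) and the 0.95 escalation threshold
are artifact choices encoding its parsimony narrative (linear model first,
SVM only when needed); leave-one-out scoring uses accuracy; ties resolve to
the smallest C then smallest γ. SMOTE is applied only when the training
imbalance ratio exceeds 1.25 — the bacteria task (12 vs 10) is already
nearly balanced. Train metrics are computed on the real training samples,
not the synthetic SMOTE points. MCC with a zero denominator factor is
defined as 0, with a warning. The positive class is *Prototaxites* in every
report so that precision/recall/MCC are comparable across tasks.

## One-class modelling (DD-SIMCA)

A PCA model of the target class yields per-sample score distances
SD (Mahalanobis inside the model) and orthogonal distances OD (squared
residual). Both are treated as scaled chi-square variables; scales and
degrees of freedom are estimated by moments (N = round(2·mean²/var),
scale = mean) or robustly (median/IQR matched to chi-square quantiles,
insensitive to training outliers). The full decision statistic
c = N~SD~·SD/SD₀ + N~OD~·OD/OD₀ is compared against χ²~1−α~(N~SD~ + N~OD~) —
a half-plane acceptance region in the scaled distance coordinates, hence
convex. Defaults: α = 0.05 (the source does not state its level), DoF
rounded to the nearest integer with floor 1, training outliers flagged at
α~out~ = 0.01 and reported rather than removed.

Component selection follows the stated rule — leave-one-out sensitivity,
maximized, ties to the smallest count. A caveat the test suite quantifies:
because the acceptance region is approximately calibrated at 1 − α for
*any* component count, LOO sensitivity is only weakly informative about the
latent dimensionality and tends toward parsimonious counts; the selector
honors its contract but should not be read as a consistent dimensionality
estimator.

Calibration is checked at deliberately large problem sizes where estimation
noise is small relative to the ±2% assertion band: the coverage test trains
on 1,000 generated in-class samples (band-feature space, 2 components,
moments estimates) and evaluates 10,000 fresh draws. At the study's actual
n = 12 target samples, DoF and scale estimates are too noisy for a tight
coverage statement; the pipeline still runs the n = 12 case and reports its
sensitivity and specificity as observed. Note that fresh-sample coverage is
assessed against a model whose residual space is estimated from many more
samples than features — with few samples and many features the training OD
is biased low and the nominal level is not attained, which is why the
calibration uses the six-band feature space rather than full spectra.

## Pipeline and reproducibility

`run_pipeline()` executes simulate/load → preprocess → features → explore
(with optional outlier removal) → classify → one-class, writing CSVs and
JSON reports plus a manifest with MD5 hashes and the seeds used. One
top-level seed derives all stage seeds; reruns with the same configuration
are byte-identical (no timestamps are written). Configuration is YAML (JSON
accepted), validated non-fail-fast with every problem reported at once and
all defaults equal to the values above. The package's R functions are the
interface; the acceptance script under `scripts/` shows the intended
headless usage.

## Known limitations

* Synthetic spectra are far cleaner and more Gaussian than real chert
  measurements; real-data performance claims cannot be transferred.
* Band deconvolution of overlapping peaks is out of scope; heights in
  crowded regions (amide I vs the silica reference) include neighbouring
  tails.
* The CCA permutation test in the suite is a diagnostic, not a full
  ordination significance framework.
* Multiclass (> 2) classification and probability calibration are
  non-goals; the discrimination stage is deliberately binary.
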
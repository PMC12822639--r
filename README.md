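# ftirtax

Chemotaxonomic classification of fossil FTIR spectra.

Organic matter preserved in chert carries a molecular fingerprint of the
organism it came from: chitinous taxa (fungi, arthropods, oomycetes,
amoebae) fossilize into amide-, nitrogen- and carboxylate-rich products,
bacteria into aliphatic-dominated kerogen, and plants and the enigmatic
*Prototaxites* into material depleted in both but carrying aromatic and
carbonyl signal. `ftirtax` implements, as a reusable and tested R pipeline,
the chemometric workflow used to exploit those contrasts: spectral
preprocessing, absorption-band feature extraction, multivariate exploration,
supervised binary discrimination, and one-class modelling — together with a
seeded synthetic-spectrum generator that emulates a multi-taxon chert
assemblage (102 samples across 7 classes), so the whole pipeline is
exercisable and testable without any external data.

## What it computes

* **Preprocessing** — truncation to analysis windows (1445–1750 and
  2760–3000 cm⁻¹), asymmetric-least-squares or rubberband baseline
  correction, Gaussian smoothing, normalization on the silica overtone peak
  near 1615 cm⁻¹, vector normalization, and Savitzky–Golay derivatives
  (window 21 or 9, order 2), packaged as named recipes per acquisition mode.
* **Band features** — heights or locally-baselined areas for six
  biologically informative bands (amide I/II, N-bearing products,
  carboxylate, CH₂ and CH₃ asymmetric stretches), and the aliphatic ratio
  R₃/₂ = I(CH₃, ~2960)/I(CH₂, ~2925) with the alkane-model chain length
  n = 2k/R₃/₂ + 2 (k = 2.625, anchored so R₃/₂ = 0.75 ↦ 9 carbons).
* **Exploration** — mean-centered PCA (first 10 PCs), bootstrap loading
  stability (cosine between original and resampled loadings, 100
  bootstraps), Hotelling T² / Q-residual outlier screening with F-based and
  Jackson–Mudholkar limits, and a native ter Braak canonical correspondence
  analysis (scaling 1) of one-hot taxon labels on standardized band
  intensities.
* **Discrimination** — stratified 70/30 split, train-only PCA projection
  (2 PCs for the nearly balanced bacteria task, 4 otherwise), SMOTE
  balancing of the training scores, LDA first with escalation to an RBF SVM
  tuned by leave-one-out grid search over C and γ, and five metrics
  (accuracy, precision, recall, F1, MCC) with *Prototaxites* fixed as the
  positive class.
* **One-class modelling** — DD-SIMCA: a PCA model of the target class with
  score distance (SD) and orthogonal distance (OD) treated as scaled
  chi-square variables, full decision statistic
  c = N_SD·SD/SD₀ + N_OD·OD/OD₀ compared to χ²₁₋α(N_SD + N_OD), with
  moments or robust (median/IQR) parameter estimation, leave-one-out
  sensitivity-based component selection, and specificity evaluation against
  alien classes.

## Worked example

```r
library(ftirtax)

ds   <- generate_dataset(study_design(seed = 42))   # 102 labelled spectra
proc <- apply_recipe(ds, "atr-paper")               # truncate/baseline/smooth/normalize
res  <- run_binary_task(proc, "vs-fungi", config = list(seed = 7))
res$test_metrics
#> confusion TP=4 FP=0 FN=0 TN=7 | acc 1.000 prec 1.000 rec 1.000 F1 1.000 MCC 1.000

r <- ch3_ch2_ratio(ds$spectra[[which(ds$labels == "Prototaxites")[1]]])
r
#> CH3/CH2 ratio 0.649  (CH3 0.09965 / CH2 0.1535)  ~10.1 carbons
```

On the shipped synthetic design the discrimination tasks separate
*Prototaxites* from every other group (the classes are constructed to be
separable), and the aliphatic ratio of generated *Prototaxites* spectra
averages ≈ 0.75, i.e. an estimated chain length of about nine carbons.

## Layout

* `R/` — implementation (spectral data model and I/O, generator,
  preprocessing, bands, exploration, classification, one-class, pipeline).
* `tests/testthat/` — unit, property and acceptance tests.
* `vignettes/ftir-chemotaxonomy.Rmd` — methods notes: models, parameter
  choices, and what the synthetic data do and do not emulate.
* `scripts/acceptance.R` — end-to-end reproduction script (above).
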
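---
title: "Biomarker discovery from multi-platform metabolomics feature tables"
author: "metamark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomarker discovery from multi-platform metabolomics feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamark)
```

# Overview

`metamark` implements a complete case-control biomarker-discovery workflow
for untargeted mass-spectrometry metabolomics, of the kind used to search for
plasma metabolite signatures of a clinical phenotype in small cohorts. The
input is a set of per-platform *mass-feature tables* — each feature an ion
defined by its m/z and retention time, with an integrated peak area per
sample. The workflow is:

1. **Quality filters** remove low-abundance features, ions with
   non-biological mass defects, known contaminants, and rarely detected
   features.
2. **Internal-standard normalization** divides out per-sample global
   intensity variation (batch, injection, extraction) using spiked reference
   compounds.
3. A **univariate screen** (Welch t tests, Benjamini-Hochberg FDR, peak-QC
   proxies) reduces thousands of features to a modeling set.
4. **Exact-mass annotation** assigns putative metabolite identities through
   electrospray adduct matching against a formula database.
5. A **nested cross-validation classification core** (PLS-DA and linear SVM)
   ranks features by a resample-averaged VIP index under recursive feature
   elimination, evaluates feature subsets on an untouched validation set, and
   calibrates everything against a label-permutation null.

Because real plasma cohorts cannot be redistributed, the package ships a
synthetic cohort generator with known ground truth; every stage of the
pipeline is exercised and tested against quantities the generator controls.

# The synthetic cohort generator

`sampleCohort()` and `generateFeatureMatrix()` emulate a two-group study of
young children (52 cases, 30 controls, ages 4–6.9, ~82% male, cases with a
lower IQ distribution) measured on five analytical platforms: HILIC and C8
liquid chromatography in positive and negative electrospray polarity, plus
GC-MS, with raw feature counts 3207 / 1865 / 3062 / 1568 / 485.

The abundance model is log-normal per feature:

$$\log A_{ij} = \mu_i + \log(f_i)\,[j \in \text{case}] + \beta_{b(j)} + s_j
+ \varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma_i^2)$$

* $\mu_i$ is set from a per-feature base abundance so that the *arithmetic*
  mean area equals the base (the $\sigma^2/2$ correction is applied), making
  the planted fold change $f_i$ exactly the expected case/control mean ratio.
* $\sigma_i$ derives from a coefficient of variation via
  $\sigma = \sqrt{\log(1 + \mathrm{cv}^2)}$. Within-group cv is drawn
  uniformly from 0.2–0.6 for background features — a calibration choice
  typical of integrated LC-MS areas, not a reported value.
* $\beta_{b(j)}$ is a per-batch multiplicative factor (3 batches, assigned
  round-robin within diagnosis so batches are balanced for class) and $s_j$ a
  per-sample loading factor; both are shared by all features of a sample,
  including internal standards, which is what makes internal-standard
  normalization effective.
* Internal standards have no group effect and a low residual cv (default
  0.05).

Artifact classes mirror what preprocessing filters remove: *noise* features
get a fractional mass above the biological mass-defect envelope, *low
abundance* features sit well below the abundance threshold, *contaminants*
are placed at configured m/z values, and cells are zeroed completely at
random at `missing_rate`. Class counts are assigned exactly
(`round(fraction * n)`), so the default design passes 1527 / 950 / 1096 /
514 / 485 features (4572 in total) through `defaultFilterConfig()` by
construction. Planted effects use fold changes spanning 0.67–2.55, the scale
reported for confirmed plasma metabolites in studies of this design.

What the generator does **not** emulate: correlated metabolite modules,
isotope/adduct redundancy between features, retention-time drift,
heteroscedastic missingness (real dropout is abundance-dependent), or
covariate effects (age, sex, medication). Passing tests on synthetic data
therefore demonstrate that the machinery is correct and calibrated — not
that a given real dataset contains a discriminative signature.

# Preprocessing

The mass-defect rule keeps a feature iff
$\mathrm{frac}(m/z) \le 0.3 + 0.001 \cdot m/z$. Biological ions occupy a
fractional-mass envelope that grows roughly linearly with mass; the linear
form and its default constants are a convention shared between the filter
and the generator (no published formula exists for the manual practice it
replaces). GC-MS features bypass the mass-defect and contaminant rules —
both are electrospray artifacts — which is why all 485 GC-MS features
survive by design. The abundance rule thresholds the per-feature median area
(default 1000, configurable; published workflows leave the value unstated),
contaminants match within 20 ppm, and the presence rule requires nonzero
areas in at least half the samples. Rules are per-feature predicates, so the
removal set is independent of evaluation order; the report attributes each
removal to its first failing rule in a fixed order (abundance, mass defect,
contaminant, presence). Internal standards are never removed.

Normalization multiplies each sample by (experiment-wide median of
per-sample internal-standard medians) / (that sample's IS median). After
normalization every sample's IS median equals the same constant, and the map
is idempotent. Filters are computed on all samples: the rules are
class-blind, so this does not leak diagnosis information into the later
train/validation separation (the univariate screen and all model fitting use
training samples only).

# Univariate screen

Welch t tests compare case and control mean integrated areas per feature
(vectorized closed form; tested against `stats::t.test` to 1e-10).
Fold change is the ratio of arithmetic means of normalized areas — the
estimator is a package choice, as the quantity is usually reported without a
definition. Benjamini-Hochberg q values are computed over the full set of
features entering the screen; computing FDR over a pre-filtered subset would
understate multiplicity. The manual extracted-ion-chromatogram review used
in practice is replaced by its reproducible core: a minimum peak-height
proxy (maximum per-sample area > 3000, the one numeric criterion such
reviews state) plus a presence fraction of at least 0.5. A feature enters
the modeling set iff p < 0.05 and both QC rules pass.

# Annotation

Candidate identities come from exact-mass matching: for metabolite mass $M$
and adduct with shift $\delta$ and charge $z$, the theoretical m/z is
$(M + \delta)/|z|$ and a hit requires relative error within 20 ppm and
polarity agreement with the feature's platform. The default adduct table
covers [M+H]+, [M+Na]+, [M+NH4]+ and [M−H]−, [M+Cl]−, [M+HCOO]−
(mass shifts include the electron). Element masses cover C, H, N, O, S, P,
Na, Cl, K, F to better than 1e-4 Da. Proprietary spectral-fit scores are
replaced by two reproducible confidence *flags* (never hard filters):
presence in at least 50% of samples, and retention-time agreement within
35 s among features matching the same metabolite/adduct. All annotations are
putative; tandem-MS confirmation is out of scope.

# Classification core

Both model families operate on autoscaled features (mean 0, sd 1), with
scaling parameters fitted on the training portion only and applied to any
test or validation data.

**PLS-DA** is fitted by NIPALS on the class coded −1/+1: each component's
weight vector maximizes covariance with the class code, followed by
deflation; prediction is the sign of the regressed score. Variable
importance in the projection is

$$\mathrm{VIP}_j = \sqrt{\; p \cdot \frac{\sum_a \mathrm{SSY}_a\,
(w_{aj}/\lVert w_a \rVert)^2}{\sum_a \mathrm{SSY}_a}}$$

with $\mathrm{SSY}_a$ the class variance explained by component $a$;
$\sum_j \mathrm{VIP}_j^2 = p$ identically, which the tests assert on every
fitted model. **Linear SVM** fits use `e1071`; the per-feature importance is
|weight|, rescaled so squared importances also sum to $p$, making the two
families' indices comparable. The weight vector is oriented so larger
decision values indicate the case class. AUC uses the rank (Mann-Whitney)
form with ties counted 1/2.

`nestedCvRank()` runs the nested procedure: 100 outer resamples of a
class-stratified 80:20 split (61 training samples give 49/12 partitions);
within each outer-train part an inner 10-fold cross-validation tunes the
model parameter (components 1–5 for PLS-DA, cost 0.01/0.1/1/10 for the SVM —
grids are package defaults), and backward recursive feature elimination
removes the 20 lowest-importance features per step, scoring each candidate
subset (179, 160, …, 20 for a 179-feature set) by inner-CV AUC; the best
subset's model predicts the outer-test part. Design points left open by
common practice, decided here:

* Tuning runs once per resample on the full feature set and the tuned
  parameter is reused across RFE steps (re-tuning at every step multiplies
  cost ~9-fold for negligible gain on 49-sample folds).
* Inner-CV AUC pools out-of-fold decision values into a single AUC; with
  10 folds of ~5 samples, per-fold AUCs are too unstable to average.
* Ties in subset AUC resolve toward the smaller subset; ties in importance
  break by feature id (stable, deterministic).
* A feature eliminated during RFE contributes its *last-computed* importance
  to that resample's score; the VIP index is the across-resample mean, ranked
  descending. Outer-test samples never touch scaling, tuning, elimination or
  ranking — the test suite verifies that corrupting outer-test rows leaves
  the VIP index bit-identical.
* One run seed deterministically derives per-resample seeds, so any resample
  is reproducible in isolation.

`featureSteppingEval()` then steps through the ranked index in 20-feature
bins (20, 40, …, all features), refitting on the full training set and
predicting an untouched validation set — the honest estimate of signature
performance at each panel size. `permutationNull()` reruns the entire nested
procedure with a fresh label permutation per outer resample; the mean
held-out AUC should sit near 0.5 (published studies of this design report
0.52 with a 0.48–0.57 interval), and a real signature should exceed the
null's 97.5th percentile.

# Numerical and degenerate-input behavior

Constant feature columns make autoscaling ill-defined and raise an error
naming the feature. NIPALS stops early if the residual covariance drops
below 1e-12; a fit with zero explained class variance errors rather than
returning undefined VIPs. Welch tests require two values per group and a
nonzero variance in at least one group. Samples whose internal-standard
median is zero abort normalization with the sample named. `bhAdjust`
validates p ∈ [0, 1]. RFE refuses feature sets smaller than its step size.

# Problem sizes used in the tests

The test suite exercises the study-scale configuration where the claim
depends on it: the five-platform default design (10187 features, 82
samples), the 61×179 modeling set with 30 planted effects, and 100-resample
nested CV and permutation runs for both families. Calibration checks with
purely statistical claims (fold-change recovery, type-I error, oracle
comparisons) run at the smallest sizes that give the stated tolerances,
e.g. fold recovery at 10,000 samples within 2% and screen type-I error at
4572 features within ±0.02.

# Limitations

* The generator's independence between features understates the difficulty
  of real metabolomics, where correlated features dilute VIP rankings.
* The EIC-quality proxy captures only the numeric part of what is, in
  practice, a partly manual review.
* Fold changes and their significance are computed on normalized arithmetic
  means without covariate adjustment.
* Annotation is exact-mass only: isomers are indistinguishable and every hit
  is putative.
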
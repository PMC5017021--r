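---
title: "Methods: untargeted metabolomics toxicity profiling with toxmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted metabolomics toxicity profiling with toxmetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxmetab)
```

## Scope and data model

`toxmetab` implements the data-evaluation stage of an untargeted LC-MS
metabolomics toxicity study on cultured cells: the pipeline starts at the
feature table (features defined by m/z and retention time, with one
peak-area column per injection) and ends at QC-filtered, cell-number
normalized, per-timepoint differential statistics, multivariate summaries
and identification-level annotation. Peak picking and feature finding from
raw spectra are upstream of this package and out of scope.

A study comprises, per dataset *mode* (chromatographic separation RP or
HILIC crossed with electrospray polarity pos or neg):

* analytical **samples** — two conditions (control, treated) over a time
  course with biological replicates,
* **blanks** — injections without biological material, used to flag
  background features,
* **pooled QC** injections — a mixture of all samples, measuring technical
  stability per feature,
* two **internal standards** (ethylparaben and nitrotyrosine analogues)
  spiked at a constant level into every injection.

The emulated design is 2 conditions x 6 time points (0, 1, 3, 6, 12, 24 h)
x 3 biological replicates = 36 analytical samples, plus 6 blanks and 8
pooled-QC injections per mode, in four modes.

## QC chain

Filters run in a fixed order; the filter report reconciles exactly
(input = removed + retained at every stage, each removed feature carries
its reason).

1. **Noise threshold.** A feature is removed when its maximum peak area
   across analytical samples falls strictly below a per-mode threshold.
   Defaults: RP_pos 100,000; RP_neg 20,000; HILIC_pos 150,000; HILIC_neg
   50,000 — instrument- and mode-dependent values appropriate for the
   emulated acquisition; a feature exactly at the threshold is retained.
2. **Blank-ratio filter.** Per feature, the *median* blank intensity must
   not exceed 20 % of the sample intensity in at least 30 of the 36
   analytical samples; the comparison is inclusive (a blank median exactly
   at 20 % of a sample's area counts as a pass for that sample). For other
   sample counts the 30/36 rule generalizes to ceil(5/6 x n). Features
   failing the rule are treated as chemical noise / background.
3. **Internal-standard gate.** The RSD (sample standard deviation over
   mean) of each internal standard across all analytical samples must be
   strictly below 20 %. This is a *dataset-level* gate: a failing mode is
   disqualified from differential analysis entirely rather than having
   features dropped. The gate is evaluated on the unfiltered table, because
   the standards are spiked into blanks too and would always fail the blank
   rule themselves.
4. **Pooled-QC stability filter.** Features are retained only when their
   RSD across pool injections is strictly below 25 %.
5. **Cell-number normalization.** Each sample column is divided by the
   mean viable cell number of its (condition, time) group, converting peak
   areas to area-per-cell. Treated cells arrest and die during the exposure
   while controls keep growing, so unnormalized areas confound treatment
   effect with cell loss; normalization removes exactly this confound.
   Blank and pool columns keep raw areas — they serve QC only. TIC and
   housekeeping-metabolite normalizations are provided as alternatives
   (`normalize_alternative()`), but cell-number normalization is the
   default method of the pipeline.

Inclusive versus strict comparisons follow the wording of the rules the
package implements ("not allowed to exceed" versus "less than"); boundary
behaviour is pinned by tests at exact floating-point constructions. Zero
intensities take part in RSD and blank comparisons as true zeros; nothing
is imputed.

## Differential statistics

Intensities are log2-transformed before model fitting; zeros are replaced
by a configurable pseudo-area (default: half the smallest nonzero value in
the table). Testing is a pairwise control-versus-treated contrast *per
time point*, not a global time-course model:

* per feature, group means and the pooled residual variance s² on
  d = n₁ + n₂ − 2 degrees of freedom;
* across features, empirical-Bayes moment matching of the s² distribution
  to a scaled F yields the prior degrees of freedom d₀ and prior variance
  s₀² (digamma/trigamma method, with a Newton inversion of the trigamma
  function). When the between-feature variance of log s² does not exceed
  trigamma(d/2), d₀ = ∞ and s₀² is the mean of the variances;
* the posterior variance is s²~post~ = (d₀ s₀² + d s²)/(d₀ + d), the
  moderated t is the mean difference over s~post~ √(1/n₁ + 1/n₂) on
  d₀ + d degrees of freedom, two-sided;
* Benjamini–Hochberg step-up adjustment across features gives q-values.

`count_significant()` counts features with q < α per time point; α = 0.05
by default. The threshold is applied to the *adjusted* q-value (a raw-p
variant is available via `on = "p"`), since the correction would be
pointless otherwise. With the default ramped-effect simulation the counts
are zero through 6 h and grow through 12 and 24 h, the signature of a
toxicity time course in which regulation appears only at later time
points.

Limits d₀ = 0 (classical pooled t) and d₀ = ∞ (common variance) are exact
special cases and are pinned by tests; the finite-d₀ estimator is verified
against an independent numerical solve of the moment equations and against
the reference empirical-Bayes implementation in the `limma` package.

## PCA and cross-validated Q²

`fit_pca()` extracts components one at a time with NIPALS and deflation on
the mean-centred (default unit-variance scaled; Pareto available) matrix.
Convergence uses the relative change of the score vector at 1e−12 of its
squared norm (up to 10,000 iterations), which keeps scores and loadings
within ~1e−9 of a singular-value decomposition even when neighbouring
eigenvalues are close. R² per component is the explained fraction of the
preprocessed matrix's total sum of squares.

`q2_crossval()` estimates predictive performance: rows are assigned to
folds (default 7) round-robin after a seeded shuffle; for each component
the held-out rows are predicted from loadings fitted on the remaining
rows, giving PRESS_a, and Q²_a = 1 − PRESS_a/SS_(a−1), cumulated as
Q²cum = 1 − Π PRESS_a/SS_(a−1). This row-prediction scheme is simple and
deterministic; the cross-validation internals of commercial chemometrics
software are unpublished, so numerical equality with values produced by
such tools is not expected — the package's Q² is used comparatively
(structure versus noise). Under pure noise the scheme has a small positive
bias of roughly one part per column per component, hence null Q²cum stays
near zero for feature-rich matrices; strong two-group structure drives it
well above 0.3.

Fold-change heat maps order metabolites by agglomerative clustering of
their log2 fold-change trajectories (`cluster_metabolites()`; Euclidean
distance, average linkage by default — the conventional choice where none
is prescribed).

Outlier injections are never excluded automatically; a manual
`exclude_injections` list in the pipeline configuration removes named
injections before PCA only.

## Cross-mode matching and annotation

Features from different modes are compared by neutral mass, assuming
protonation/deprotonation only ([M+H]⁺ / [M−H]⁻, proton mass 1.00728 u);
masses agreeing within ±5 ppm are grouped transitively, and per-region
counts over the mode combinations summarize the overlap (Venn regions).

Annotation searches feature neutral masses against a user-supplied
compound table at ±5 ppm and assigns identification confidence:

| level    | evidence                                             |
|----------|------------------------------------------------------|
| 1        | reference substance: retention time **and** MS² match |
| 1a       | reference substance: retention time only             |
| 2        | MS² match against a database (or reference) spectrum without a reference RT match |
| putative | exact mass only                                      |

Precedence is 1 > 1a > 2 > putative. Two combinations are not covered
verbatim by that scheme and are resolved as design choices: a reference
MS² match without a reference RT match counts as spectral (level 2)
evidence, and a database MS² match in the presence of a reference RT match
does not upgrade 1a to 1 (level 1 requires the reference spectrum).
MS² similarity is a normalized dot product with square-root intensity
weighting over greedily nearest-paired peaks; a score ≥ 0.7 counts as a
match (no published cutoff exists; 0.7 is a common working value).
The reference RT tolerance defaults to ±0.3 min (18 s). Ambiguous mass
matches (several compounds within tolerance) are all reported, ranked by
|ppm|, and flagged.

## Companion-assay calculators

* **Dissolution stoichiometry**: the maximal ion release from complete
  dissolution of a metal compound is the compound concentration times the
  element's mass fraction (CuO → 79.9 % Cu, so 10 µg/ml CuO can release at
  most ≈ 8 µg/ml Cu²⁺; conversely ≈ 21.46 µg/ml CuCl₂·2H₂O delivers
  8 µg/ml Cu). Atomic masses are conventional IUPAC weights at 4–5
  significant figures.
* **Glutathione redox ratio**: the luminescence assay detects oxidized
  glutathione as two moles of GSH per mole of GSSG, so
  GSSG = (GSSG-well readout)/2, reduced GSH = total − readout, and the
  redox ratio is reduced/oxidized (∞ when no GSSG is detected, which is
  reported as such).
* **Efficiency-corrected qPCR**: relative expression is
  E_target^ΔCt(target) / E_ref^ΔCt(ref) with ΔCt = Ct(control) −
  Ct(treated) and amplification efficiencies in (1, 2].

## The synthetic-data generator

`simulate_study()` emulates the study design so the whole pipeline is
testable without external data:

* baseline feature abundances are log-normal (log₁₀ mean 6, sd 0.8), so
  the default noise thresholds bite realistically;
* treatment effects ramp linearly in log2 space from an onset hour
  (default 6 h) to a maximum log2 fold change (default 2) at the last time
  point, for a configurable fraction of features (default 10 %) — the
  time-course pattern in which differential regulation appears late and
  keeps growing;
* viable cells: controls double every 24 h; treated cells arrest at 6 h
  and then decline exponentially (5 %/h). Raw sample areas scale with the
  relative cell number, so the generator reproduces the confound that
  cell-number normalization exists to remove;
* **technical noise** (`noise_cv`, default 0.1) is multiplicative
  log-normal with unit expectation, applied to every feature in every
  injection — including internal standards, blanks and pools, whose RSDs
  measure precisely this noise. **Biological variability** (`bio_cv`,
  default 0.2) applies per biological sample to biological features only.
  The split matters: the internal standards are spiked per injection, so
  a 20 % *total* CV applied to them would park their RSD exactly at the
  20 % gate and make the default study unanalysable, which is not how a
  competently run study behaves. Defaults of 10 % technical and 20 %
  biological CV are typical of cell-culture untargeted metabolomics;
* blanks are zero except for a configurable fraction (default 10 %) of
  background features whose blank median is 50 % of the sample level,
  violating the blank rule by construction; pools are the exact mean
  sample composition plus technical noise; two internal standards are
  spiked at a constant nominal level (5e6) into every injection;
* identical seeds give bit-identical output.

What the generator does **not** emulate: retention-time drift, batch
effects, missing values (sub-threshold intensities are zeros, never
absent), correlated features (metabolites from shared pathways), isotopes
and adducts of the same metabolite, and heavier-tailed biological
variation. Passing tests therefore demonstrate that the implementation
honours its stated rules and statistical guarantees under a clean,
known-truth model — not that any particular real dataset will show the
same power or error rates.

## Numerical and design choices

* Filter thresholds are compared exactly as specified (inclusive blank
  ratio, strict RSD gates); tests pin these boundaries with values that
  are exact in floating point.
* The trigamma inversion falls back to d₀ = ∞ when there is no excess
  variability (and errors if every feature has zero variance).
* NIPALS starts from the column with the largest sum of squares; sign
  indeterminacy of components is accepted and all comparisons in tests are
  up to column sign.
* Ties in annotation are reported, not resolved.
* Problem sizes used by the test-suite and acceptance computations —
  hundreds to a thousand features, 200 replicate simulations for the
  false-discovery estimate, 100 replicates for the null Q² — were chosen
  as the smallest sizes at which the measured statistical properties are
  stable across seeds.

## Known limitations

* The pipeline assumes one feature table per mode with consistent
  injection ids across metadata and counts; it does not align features
  across modes beyond exact-mass matching.
* Q² values are scheme-dependent and not comparable across software.
* The IS gate halts a dataset; no rescue (e.g. drift correction from
  pools) is attempted — drift correction is deliberately out of scope.
* Annotation assumes single protonation/deprotonation; other adducts can
  be added to the adduct table but are not searched by default.
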
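---
title: "Methods: matched case-case serum NMR metabolomics"
author: "matchedMetabo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched case-case serum NMR metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchedMetabo)
```

# The analytical problem

Mammographic breast density (MBD) is a strong risk factor for breast
cancer. A matched case-case design compares two series of breast-cancer
cases — women with low MBD and women with high MBD at a pre-diagnostic
mammographic examination — using serum drawn years before diagnosis. Each
low-MBD case is matched 1:1 to a high-MBD case on age at cohort entry
(within 5 years), the type and purpose of the mammographic examination
and its era. Two kinds of data per subject enter the analysis:

* a **quantified panel**: metabolites, lipid main fractions and
  lipoprotein subfractions with per-feature limits of quantification
  (LOQ), and
* three **1D ^1^H NMR spectra** (NOESY-type, detecting everything;
  CPMG-type, selecting low-molecular-weight metabolites; diffusion-edited,
  selecting lipoprotein envelopes) on a common ppm axis.

The package implements the complete chain from these inputs to
conditional-logistic odds ratios per SD, FDR-controlled association
tables, OPLS-DA fingerprint classification with Monte Carlo
cross-validation, and topology-weighted pathway impact — together with a
synthetic-cohort generator that makes every stage testable without any
cohort data.

# Quantified-panel preparation

Values below the LOQ are left-censored instrument readings. Preparation
follows three steps (`preparePanel()`):

1. **Half-LOQ imputation** (`loqImpute()`): every flagged cell becomes
   `loq/2`. The rule is idempotent and touches only flagged cells.
2. **Below-LOQ exclusion** (`loqFilter()`): a feature is dropped iff its
   below-LOQ fraction *strictly exceeds* 20% (a feature at exactly 20% is
   retained). The rule is applied uniformly to all feature families; a
   `families` argument restores a metabolites-only reading.
3. **Log transform and per-SD scaling** (`logSdScale()`): each feature is
   mapped to `(ln x − mean)/SD` with the mean and *sample* SD (n−1
   denominator) pooled over all subjects — not within group or within
   pair — so that a one-unit difference is one SD of log-concentration,
   the scale on which odds ratios per SD are reported. The natural log is
   used; after SD scaling the OR per SD is invariant to the log base, so
   the choice is cosmetic and recorded only for reproducibility. Scaling
   is affine-equivariant: multiplying a raw feature by a positive
   constant leaves the standardized column unchanged.

# Matched association models

For 1:1 matched sets, conditional logistic regression conditions the
likelihood on pair membership, eliminating all pair-constant nuisance
terms. The conditional likelihood reduces to an intercept-free logistic
regression on within-pair differences (high-MBD member minus low-MBD
member) with all responses equal to one:

$$\ell(\beta) = \sum_{i=1}^{n} \log \frac{e^{\beta^\top \Delta x_i}}{1 + e^{\beta^\top \Delta x_i}}.$$

`fitConditionalLogit()` maximizes this by Newton-Raphson on the observed
information, to gradient sup-norm below `1e-8` with at most 50
iterations; steps larger than 5 in sup-norm are damped. Monotone
likelihood (separation) is detected when any coefficient passes 15 in
absolute value and flagged rather than reported as converged. The
covariance is the inverse observed information, and 95% confidence
intervals are Wald intervals `exp(beta ± 1.959964·SE)`. On a single
binary covariate the estimate equals the classical discordant-pair ratio
exactly, which the test suite exploits as a closed-form oracle (and
cross-checks against `survival::clogit` on continuous designs).

`runFeaturePanel()` fits one model per retained feature. Matching
variables never enter as covariates — they are pair-constant and the
conditioning removes them. The adjusted model differences the confounder
set (age at diagnosis, parity, breastfeeding, menopausal status, ER
status, BMI class) alongside the feature; pairs with a missing covariate
in either member are dropped for that model (complete-pair analysis, the
convention of standard conditional-logistic software) and the used pair
count is reported. BMI class is coded as a single ordinal integer over
the WHO categories (<25, 25–29.9, ≥30) — the most parsimonious reading of
"body mass index class". A feature whose within-pair differences are all
zero is degenerate: it is reported with OR 1, an infinite CI, and is
excluded from the FDR family.

Benjamini-Hochberg adjustment (`bhFdr()`, step-up with
cumulative-minimum monotonization at α = 0.05) is applied **within each
feature family** by default, mirroring how association tables print one
FDR column per table; `fdrScope = "global"` pools all features into a
single family instead. The family choice is a genuine ambiguity; both
modes are provided and the per-table default is the more conservative
match to printed layouts.

# Baseline descriptives

`buildTableOne()` assembles group summaries with three tests, chosen per
variable: the **pooled-variance Student t** (not Welch — the pooled form
is what reproduces p-values recomputable from printed means and SDs; a
`welch` flag is available), the **Wilcoxon rank-sum** (exact enumeration
for small untied samples, otherwise the tie-corrected
continuity-corrected normal approximation), and the **Pearson
chi-squared without continuity correction** (Yates' correction would not
reproduce printed 2×2 p-values, e.g. it turns 0.04 into ≈0.06). Missing
values are excluded pairwise per variable and the effective n reported.

# Spectral fingerprint analysis

**Bucketing** (`bucketSpectra()`): bins are defined by left edges
`0.20 + k·0.02` ppm for `k = 0..490` inclusive — 491 bins, the last
covering 10.00–10.02 ppm. Each bin value is the exact integral of the
piecewise-linear spectrum over the bin (in ppm units). The edge
convention matters: with the water region 4.40–5.12 ppm removed by
dropping every bin whose left edge lies in [4.40, 5.10] (36 bins),
exactly **455 bins** remain; the naive half-open reading of the same
ranges would give 454. The convention is fixed to reproduce the 455-bin
dimensionality and both window and width are configurable.

**Normalization** (`normalizeTotalIntegral()`): each subject's bin vector
is divided by its own total area, removing dilution and gain
differences; rows then sum to one and the result is invariant to global
per-subject intensity scaling. No Pareto or unit-variance scaling is
applied before modeling — a minimal-intervention choice, since only
normalization is part of the stated protocol.

**PCA screening** (`pcaScreen()`): mean-centered PCA with Hotelling
T² outlier flags at the 97.5% quantile of the
$k(n-1)/(n-k)\,F_{k,n-k}$ reference distribution. Note that by
construction ≈2.5% of clean subjects exceed this threshold; "no
outliers" in practice means the flagged share stays at the nominal level
and no subject stands far above it, which is how the tests phrase it.

**OPLS-DA** (`oplsdaFit()`): classes are coded −1/+1 and columns centered
with training means. The predictive weight is $w \propto X^\top y$; each
orthogonal component orthogonalizes the current loading against $w$
($w_o \propto p - (w^\top p)w$) and deflates $X$ by the resulting
score/loading pair; the predictive component is fit on the fully
deflated matrix. Predictive scores are exactly orthogonal to every
orthogonal score (an enforced class invariant), and with zero orthogonal
components the model coincides with single-component PLS-DA, which the
tests verify against a direct SVD-based oracle. Published latent-variable
counts (CPMG 7, NOESY 9, diffusion 6) are interpreted as **total**
components — one predictive plus n−1 orthogonal — since single-response
OPLS-DA has exactly one predictive component; a configuration switch
(`latent_interpretation`) restores the "n orthogonal" reading.

**Validation** (`mccv()`, `permutationTest()`): 100 cycles of Monte Carlo
cross-validation with stratified random 90/10 splits; accuracy,
sensitivity and specificity (high-MBD positive) are averaged over
cycles. Splits are drawn at the subject level and ignore the pair
structure, matching a subject-level 90/10 description; mean and median
accuracy are both reported because the summary statistic is not uniquely
determined. The permutation test recomputes the mean MCCV accuracy under
random relabeling and uses the add-one estimator
$p = (1 + \#\{null \ge obs\})/(B+1)$, so the attainable minimum with 100
permutations is 1/101 and p can never be exactly zero.

# Pathway topology impact

Significant metabolites (lipid fractions are excluded by family — they
have no direct compound match) are mapped into a pathway library of
compound sets with undirected topology. Per pathway:

* **enrichment**: upper-tail hypergeometric p-value for the hit count,
  drawing the mapped input from the library-wide compound universe (the
  default reference scope; configurable in principle, and the backend a
  hypergeometric test, numerically identical to one-sided Fisher);
* **Holm and BH adjustment** across pathways;
* **impact**: the hit share of relative betweenness centrality, computed
  on the undirected unit-weight pathway graph normalized by
  $(n-1)(n-2)/2$, falling back to degree centrality when every
  betweenness is zero (tiny graphs) and to the node share when there are
  no edges. Impact is always in [0, 1], and pathways with impact
  strictly above 0.2 are flagged as "considered".

The package ships a small **synthetic** JSON library (17 pathways): a
4-compound aromatic-amino-acid pathway containing tyrosine at an
interior (high-betweenness) position, a 22-compound pyruvate hub
containing pyruvate, lactate and acetate, and 15 decoys whose hits sit
at leaves, so exactly two pathways clear the 0.2 impact bar. Compound
sets and edges are fixture constants, not a curated database: real KEGG
content is version-dependent and non-redistributable, and the algorithms,
not the database, are the package's contribution.

# The synthetic-cohort generator

`generateCohort()` is a pure function of its `generatorSpec()`: a fixed
draw order (pair matching variables → member BMI → latent lipoprotein
factors → feature z-scores → label assignment → member covariates →
spectral noise) makes a given spec byte-reproducible, and the caller's
RNG stream is left untouched.

**The conditional-logistic structure is generative.** Standardized
log-concentrations for both pair members are drawn first; the high-MBD
label is then assigned to member 1 with probability
$\operatorname{plogis}(\beta^\top \Delta z)$ given the standardized
within-pair differences. This makes the conditional-logistic coefficient
the literal generative parameter, so recovery tests have an exact truth:
with a single effect of ln 2 at 500 pairs the crude estimate recovers
the truth with bias well below 0.05.

**Confounding is injected through BMI.** The member's standardized BMI
enters both the label probability (coefficient −1.1: leaner women tend
to be the dense-breast member) and the mean log-concentration of lipid
features (loading 0.5 on triglyceride-rich VLDL features, smaller or
negative elsewhere). Lipid features therefore acquire crude associations
without any direct effect, which shrink once BMI class is adjusted for —
the crude-vs-adjusted divergence characteristic of matched observational
panels. Recovery and type-I-error checks set the BMI-to-label
coefficient to zero (`nullGeneratorSpec()`), because those properties
are statements about the pure conditional-logistic process.

**Panel layout.** The default catalogue has 21 metabolites — the 15
analyzed ones plus 6 low-abundance compounds censored at a target 35%
below-LOQ fraction — 7 lipid main fractions and 95 lipoprotein
subfractions (19 particle classes × 5 constituents). The >20% exclusion
rule therefore removes exactly 6 features, reproducing the 15/7/95
analyzed layout end to end. Default per-feature effects place six
inverse and one direct (acetic acid) metabolite associations, the
pattern the matched analysis is designed to flag; subfractions share a
low-rank latent structure per particle class (loading share 0.6), a
structure chosen for plausibility without claiming fidelity to any real
covariance. LOQs are set as empirical quantiles realizing the target
censoring fractions exactly.

**Spectra.** Each feature contributes Lorentzian peaks
$A\,hw/((\delta-c)^2+hw^2)$ (integral $A\pi$ per unit concentration)
from a bundled synthetic peak library of literature-plausible positions;
half-widths below 0.03 ppm mark narrow metabolite resonances. Experiment
types are emulated by attenuation: CPMG passes narrow peaks and damps
broad ones 20-fold, diffusion editing does the reverse, NOESY passes
both. A residual-water hump is confined to the open interval
(4.40, 5.12) ppm so that bins bordering the window integrate to exactly
zero, white noise (SD 0.5 intensity units) is added and intensities are
truncated at zero. The default grid spans 10.2–0 ppm in 0.002 ppm steps.
The generator does **not** emulate J-coupling multiplets, peak-position
drift, baseline distortion or field-strength effects — so passing
fingerprint tests demonstrate the correctness of the bucketing, O-PLS
algebra and validation machinery, not classifier performance on real
serum spectra; published accuracies (≈61–63%) require the real data and
are deliberately not a target.

# Problem sizes and numerical choices

Tests run the generator at 2–150 pairs and the full default series at
87 pairs; the acceptance script uses 100 replicates of 500 pairs for
recovery, 10⁴ features for the null calibration, 100 MCCV cycles and 100
permutations — sizes chosen so the whole suite completes in a few
minutes on one core while keeping Monte Carlo error far below every
asserted tolerance. Newton-Raphson tolerance is 1e-8 on the gradient
sup-norm; orthogonality is asserted at 1e-8 relative; bucket/water
arithmetic uses a 1e-9 edge tolerance to absorb floating-point drift in
ppm grids.

Two subtle behaviours are worth recording. First, MCCV with *duplicated*
subjects in both classes is not a "coin-flip" fixture: exact duplicates
make $X^\top y$ exactly zero (a degenerate weight, rejected by design),
and near-duplicates are memorized — the held-out subject matches a
training row of the opposite class and accuracy falls *below* chance.
The indistinguishable-classes check therefore uses i.i.d.
same-distribution classes. Second, monotonicity of MCCV accuracy in the
generator effect size is tested on the standardized panel matrix with
three cohort replicates averaged per grid point: raw-spectra OPLS-DA
accuracy saturates quickly and single-cohort sampling noise would break
strict five-point monotonicity regardless of implementation correctness.

# Limitations

* The generator's covariate model reproduces marginal group contrasts,
  not the joint dependence structure of real reproductive histories.
* Pathway enrichment values depend entirely on the bundled synthetic
  library's universe; only the hit/compound arithmetic and the impact
  algebra are meaningful beyond it.
* Conditional logistic regression is implemented for 1:1 sets only;
  general n:m strata are out of scope.
* Half-LOQ is the only imputation rule provided, by design.
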
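# matchedMetabo

Analysis toolkit for **1:1 matched case–case serum NMR metabolomics**
studies — the design that compares pre-diagnostic metabolomic profiles
between breast-cancer cases who had *high* versus *low* mammographic
breast density (MBD), each low-MBD case matched to a high-MBD case on
age at cohort entry (±5 years) and the characteristics of the
mammographic examination.

It is aimed at epidemiologists and metabolomics analysts who need the
full chain from raw quantification tables and 1D ^1^H NMR spectra to
publishable association and classification results, with every stage
unit-tested against independent oracles and a synthetic-cohort generator
standing in for restricted cohort data.

## What it computes

**Matched association.** For 1:1 matched sets the conditional logistic
likelihood reduces to an intercept-free logistic regression on
within-pair covariate differences:

$$\ell(\beta) = \sum_i \log\frac{e^{\beta^\top \Delta x_i}}{1+e^{\beta^\top \Delta x_i}},
\qquad \Delta x_i = x_i^{\text{high}} - x_i^{\text{low}},$$

maximized by Newton–Raphson with separation detection. Each feature
(log-transformed, standardized to unit SD over all subjects) is modeled
separately, crude and adjusted for the MBD-related confounders (age at
diagnosis, parity, breastfeeding, menopausal status, ER status, BMI
class), with Wald 95% CIs and Benjamini–Hochberg FDR control at
α = 0.05. Panels are prepared with half-LOQ imputation and exclusion of
features with more than 20% of observations below the limit of
quantification.

**Spectral fingerprint.** Spectra in 0.2–10.0 ppm are integrated into
0.02 ppm buckets (491 bins; removing the 4.40–5.12 ppm residual-water
window leaves exactly **455 bins**), total-integral normalized, screened
by PCA with Hotelling T² outlier flags, and classified by OPLS-DA (one
predictive plus k orthogonal components) validated with 100 cycles of
stratified 90/10 Monte Carlo cross-validation and a 100-permutation
test.

**Pathway topology.** Significant metabolites are mapped into a pathway
library; per pathway the package reports the hypergeometric enrichment
p-value, Holm and FDR adjustments, and the *impact* — the hit share of
relative betweenness centrality — flagging pathways with impact > 0.2.

**Baseline table.** Group summaries with pooled-variance t,
Wilcoxon rank-sum and uncorrected Pearson chi-squared tests.

**Synthetic cohorts.** `generateCohort()` draws matched pairs in which
the conditional-logistic coefficient is the *literal* generative
parameter, with BMI acting as a genuine confounder of lipid features,
LOQ censoring at exact target fractions, and three spectra per subject
synthesized from Lorentzian peak libraries with experiment-type
filtering.

## Worked example

```r
library(matchedMetabo)

sc   <- generateCohort(generatorSpec(nPairs = 87, seed = 1))
quantPanel(sc)
#> QuantPanel: 123 features x 174 subjects
#>   metabolites: 21 | lipid main fractions: 7 | subfractions: 95
#>   below-LOQ cells: 411

prep <- preparePanel(quantPanel(sc))
prep
#> PreparedPanel: 117 retained features x 174 subjects
#>   excluded (> 20% below LOQ): 6

crude    <- runFeaturePanel(prep, cohortTable(sc), model = "crude")
adjusted <- runFeaturePanel(prep, cohortTable(sc), model = "adjusted")
head(crude[order(crude$p_value),
           c("feature", "or_", "ci_low", "ci_high", "p_value", "p_fdr")], 5)
#>                 feature   or_ ci_low ci_high p_value p_fdr
#>     vldl5_phospholipids 0.589  0.415   0.836   0.003 0.212
#>       vldl3_cholesterol 0.635  0.456   0.885   0.007 0.212
#>      ldl6_triglycerides 0.613  0.426   0.881   0.008 0.212
#>  vldl2_free_cholesterol 0.641  0.456   0.902   0.011 0.212
#>     vldl4_phospholipids 0.654  0.466   0.918   0.014 0.212
sum(crude$p_value < 0.05, na.rm = TRUE)      # 16 features at raw p < 0.05
sum(adjusted$fdr_rejected)                   # 0 survive FDR
```

Sixteen features reach raw significance in the crude matched models
(odds ratios per SD below 1: higher pre-diagnostic levels in the
*low*-MBD member of the pair, the direction the BMI-confounded lipid
path produces), and none survives FDR correction in adjusted models — a
small-sample pattern the generator is designed to reproduce.

```r
bn <- normalizeTotalIntegral(removeWater(bucketSpectra(spectrumSets(sc)$cpmg)))
bn
#> BinnedMatrix [cpmg]: 174 subjects x 455 bins (total-integral normalized)
mccv(binValues(bn), cohortTable(sc)$group, nOrthogonal = 6,
     nCycles = 100, seed = 42)
#> MccvResult: 100 cycles | accuracy 0.532 | sensitivity 0.538 | specificity 0.527

runPathwayAnalysis(c("alanine", "leucine", "tyrosine", "valine",
                     "lactic_acid", "pyruvic_acid", "acetic_acid"))[1:2, ]
# 17 pathways detected; the 4-compound tyrosine-containing pathway
# (1 hit, impact 0.5) and the 22-compound pyruvate hub (3 hits,
# impact 1.0) are the two with impact > 0.2
```

The whole chain runs as one call with `runPipeline(list(seed = 1))`,
which writes `table1.csv`, `assoc_crude.csv`, `assoc_adjusted.csv`,
`fp_{noesy,cpmg,diffusion}.json`, `pathways.csv`, `run.log` and a
manifest, and `makeReport()` condenses them into a markdown summary.

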
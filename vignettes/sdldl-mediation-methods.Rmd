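---
title: "Methods: screening sdLDL-mediated LDL-C-transcriptome associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening sdLDL-mediated LDL-C-transcriptome associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the estimand

Elevated LDL-cholesterol (LDL-C) is the canonical modifiable driver of
atherosclerotic cardiovascular risk, but LDL particles are heterogeneous:
small dense LDL (sdLDL, diameter < 25.5 nm) is the subclass most strongly
implicated in atherogenesis. When whole-blood gene expression associates
with plasma LDL-C, a natural question is how much of that association is
carried by sdLDL. This package implements a deterministic, regression-based
screen for that question on bulk RNA-seq count data:

1. the gene-LDL-C association must be significant (BH-FDR <= 0.05),
2. the gene-sdLDL association must be significant (BH-FDR <= 0.05),
   with the two log fold changes in the same direction, and
3. the LDL-C log fold change must shrink in absolute value when sdLDL
   enters the model as a covariate.

For genes passing all three conditions the *proportion mediated* is

$$\mathrm{PM} = 100 \times \left(1 - \frac{\mathrm{logFC}_{\mathrm{adj}}}{\mathrm{logFC}_{\mathrm{base}}}\right),$$

clamped to [0, 100]: an adjusted logFC that overshoots zero is complete
mediation, one that grows is no attenuation. The clamp and the formula are
a design choice — the screen is a Baron-Kenny-style attenuation argument on
GLM coefficients, not a counterfactual mediation estimand; no bootstrap or
Sobel inference is attached because the screen is deterministic given the
three fits.

## Differential expression engine

Associations are tested with a tertile-extremes design: samples at or below
the empirical 1/3 quantile (linear-interpolation definition, ties to the
lower bin for determinism) form the `low` group, samples strictly above the
2/3 quantile the `high` group, and the middle third is excluded. Extreme
groups sharpen contrast and power in a heterogeneous cohort at the cost of
a third of the samples.

Per gene we fit a negative binomial GLM with log link, log effective
library sizes as offsets, and covariates age (standardized), sex, and
education (five levels with `not_available` kept as its own dummy so
samples with unreported education are retained; reference re-chosen
automatically if a level is absent). Fitting is iteratively reweighted
least squares with working weights $\mu/(1+\phi\mu)$, convergence at a
relative deviance change below 1e-8 or 100 iterations; dispersion 0
degrades to Poisson. The group coefficient is tested by likelihood ratio
against the model without it, $\chi^2_1$; logFC is reported in log2.

Dispersions maximize the Cox-Reid adjusted profile likelihood (penalizing
the log-determinant of the weighted information to correct for estimating
the mean coefficients) over log10 dispersion in [-6, 1] by bounded scalar
search, then shrink on the log scale toward a running-median
mean-dispersion trend with a prior weight of 10 degrees of freedom against
the gene's residual degrees of freedom. This is deliberately "edgeR-like
behavior without being edgeR": the test suite checks rank agreement with
edgeR's NB LRT on shared contrasts rather than numerical identity, and the
engine's own calibration is verified directly (all-null cohorts give a
p < 0.05 fraction of ~0.05 and pass a Kolmogorov-Smirnov uniformity
check).

Normalization is trimmed-mean-of-M-values (TMM) with the canonical trims
(30% on M, 5% on A), delta-method precision weights, reference sample by
upper-quartile fraction closest to the mean (smallest index on ties), and
factors rescaled to geometric mean one. The low-expression filter (>= 1 CPM
in >= 3 samples, boundary inclusive) runs *before* TMM on raw library
sizes, mirroring the standard count-model workflow; the choice is
switchable by computing CPM with a normalization object.

In the adjusted (condition 3) fit, sdLDL enters as a *standardized
continuous* covariate — the plainest reading of "adding the mediator to the
model" — and the gene's dispersion from the base LDL-C fit is reused, so
the attenuation comparison reflects the mean model, not a re-estimated
variance model. The covariate default is age + sex + education for every
fit; a narrower age + sex set is a defensible alternative reading of the
screen's conditions, and the covariate list is a single configurable
argument throughout.

## Synthetic cohort generator

The study data are access-restricted, so every stage is exercised on a
synthetic cohort whose phenotype layer is calibrated to the cohort's
printed margins: LDL-C truncated-normal with mean 105 and SD 33 mg/dL; age
48/12 years; 69% female; education sampled at 6/15/17/20/42%, the last
level an explicit `not_available` category (42% of the cohort — dropping it
would halve the sample, so it is modeled, not imputed); 10% on
lipid-lowering medication (available as an optional covariate, not adjusted
for by default). sdLDL is linear in standardized LDL-C plus independent
normal noise, truncated at zero. Zero-truncation of a variable whose SD
(333) is a large fraction of its mean (477) removes ~8% of the mass and
would bias the correlation from 0.40 to ~0.36, so the *pre*-truncation
mean, SD and slope are solved numerically (quadrature over the LDL-C
standard normal plus Nelder-Mead) such that the *post*-truncation
population moments equal the targets; the acceptance suite verifies the
empirical correlation at n = 100,000 to within 0.01. The printed sdLDL
magnitudes are more consistent with NMR particle concentrations (nmol/L)
than with mg/dL; the generator treats the units as opaque assay units.

Counts are NB with
$\log \mu_{gi} = \log L_i + b_{0g} + \beta_{d,g} z(\mathrm{LDL}_i) + \beta_{m,g} z(\mathrm{sdLDL}_i) + \text{nuisance}$,
log-normal library sizes (median 2e6), gamma dispersions (mean 0.1), and
small per-gene age/sex nuisance coefficients so covariate adjustment is
exercised without dominating. Genes split into `null` (90% by default),
`direct_only` (4%), `mediated` (4%, direct path zero) and `mixed` (2%)
classes; effect magnitudes are log-normal around a typical size (0.20
natural-log units per phenotype SD for direct, 0.35 for mediated effects)
with random sign. Because the phenotypes are standardized, the ground-truth
proportion mediated has the closed form
$100\,\beta_m a / (\beta_d + \beta_m a)$ with $a$ the sdLDL-on-LDL-C slope
(equal to the configured correlation), verified in the tests against an
independent OLS decomposition at large n.

The generator does *not* emulate gene-gene correlation networks, sample or
gene outliers, batch structure, or sequencing artifacts; passing tests
therefore demonstrate the statistical machinery under a clean generative
model, not robustness to those real-data features.

### Recovery conditions used by the test suite

The acceptance-level simulations use 2,000 genes x 400 samples: large
enough for stable tertile DE and BH behavior, small enough for minutes on a
single core. The planted-mediation recovery runs use 100 pure-mediated
genes (5%) with strong effects (typical mediated magnitude 0.5, direct
0.3) across three seeds; the no-mediation null run uses the default cohort
with the mediator decoupled (`mediator_slope = 0`). Calibration checks on
the phenotype layer use n = 100,000.

## Sex-stratified screen

The pooled mediated genes are re-screened independently within the female
and male strata. Each stratum is treated as a new cohort: tertile cutpoints
and TMM factors are recomputed within the stratum (pooled cutpoints would
unbalance the stratum group sizes; the choice is switchable by passing
precomputed designs), sex leaves the covariate list, education dummies
collapse automatically where a stratum lacks levels, and BH runs within the
screened gene subset per stratum — matching a screen of a small
pre-identified panel rather than a fresh transcriptome-wide scan. Genes are
classified `both` / `female_only` / `male_only` / `neither`; the four
counts partition the screened set by construction, and swapping the strata
swaps the exclusive counts exactly.

## Enrichment

Over-representation of the mediated list is tested per gene set with the
upper-tail hypergeometric probability $P(X \ge k)$, universe defaulting to
all genes tested in the DE stage (standard over-representation practice;
configurable). Raw p-values with a 0.05 retention threshold and a minimum
overlap of 2 mirror how small mediated panels are usually reported; a BH
column is emitted for reference but not applied to retention. Gene sets
come from a user-supplied GMT file; no pathway-database retrieval is
performed.

## Numerical and degenerate-input choices

- IRLS: linear predictor clamped to [-30, 30]; all-zero genes flagged, not
  fitted; non-converged genes excluded from testing with a message and
  recorded on the result.
- Dispersion search tolerance 0.02 on log10 dispersion, warm-started
  across candidate values; genes with fewer positive counts than design
  columns take the trend value directly; constant genes land at the lower
  bound.
- TMM: samples with all-zero counts are an error naming the sample; fewer
  than 10 genes surviving trimming yields a factor of 1 with a warning.
- Tertiles: fewer than 2 distinct values, coincident cutpoints, or an
  empty extreme group are errors (degenerate phenotype).
- p-values are floored at the smallest positive double before BH.
- The screen requires identical gene universes for the two base contrasts;
  genes not testable in both are dropped with a message, and the adjusted
  table may lazily cover only the candidate genes.
- One user seed fans out to fixed per-stage seeds, so stage re-ordering
  does not shift the streams and any stage is reproducible in isolation.

## Known limitations

- *Attenuation leakage.* The tertile indicator coarsens LDL-C while the
  mediator covariate carries additional LDL-C information, so genes with a
  purely direct LDL-C effect show genuine systematic attenuation when the
  correlated mediator enters the model. The screen (faithfully) calls a
  fraction of such genes mediated; the recovery tests therefore assert
  sensitivity for planted mediated genes and near-zero calls among null
  genes, not perfect specificity against direct-only genes. Interpreting
  PM causally requires the usual no-unmeasured-confounding assumptions.
- Condition 3 uses strict attenuation with no minimum threshold; a single
  noisy fit can flip it near the boundary. A minimum-attenuation option
  exists but defaults off to keep the screen as stated.
- PM is a ratio of estimated coefficients; for base logFC near zero it is
  unstable, which the clamp bounds but does not remove.
- BH within the per-stratum gene subset makes stratum significance
  conditional on the pooled selection; this matches screening a fixed
  panel, not an independent discovery.
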
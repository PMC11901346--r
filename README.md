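# sdldlmed

Does small dense LDL (sdLDL) carry the association between LDL-cholesterol
(LDL-C) and whole-blood gene expression? `sdldlmed` is an R package plus a
numbered analysis workflow for lipidomics/transcriptomics researchers who
want to answer that question on bulk RNA-seq counts — and for
methodologists who want a fully synthetic, ground-truthed testbed for
attenuation-based mediation screens on count data.

The pipeline chains:

1. **Filtering & normalization** — genes kept at >= 1 CPM in >= 3 samples;
   trimmed-mean-of-M-values (TMM) scaling factors.
2. **Tertile-extremes differential expression** — per gene, a negative
   binomial GLM (log link, effective-library-size offsets, Cox–Reid
   dispersion with trend shrinkage) contrasting the upper vs lower tertile
   of the phenotype, likelihood-ratio tested (χ² with 1 df) and
   Benjamini–Hochberg corrected; covariates age, sex, education.
3. **Three-condition mediation screen** — a gene is *mediated* when the
   LDL-C and sdLDL associations are both significant (FDR ≤ 0.05) with
   sign-concordant logFC, and |logFC(LDL-C)| shrinks once sdLDL enters the
   model as a standardized covariate. The proportion mediated is
   PM = 100·(1 − logFC_adj / logFC_base), clamped to [0, 100].
4. **Sex-stratified screen** — the mediated panel re-screened within the
   female and male strata (tertiles and TMM recomputed per stratum) and
   classified `both` / `female_only` / `male_only` / `neither`.
5. **Hypergeometric enrichment** — upper-tail over-representation of the
   mediated panel in user-supplied GMT gene sets, universe = all tested
   genes.

Because the motivating cohort data are access-restricted, the package
ships a calibrated synthetic cohort generator (LDL-C ~ 105/33 mg/dL,
corr(LDL-C, sdLDL) = 0.4 after zero-truncation, 69% female, five-level
education with an explicit `not_available` category) that plants
direct-only, mediated and mixed effects with known per-gene ground truth —
including a closed-form true proportion mediated. A printed 33-mRNA
mediated-gene table is packaged as a fixture (`load_table2_fixture()`).

## Worked example

The numbered drivers under `analysis/` run the whole chain on the default
synthetic cohort (2,000 genes × 400 samples) and write tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_normalize.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_mediation.R
Rscript analysis/05_sex_stratified.R
Rscript analysis/06_enrichment.R
```

Stage 4 prints the screen's accounting funnel and its agreement with the
planted truth; a run with seed 20260919 prints:

```
accounting funnel:
        n_genes_tested    n_significant_trait n_significant_mediator
                  2000                    193                    186
             n_overlap           n_concordant             n_mediated
                   164                    154                    149

sensitivity for planted pure-mediated genes: 0.94
Spearman(estimated PM, true PM) on 149 calls: 0.92
```

Reading the funnel: of 2,000 genes, 193 associate with LDL-C and 186 with
sdLDL at FDR ≤ 0.05; 164 with both; 154 of those with concordant logFC
signs; 149 survive the attenuation condition and are called mediated. The
screen recovers 94% of the planted pure-mediated genes, and the estimated
proportion mediated tracks the ground truth (Spearman 0.92). Stage 5 then
classifies those 149 genes by sex (`119 both / 20 female_only /
10 male_only / 0 neither` on this run), and stage 6 retrieves the gene
sets spiked with mediated genes at the top of the enrichment table.

The same machinery is available programmatically:

```r
library(sdldlmed)
cfg <- sim_config(n_samples = 400, n_genes = 2000, seed = 1)
ph  <- simulate_phenotypes(cfg)
sim <- simulate_counts(ph, cfg)
res <- run_mediation_pipeline(sim$counts, ph)
res$summary
head(res$records[res$records$mediated, ])
```

or end to end with `run_full_pipeline(pipeline_config(...))`, which writes
every stage table, a stage-count summary, the effective configuration and
a log into a run directory.

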
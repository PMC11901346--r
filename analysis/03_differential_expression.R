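#!/usr/bin/env Rscript
# Stage 3 — tertile-extremes differential expression.
#
# Contrasts the upper vs lower tertile of each lipid phenotype with per-gene
# NB GLMs (LRT on the group coefficient), adjusted for age, sex and
# education, BH-corrected across genes.

library(sdldlmed)

phenotypes <- read_phenotypes("results/synthetic_cohort/phenotypes.csv")
filtered <- read_counts("results/normalization/counts_filtered.tsv")
outdir <- "results/differential_expression"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

norm <- compute_tmm_factors(filtered)
for (target in c("ldl_c", "sdldl")) {
  de <- lrt_de(filtered, phenotypes, target,
               covariates = c("age", "sex", "education"), norm = norm)
  write_result_table(as.data.frame(de),
                     file.path(outdir, paste0("de_", target, ".tsv")))
  n_sig <- sum(de$fdr_adjusted_p <= 0.05)
  cat(sprintf(
    "%s: %d/%d extreme-tertile samples; %d genes at FDR <= 0.05 (%d up, %d down)\n",
    target, attr(de, "n_low"), attr(de, "n_high") + attr(de, "n_low"), n_sig,
    sum(de$fdr_adjusted_p <= 0.05 & de$direction == "up"),
    sum(de$fdr_adjusted_p <= 0.05 & de$direction == "down")))
}
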
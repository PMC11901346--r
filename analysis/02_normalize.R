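#!/usr/bin/env Rscript
# Stage 2 — expression filter and TMM normalization.
#
# Drops genes below 1 CPM in at least 3 samples (raw library sizes), then
# computes TMM scaling factors and effective library sizes on the retained
# genes.

library(sdldlmed)

indir <- "results/synthetic_cohort"
outdir <- "results/normalization"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

counts <- read_counts(file.path(indir, "counts.tsv"))
filtered <- filter_low_expression(counts, min_cpm = 1, min_samples = 3)
norm <- compute_tmm_factors(filtered)

write_counts(filtered, file.path(outdir, "counts_filtered.tsv"))
write_result_table(
  data.frame(sample_id = names(norm$tmm_factor),
             library_size = as.integer(norm$library_size),
             tmm_factor = as.numeric(norm$tmm_factor),
             effective_library_size = as.numeric(norm$effective_library_size)),
  file.path(outdir, "tmm_factors.tsv"))

cat(sprintf("filter: %d of %d genes retained\n", nrow(filtered), nrow(counts)))
cat(sprintf("TMM factors in [%.3f, %.3f], reference sample %s\n",
            min(norm$tmm_factor), max(norm$tmm_factor),
            norm$reference_sample))
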
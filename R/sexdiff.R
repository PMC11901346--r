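#' Four-way overlap classification of stratified mediation calls
#'
#' @param female_records,male_records screen tables from
#'   [screen_mediation()] (or any data.frames with `gene_id` and `mediated`
#'   columns) over the same gene set.
#' @return list: `classification` data.frame (`gene_id`, `mediated_female`,
#'   `mediated_male`, `classification` in
#'   `both`/`female_only`/`male_only`/`neither`) and `summary` counts per
#'   class (these partition the gene set).
#' @export
classify_overlap <- function(female_records, male_records) {
  if (!setequal(female_records$gene_id, male_records$gene_id))
    stop("female and male record tables cover different gene sets")
  m <- male_records[match(female_records$gene_id, male_records$gene_id), ]
  f_med <- female_records$mediated
  m_med <- m$mediated
  cls <- ifelse(f_med & m_med, "both",
                ifelse(f_med, "female_only",
                       ifelse(m_med, "male_only", "neither")))
  cls <- factor(cls, levels = c("both", "female_only", "male_only", "neither"))
  list(
    classification = data.frame(
      gene_id = female_records$gene_id,
      mediated_female = f_med, mediated_male = m_med,
      classification = cls, stringsAsFactors = FALSE
    ),
    summary = table(cls)
  )
}

#' Sex-stratified mediation screen
#'
#' Re-runs the three-condition mediation screen independently within the
#' female and the male stratum, over a pre-identified gene subset (typically
#' the genes called mediated on the full cohort). Each stratum is treated as
#' a cohort of its own: tertile cutpoints and TMM factors are recomputed
#' within the stratum, sex is removed from the covariates, and BH adjustment
#' runs within the gene subset per stratum. Genes are then classified as
#' mediated in both strata, females only, males only, or neither.
#'
#' @param counts raw gene x sample count matrix (all genes; normalization
#'   uses the stratum's full filtered matrix).
#' @param phenotypes matching phenotype table with a `sex` column.
#' @param gene_subset gene ids to screen (empty input returns an empty
#'   result).
#' @param covariates covariates excluding sex (default age + education).
#' @param target,mediator,alpha,min_cpm,min_samples as in
#'   [run_mediation_pipeline()].
#' @return a `sex_stratified_result` list: `classification`, `summary`
#'   (counts per class), and the per-stratum screen `records`.
#' @export
stratified_mediation <- function(counts, phenotypes, gene_subset,
                                 covariates = c("age", "education"),
                                 target = "ldl_c", mediator = "sdldl",
                                 alpha = 0.05, min_cpm = 1, min_samples = 3) {
  if ("sex" %in% covariates)
    stop("sex cannot be a covariate in a sex-stratified analysis")
  if (!length(gene_subset)) {
    empty <- data.frame(gene_id = character(), mediated_female = logical(),
                        mediated_male = logical(),
                        classification = factor(character(),
                          levels = c("both", "female_only", "male_only",
                                     "neither")))
    return(structure(list(classification = empty,
                          summary = table(empty$classification),
                          records = list()),
                     class = "sex_stratified_result"))
  }
  run_stratum <- function(sx) {
    keep <- phenotypes$sex == sx
    ph <- phenotypes[keep, , drop = FALSE]
    cts <- counts[, keep, drop = FALSE]
    # rough design-size check before any computation
    n_design <- 2L + length(covariates) + 3L * ("education" %in% covariates)
    n_extreme <- 2 * floor(nrow(ph) / 3)
    if (n_extreme < 3L * n_design)
      stop("stratum '", sx, "' too small: ", nrow(ph),
           " samples; need at least ", ceiling(4.5 * n_design))
    filtered <- filter_low_expression(cts, min_cpm, min_samples)
    missing <- setdiff(gene_subset, rownames(filtered))
    if (length(missing))
      stop("gene subset member(s) filtered out in the ", sx, " stratum: ",
           paste(utils::head(missing, 5), collapse = ", "))
    norm <- compute_tmm_factors(filtered)
    de_t <- lrt_de(filtered, ph, target, covariates, norm = norm,
                   genes = gene_subset, alpha = alpha)
    de_m <- lrt_de(filtered, ph, mediator, covariates, norm = norm,
                   genes = gene_subset, alpha = alpha)
    disp_t <- attr(de_t, "dispersions")
    common <- intersect(de_t$gene_id, de_m$gene_id)
    de_t <- de_t[de_t$gene_id %in% common, , drop = FALSE]
    de_m <- de_m[de_m$gene_id %in% common, , drop = FALSE]
    cand <- intersect(de_t$gene_id[de_t$fdr_adjusted_p <= alpha],
                      de_m$gene_id[de_m$fdr_adjusted_p <= alpha])
    cand <- cand[sign(de_t$logFC[match(cand, de_t$gene_id)]) ==
                   sign(de_m$logFC[match(cand, de_m$gene_id)])]
    de_a <- if (length(cand)) {
      lrt_de(filtered, ph, target, covariates, extra_continuous = mediator,
             norm = norm, genes = cand, dispersions = disp_t, alpha = alpha)
    } else de_t[0, , drop = FALSE]
    screen_mediation(de_t, de_m, de_a, alpha)
  }
  records <- list(female = run_stratum("female"), male = run_stratum("male"))
  common <- intersect(records$female$gene_id, records$male$gene_id)
  if (length(common) < length(gene_subset))
    message(length(gene_subset) - length(common),
            " gene(s) not testable in both strata dropped")
  records <- lapply(records, function(r) r[r$gene_id %in% common, ,
                                           drop = FALSE])
  cls <- classify_overlap(records$female, records$male)
  pm_f <- records$female$proportion_mediated[
    match(cls$classification$gene_id, records$female$gene_id)]
  pm_m <- records$male$proportion_mediated[
    match(cls$classification$gene_id, records$male$gene_id)]
  cls$classification$pm_female <- pm_f
  cls$classification$pm_male <- pm_m
  structure(list(classification = cls$classification, summary = cls$summary,
                 records = records),
            class = "sex_stratified_result")
}
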
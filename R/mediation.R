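#' Proportion of an effect mediated
#'
#' Percent reduction of the trait log fold change when the mediator enters
#' the model: `100 * (1 - logfc_adjusted / logfc_base)`, clamped to
#' \[0, 100\] — an adjusted logFC that overshoots zero counts as complete
#' mediation, and one that exceeds the base counts as no attenuation.
#' Undefined (`NA`) when the base logFC is zero.
#'
#' @param logfc_base log fold change of the trait contrast.
#' @param logfc_adjusted log fold change after adding the mediator as a
#'   covariate.
#' @return percent mediated in \[0, 100\] (vectorized), `NA` where the base
#'   is zero.
#' @export
proportion_mediated <- function(logfc_base, logfc_adjusted) {
  pm <- ifelse(logfc_base == 0, NA_real_,
               100 * (1 - logfc_adjusted / logfc_base))
  clamp(pm, 0, 100)
}

#' Three-condition mediation screen
#'
#' A gene's trait association is called mediated when all of: (1) the
#' trait-gene association is significant (BH-adjusted p <= `alpha`); (2) the
#' mediator-gene association is significant; the two log fold changes are
#' sign-concordant; and (3) the trait logFC is attenuated in absolute value
#' when the mediator enters the model. The proportion mediated is computed
#' for mediated genes only.
#'
#' @param de_trait DE table for the trait contrast (e.g. LDL-C).
#' @param de_mediator DE table for the mediator contrast (e.g. sdLDL); must
#'   share the gene universe of `de_trait`.
#' @param de_trait_adjusted DE table for the trait contrast with the
#'   mediator as covariate; must cover at least every gene passing
#'   conditions 1-2 with sign concordance (lazy evaluation of the adjusted
#'   fit is permitted).
#' @param alpha FDR threshold for conditions 1 and 2 (default 0.05).
#' @return a `data.frame` (one row per gene of the shared universe):
#'   `gene_id`, the three logFCs, condition flags, `proportion_mediated`,
#'   `mediated`, `direction`.
#' @export
screen_mediation <- function(de_trait, de_mediator, de_trait_adjusted,
                             alpha = 0.05) {
  u1 <- de_trait$gene_id; u2 <- de_mediator$gene_id
  if (!setequal(u1, u2)) {
    stop("gene universes differ: ", length(setdiff(u1, u2)),
         " only in trait table, ", length(setdiff(u2, u1)),
         " only in mediator table")
  }
  med <- de_mediator[match(u1, de_mediator$gene_id), ]
  rec <- data.frame(
    gene_id = u1,
    logfc_trait = de_trait$logFC,
    logfc_mediator = med$logFC,
    logfc_trait_adjusted = NA_real_,
    cond1_significant = de_trait$fdr_adjusted_p <= alpha,
    cond2_significant = med$fdr_adjusted_p <= alpha,
    sign_concordant = sign(de_trait$logFC) == sign(med$logFC),
    cond3_attenuated = NA,
    stringsAsFactors = FALSE
  )
  candidate <- rec$cond1_significant & rec$cond2_significant &
    rec$sign_concordant
  need <- rec$gene_id[candidate]
  missing_adj <- setdiff(need, de_trait_adjusted$gene_id)
  if (length(missing_adj))
    stop("adjusted DE table lacks ", length(missing_adj),
         " candidate gene(s), e.g. ",
         paste(utils::head(missing_adj, 5), collapse = ", "))
  idx <- match(rec$gene_id, de_trait_adjusted$gene_id)
  rec$logfc_trait_adjusted <- de_trait_adjusted$logFC[idx]
  rec$cond3_attenuated <- abs(rec$logfc_trait_adjusted) < abs(rec$logfc_trait)
  rec$mediated <- candidate & !is.na(rec$cond3_attenuated) &
    rec$cond3_attenuated
  rec$proportion_mediated <- ifelse(
    rec$mediated,
    proportion_mediated(rec$logfc_trait, rec$logfc_trait_adjusted),
    NA_real_
  )
  rec$direction <- ifelse(rec$logfc_trait > 0, "up", "down")
  rec
}

#' Run the full mediation screen from counts and phenotypes
#'
#' Orchestrates: low-expression filter, TMM normalization, trait-tertile DE,
#' mediator-tertile DE (each phenotype gets its own tertiles), selection of
#' significant sign-concordant overlap genes, the adjusted trait DE with the
#' mediator as a standardized continuous covariate (fitted lazily for the
#' candidate genes at their trait-fit dispersions), and the three-condition
#' screen. Stage gene counts are reported alongside the records.
#'
#' @param counts raw gene x sample count matrix.
#' @param phenotypes matching phenotype table.
#' @param target,mediator phenotype column names (defaults `ldl_c`,
#'   `sdldl`).
#' @param covariates adjustment covariates for all fits.
#' @param alpha FDR threshold (default 0.05).
#' @param min_cpm,min_samples low-expression filter settings.
#' @return a `mediation_result` list: `records` (the screen table),
#'   `summary` (named stage counts: genes tested, significant per contrast,
#'   overlap, concordant, mediated), and the three DE tables.
#' @export
run_mediation_pipeline <- function(counts, phenotypes,
                                   target = "ldl_c", mediator = "sdldl",
                                   covariates = c("age", "sex", "education"),
                                   alpha = 0.05, min_cpm = 1,
                                   min_samples = 3) {
  filtered <- filter_low_expression(counts, min_cpm, min_samples)
  norm <- compute_tmm_factors(filtered)
  de_trait <- lrt_de(filtered, phenotypes, target, covariates, norm = norm,
                     alpha = alpha)
  de_med <- lrt_de(filtered, phenotypes, mediator, covariates, norm = norm,
                   alpha = alpha)

  # genes flagged in one fit but not the other leave the tested universe
  disp_trait <- attr(de_trait, "dispersions")
  common <- intersect(de_trait$gene_id, de_med$gene_id)
  if (length(common) < max(nrow(de_trait), nrow(de_med))) {
    message(max(nrow(de_trait), nrow(de_med)) - length(common),
            " gene(s) not testable in both contrasts dropped from the screen")
    de_trait <- de_trait[de_trait$gene_id %in% common, , drop = FALSE]
    de_med <- de_med[de_med$gene_id %in% common, , drop = FALSE]
  }
  sig1 <- de_trait$gene_id[de_trait$fdr_adjusted_p <= alpha]
  sig2 <- de_med$gene_id[de_med$fdr_adjusted_p <= alpha]
  overlap <- intersect(sig1, sig2)
  s_t <- sign(de_trait$logFC[match(overlap, de_trait$gene_id)])
  s_m <- sign(de_med$logFC[match(overlap, de_med$gene_id)])
  concordant <- overlap[s_t == s_m]

  if (length(concordant)) {
    de_adj <- lrt_de(filtered, phenotypes, target, covariates,
                     extra_continuous = mediator, norm = norm,
                     genes = concordant, dispersions = disp_trait,
                     alpha = alpha)
  } else {
    de_adj <- de_trait[0, , drop = FALSE]
  }
  records <- screen_mediation(de_trait, de_med, de_adj, alpha)
  summary <- c(
    n_genes_tested = nrow(de_trait),
    n_significant_trait = length(sig1),
    n_significant_mediator = length(sig2),
    n_overlap = length(overlap),
    n_concordant = length(concordant),
    n_mediated = sum(records$mediated)
  )
  structure(list(records = records, summary = summary,
                 de_trait = de_trait, de_mediator = de_med,
                 de_trait_adjusted = de_adj,
                 alpha = alpha, target = target, mediator = mediator),
            class = "mediation_result")
}
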
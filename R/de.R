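#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()] with `method = "BH"`:
#' inputs must lie in (0, 1], the input order is preserved, and adjusted
#' values are capped at 1.
#'
#' @param p_values raw p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Tertile-extremes differential expression by NB likelihood ratio test
#'
#' Contrasts the upper against the lower tertile of a continuous phenotype.
#' Per gene, a negative binomial GLM (log link, log effective library size
#' offsets) is fitted with the group indicator plus covariates, and again
#' without the group indicator, both at the gene's trend-shrunken Cox-Reid
#' dispersion; the likelihood ratio statistic is referred to chi-square with
#' one degree of freedom and p-values are BH-adjusted across all tested
#' genes. Log fold changes are reported in log2 units (high vs low).
#'
#' @param counts filtered gene x sample count matrix.
#' @param phenotypes phenotype table with one row per sample of `counts`
#'   (matched by `sample_id`).
#' @param target name of the phenotype column defining the tertiles.
#' @param covariates adjustment covariates (default age, sex, education).
#' @param extra_continuous additional standardized continuous covariates
#'   (e.g. the mediator in the adjusted fit).
#' @param norm optional precomputed [compute_tmm_factors()] result for
#'   `counts`.
#' @param genes optional subset of gene ids to test (normalization and
#'   offsets still use the full matrix); BH adjustment is over the tested
#'   genes.
#' @param dispersions optional named per-gene dispersions to use instead of
#'   estimating them under the full design.
#' @param alpha FDR threshold recorded on the result (default 0.05).
#' @return a `data.frame` sorted by p-value with columns `gene_id`, `logFC`,
#'   `dispersion`, `lrt_stat`, `p_value`, `fdr_adjusted_p`, `direction`, and
#'   attributes `design` (the tertile design), `n_low`/`n_high`, `flagged`
#'   (genes excluded for non-convergence or all-zero counts) and
#'   `dispersions` (the full named vector used).
#' @export
lrt_de <- function(counts, phenotypes, target,
                   covariates = c("age", "sex", "education"),
                   extra_continuous = character(),
                   norm = NULL, genes = NULL, dispersions = NULL,
                   alpha = 0.05) {
  assert_count_matrix(counts)
  if (!target %in% names(phenotypes))
    stop("target phenotype '", target, "' not found")
  if (!identical(colnames(counts), phenotypes$sample_id))
    stop("sample ids of counts and phenotypes differ")
  used <- intersect(c(target, covariates, extra_continuous),
                    names(phenotypes))
  complete <- stats::complete.cases(phenotypes[, used, drop = FALSE])
  if (!all(complete)) {
    counts <- counts[, complete, drop = FALSE]
    phenotypes <- phenotypes[complete, , drop = FALSE]
    if (!is.null(norm)) norm <- NULL   # sample set changed; recompute
  }
  if (is.null(norm)) norm <- compute_tmm_factors(counts)

  design <- assign_tertiles(phenotypes[[target]], target)
  dm <- build_design_matrix(phenotypes, design, covariates, extra_continuous)
  X <- dm$X
  X0 <- X[, setdiff(colnames(X), dm$group_col), drop = FALSE]
  keep <- dm$keep
  offset <- log(norm$effective_library_size[keep])
  sub <- counts[, keep, drop = FALSE]
  if (ncol(sub) <= ncol(X))
    stop("fewer extreme-tertile samples than design columns")

  test_genes <- genes %||% rownames(sub)
  missing_genes <- setdiff(test_genes, rownames(sub))
  if (length(missing_genes))
    stop("genes not in count matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))

  if (is.null(dispersions)) {
    disp <- estimate_dispersion(sub[test_genes, , drop = FALSE], X, offset)$dispersion
  } else {
    if (is.null(names(dispersions)) || !all(test_genes %in% names(dispersions)))
      stop("dispersions must be named and cover all tested genes")
    disp <- dispersions[test_genes]
  }

  res <- lapply(test_genes, function(g) {
    y <- sub[g, ]
    phi <- disp[[g]]
    full <- fit_nb_glm(y, X, offset, phi)
    if (full$flag != "ok" || !full$converged)
      return(list(flagged = TRUE))
    red <- fit_nb_glm(y, X0, offset, phi)
    if (red$flag != "ok" || !red$converged)
      return(list(flagged = TRUE))
    stat <- max(0, 2 * (full$loglik - red$loglik))
    list(flagged = FALSE,
         logFC = full$coefficients[[dm$group_col]] / log(2),
         lrt_stat = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  })
  flagged <- test_genes[vapply(res, `[[`, TRUE, "flagged")]
  ok <- setdiff(test_genes, flagged)
  if (length(flagged))
    message(length(flagged), " gene(s) flagged (all-zero or non-converged) ",
            "and excluded from testing")
  tab <- data.frame(
    gene_id = ok,
    logFC = vapply(res[match(ok, test_genes)], `[[`, 0, "logFC"),
    dispersion = as.numeric(disp[ok]),
    lrt_stat = vapply(res[match(ok, test_genes)], `[[`, 0, "lrt_stat"),
    p_value = vapply(res[match(ok, test_genes)], `[[`, 0, "p_value"),
    stringsAsFactors = FALSE
  )
  tab$p_value <- pmin(pmax(tab$p_value, .Machine$double.xmin), 1)
  tab$fdr_adjusted_p <- bh_adjust(tab$p_value)
  tab$direction <- ifelse(tab$logFC > 0, "up", "down")
  tab <- tab[order(tab$p_value), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "design") <- design
  attr(tab, "n_low") <- sum(design$group[keep] == "low")
  attr(tab, "n_high") <- sum(design$group[keep] == "high")
  attr(tab, "flagged") <- flagged
  attr(tab, "dispersions") <- disp
  attr(tab, "alpha") <- alpha
  attr(tab, "target") <- target
  class(tab) <- c("de_result", "data.frame")
  tab
}
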
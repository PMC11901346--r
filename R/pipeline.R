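#' Pipeline configuration
#'
#' Collects paths, thresholds and options of the end-to-end run. When
#' `counts`/`phenotypes` paths are `NULL` the pipeline simulates a synthetic
#' cohort instead (controlled by `sim`, a list of [sim_config()] overrides).
#' Round-trips losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param counts,phenotypes,gmt input file paths (or `NULL`).
#' @param outdir run directory (created if absent).
#' @param alpha FDR threshold of the DE and mediation stages.
#' @param min_cpm,min_samples low-expression filter settings.
#' @param enrichment_p,min_overlap enrichment retention settings.
#' @param covariates adjustment covariates of the pooled analysis.
#' @param run_sexdiff,run_enrichment stage switches.
#' @param sim named list of [sim_config()] overrides for the synthetic run.
#' @param seed integer seed fanned out to the stages.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, phenotypes = NULL, gmt = NULL,
                            outdir = tempfile("sdldlmed_run_"),
                            alpha = 0.05, min_cpm = 1, min_samples = 3,
                            enrichment_p = 0.05, min_overlap = 2,
                            covariates = c("age", "sex", "education"),
                            run_sexdiff = TRUE, run_enrichment = !is.null(gmt),
                            sim = list(), seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, min_cpm >= 0, min_samples >= 1,
            enrichment_p > 0, enrichment_p <= 1, min_overlap >= 1)
  if (xor(is.null(counts), is.null(phenotypes)))
    stop("provide both counts and phenotypes paths, or neither (synthetic run)")
  cfg <- list(counts = counts, phenotypes = phenotypes, gmt = gmt,
              outdir = outdir, alpha = alpha, min_cpm = min_cpm,
              min_samples = min_samples, enrichment_p = enrichment_p,
              min_overlap = min_overlap, covariates = covariates,
              run_sexdiff = run_sexdiff, run_enrichment = run_enrichment,
              sim = sim, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$covariates <- as.character(raw$covariates %||% character())
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes (simulate ->) filter -> TMM -> trait DE -> mediator DE ->
#' three-condition mediation screen -> sex-stratified screen over the
#' mediated genes -> hypergeometric enrichment of the mediated genes against
#' a GMT collection (universe = all tested genes). Every stage table, a
#' machine-readable stage-count summary, the effective configuration and a
#' log (seed, thresholds, covariates, package version) are written under
#' `config$outdir`. Inputs are validated before any computation starts.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the run directory, the stage `summary`,
#'   and the in-memory stage results.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$run_enrichment &&
      (is.null(config$gmt) || !file.exists(config$gmt)))
    stop("enrichment requested but GMT file is missing: ",
         config$gmt %||% "<NULL>")
  if (!is.null(config$counts) && !file.exists(config$counts))
    stop("counts file not found: ", config$counts)
  if (!is.null(config$phenotypes) && !file.exists(config$phenotypes))
    stop("phenotype file not found: ", config$phenotypes)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)

  truth <- NULL
  if (is.null(config$counts)) {
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    phenotypes <- simulate_phenotypes(scfg)
    sim <- simulate_counts(phenotypes, scfg)
    counts <- sim$counts
    truth <- sim$truth
    write_phenotypes(phenotypes, out("phenotypes.csv"))
    write_counts(counts, out("counts.tsv"))
    write_result_table(truth, out("simulation_truth.tsv"))
  } else {
    counts <- read_counts(config$counts)
    phenotypes <- read_phenotypes(config$phenotypes)
  }
  if (!identical(colnames(counts), phenotypes$sample_id))
    stop("sample ids of counts and phenotypes differ")

  med <- run_mediation_pipeline(
    counts, phenotypes, covariates = config$covariates,
    alpha = config$alpha, min_cpm = config$min_cpm,
    min_samples = config$min_samples
  )
  write_result_table(as.data.frame(med$de_trait), out("de_ldl.tsv"))
  write_result_table(as.data.frame(med$de_mediator), out("de_sdldl.tsv"))
  write_result_table(as.data.frame(med$de_trait_adjusted),
                     out("de_ldl_adjusted.tsv"))
  write_result_table(med$records, out("mediation_records.tsv"))
  tmm <- compute_tmm_factors(
    filter_low_expression(counts, config$min_cpm, config$min_samples))
  write_result_table(
    data.frame(sample_id = names(tmm$tmm_factor),
               tmm_factor = as.numeric(tmm$tmm_factor)),
    out("tmm_factors.tsv"))

  mediated_genes <- med$records$gene_id[med$records$mediated]
  summary <- as.list(med$summary)

  sexdiff <- NULL
  if (config$run_sexdiff) {
    sexdiff <- stratified_mediation(
      counts, phenotypes, mediated_genes,
      covariates = setdiff(config$covariates, "sex"),
      alpha = config$alpha, min_cpm = config$min_cpm,
      min_samples = config$min_samples
    )
    write_result_table(sexdiff$classification, out("sex_classification.tsv"))
    summary <- c(summary, as.list(stats::setNames(
      as.integer(sexdiff$summary), paste0("n_", names(sexdiff$summary)))))
  }

  enrich <- NULL
  if (config$run_enrichment) {
    sets <- read_gmt(config$gmt)
    enrich <- hypergeometric_enrichment(
      mediated_genes, med$de_trait$gene_id, sets,
      p_threshold = config$enrichment_p, min_overlap = config$min_overlap
    )
    write_result_table(enrich, out("enrichment.tsv"))
    summary$n_enriched_sets <- nrow(enrich)
  }

  yaml::write_yaml(summary, out("stage_summary.yaml"))
  write_pipeline_config(config, out("config.yaml"))
  writeLines(c(
    paste0("sdldlmed version: ",
           as.character(utils::packageVersion("sdldlmed"))),
    paste0("seed: ", config$seed),
    paste0("alpha: ", config$alpha),
    paste0("min_cpm: ", config$min_cpm),
    paste0("min_samples: ", config$min_samples),
    paste0("covariates: ", paste(config$covariates, collapse = ",")),
    paste0("run date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  ), out("log.txt"))

  invisible(list(outdir = config$outdir, summary = summary,
                 mediation = med, sexdiff = sexdiff, enrichment = enrich,
                 truth = truth))
}
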
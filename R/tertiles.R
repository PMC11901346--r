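#' Assign samples to phenotype tertile extremes
#'
#' Cutpoints are the empirical 1/3 and 2/3 quantiles (linear-interpolation
#' definition). Samples at or below the lower cutpoint form the `low` group,
#' samples strictly above the upper cutpoint the `high` group, and the middle
#' third is `excluded` from the contrast. Ties at a cutpoint therefore fall
#' to the lower bin, which keeps the assignment deterministic on granular
#' data.
#'
#' @param values per-sample phenotype values (finite numerics).
#' @param phenotype_name label carried through to results.
#' @return a `tertile_design` list: `phenotype_name`, per-sample `group`
#'   factor (`low`/`excluded`/`high`) and the `cutpoints`.
#' @export
assign_tertiles <- function(values, phenotype_name = "phenotype") {
  if (sum(is.finite(values)) < 3L) stop("need at least 3 finite values")
  if (any(!is.finite(values))) stop("non-finite phenotype values")
  if (length(unique(values)) < 2L)
    stop("degenerate phenotype: fewer than 2 distinct values")
  cut <- stats::quantile(values, c(1, 2) / 3, type = 7, names = FALSE)
  if (cut[1] == cut[2])
    stop("degenerate tertiles for '", phenotype_name,
         "': 1/3 and 2/3 quantiles coincide")
  group <- factor(ifelse(values <= cut[1], "low",
                         ifelse(values > cut[2], "high", "excluded")),
                  levels = c("low", "excluded", "high"))
  if (!any(group == "low") || !any(group == "high"))
    stop("degenerate tertiles for '", phenotype_name, "': an extreme group is empty")
  structure(list(phenotype_name = phenotype_name, group = group,
                 cutpoints = c(lower = cut[1], upper = cut[2])),
            class = "tertile_design")
}

#' Build the per-contrast design matrix
#'
#' Intercept, a high-vs-low group indicator, and covariate columns: age
#' standardized, a male indicator, education dummies (reference
#' `<=high_school`, with `not_available` kept as its own level so samples
#' with unreported education stay in the model), plus optional standardized
#' continuous columns (e.g. the mediator). Samples in the excluded middle
#' tertile are dropped. Covariate columns that are constant in the retained
#' samples are dropped with a warning; remaining collinearity is an error.
#'
#' @param phenotypes phenotype table (one row per sample).
#' @param design a `tertile_design` from [assign_tertiles()], or `NULL` for
#'   no group column (covariate-only matrix).
#' @param covariates subset of `c("age", "sex", "education",
#'   "on_lipid_med")`.
#' @param extra_continuous names of phenotype columns appended as
#'   standardized continuous covariates.
#' @return list: `X` (model matrix), `keep` (logical per input sample),
#'   `group_col` (name of the group coefficient or `NA`).
#' @export
build_design_matrix <- function(phenotypes, design = NULL,
                                covariates = c("age", "sex", "education"),
                                extra_continuous = character()) {
  known <- c("age", "sex", "education", "on_lipid_med")
  if (length(covariates) && !all(covariates %in% known))
    stop("unknown covariates: ",
         paste(setdiff(covariates, known), collapse = ", "))
  missing_cols <- setdiff(c(covariates, extra_continuous), names(phenotypes))
  if (length(missing_cols))
    stop("phenotype table lacks columns: ",
         paste(missing_cols, collapse = ", "))

  keep <- rep(TRUE, nrow(phenotypes))
  if (!is.null(design)) {
    stopifnot(inherits(design, "tertile_design"),
              length(design$group) == nrow(phenotypes))
    keep <- design$group != "excluded"
  }
  df <- phenotypes[keep, , drop = FALSE]

  X <- matrix(1, nrow(df), 1, dimnames = list(df$sample_id, "(Intercept)"))
  group_col <- NA_character_
  if (!is.null(design)) {
    X <- cbind(X, group_high = as.numeric(design$group[keep] == "high"))
    group_col <- "group_high"
  }
  dropped <- character()
  add_col <- function(v, name, standardize = FALSE) {
    if (stats::sd(v) == 0) {
      dropped <<- c(dropped, name)
    } else {
      X <<- cbind(X, if (standardize) zstd(v) else v)
      colnames(X)[ncol(X)] <<- name
    }
  }
  for (cv in covariates) {
    switch(cv,
      age = add_col(df$age, "age", standardize = TRUE),
      sex = add_col(as.numeric(df$sex == "male"), "sex_male"),
      on_lipid_med = add_col(as.numeric(df$on_lipid_med), "on_lipid_med"),
      education = {
        edu <- as.character(df$education)
        present <- education_levels[education_levels %in% unique(edu)]
        if (length(present) < 2L) {
          dropped <- c(dropped, "education")
        } else {
          # reference = first level present, so an absent reference level
          # cannot leave the dummies collinear with the intercept
          for (lev in present[-1L])
            add_col(as.numeric(edu == lev), paste0("education_", lev))
        }
      }
    )
  }
  for (ec in extra_continuous) {
    v <- df[[ec]]
    if (!is.numeric(v)) stop("extra_continuous column '", ec, "' not numeric")
    add_col(v, ec, standardize = TRUE)
  }
  if (length(dropped))
    warning("constant covariate column(s) dropped: ",
            paste(dropped, collapse = ", "))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  rownames(X) <- df$sample_id
  list(X = X, keep = keep, group_col = group_col)
}
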
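#' Read a gene x sample count matrix
#'
#' Accepts a TSV (gene id in the first column, sample ids in the header) or
#' a MatrixMarket `.mtx` triplet with `<path>.rownames` / `<path>.colnames`
#' sidecar files (one id per line). Entries must be non-negative integers;
#' duplicate ids are an error.
#'
#' @param path file path (`.mtx` selects MatrixMarket, anything else TSV).
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- paste0(path, ".rownames"); cn <- paste0(path, ".colnames")
    if (!file.exists(rn) || !file.exists(cn))
      stop("MTX sidecar id files missing: ", rn, " / ", cn)
    rownames(m) <- readLines(rn)
    colnames(m) <- readLines(cn)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("counts TSV needs a gene column plus samples")
    if (anyDuplicated(df[[1L]]))
      stop("duplicate gene ids in ", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
  }
  if (!nrow(m)) stop("empty counts file: ", path)
  storage.mode(m) <- "double"
  assert_count_matrix(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as TSV or MatrixMarket
#'
#' @param counts gene x sample matrix.
#' @param path output path; a `.mtx` extension writes MatrixMarket plus
#'   `<path>.rownames` / `<path>.colnames` sidecars, anything else a TSV
#'   with the gene id in the first column.
#' @export
write_counts <- function(counts, path) {
  assert_count_matrix(counts)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rownames"))
    writeLines(colnames(counts), paste0(path, ".colnames"))
  } else {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a phenotype table (CSV)
#'
#' The CSV carries `sample_id`, `ldl_c`, `sdldl`, `age`, `sex`, `education`
#' and optionally `on_lipid_med`; categorical columns are restored with
#' their full level sets.
#'
#' @param path CSV path.
#' @return phenotype `data.frame`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "ldl_c", "sdldl", "age", "sex", "education")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("phenotype table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (any(df$ldl_c <= 0) || any(df$sdldl <= 0))
    stop("ldl_c and sdldl must be positive")
  if (!all(df$sex %in% sex_levels))
    stop("sex values outside {", paste(sex_levels, collapse = ", "), "}")
  if (!all(df$education %in% education_levels))
    stop("education values outside the expected level set")
  df$sex <- factor(df$sex, levels = sex_levels)
  df$education <- factor(df$education, levels = education_levels)
  if ("on_lipid_med" %in% names(df))
    df$on_lipid_med <- as.logical(df$on_lipid_med)
  df
}

#' @rdname read_phenotypes
#' @param phenotypes phenotype table to write.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a result table as TSV
#'
#' Tab-separated, UTF-8, header row, missing values as `NA`. The reader
#' restores what the writer wrote (round-trip identity for the pipeline's
#' result tables).
#'
#' @param table data.frame to write.
#' @param path TSV path.
#' @export
write_result_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE)
}

#' Packaged 33-mRNA mediated-gene fixture
#'
#' The printed differential-expression summary (log2 fold change, raw and
#' BH-adjusted p, for both the LDL-C and the sdLDL tertile contrasts) for
#' the 33 whole-blood mRNAs whose LDL-C association is mediated by sdLDL in
#' the source cohort. The packaged file is checksum-pinned; a mismatch
#' signals fixture corruption.
#'
#' @return data.frame with 33 rows and columns `gene`, `logfc_ldl`,
#'   `p_ldl`, `fdr_ldl`, `logfc_sdldl`, `p_sdldl`, `fdr_sdldl`.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_mediated_mrnas.tsv",
                      package = "sdldlmed", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, "c63fa2e11c5b4425009c8f05598998b9"))
    stop("table2 fixture checksum mismatch: file corrupted")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 33L, !anyDuplicated(df$gene))
  df
}
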
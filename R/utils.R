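#' @keywords internal
"_PACKAGE"

# Stage-indexed seed derivation: one user-facing seed fans out to independent
# per-stage seeds so re-ordering or skipping stages does not shift the stream.
stage_seeds <- c(
  phenotypes = 11L, counts = 23L, pipeline = 37L, enrichment = 41L,
  stratified_female = 53L, stratified_male = 59L
)

derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!stage %in% names(stage_seeds)) stop("unknown stage: ", stage)
  # double arithmetic (exact below 2^53) to avoid 32-bit integer overflow
  as.integer((abs(as.numeric(seed)) * 1009 + stage_seeds[[stage]]) %%
               (.Machine$integer.max - 1))
}

# Standardize to zero mean, unit SD. Constant input is an error: a constant
# covariate cannot be standardized and signals a degenerate design.
zstd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

education_levels <- c(
  "<=high_school", "some_college", "college_grad", ">graduate", "not_available"
)
sex_levels <- c("female", "male")

assert_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in counts")
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(counts)[idx[1L]], colnames(counts)[idx[2L]]))
  }
  if (any(counts != round(counts))) {
    idx <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 rownames(counts)[idx[1L]], colnames(counts)[idx[2L]]))
  }
  invisible(counts)
}
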
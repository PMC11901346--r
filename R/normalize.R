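#' Filter genes below a CPM floor
#'
#' Removes genes that do not reach `min_cpm` counts per million in at least
#' `min_samples` samples (boundary inclusive). CPM here uses raw library
#' sizes (scaling factors of one): the filter runs before composition
#' normalization, mirroring the standard count-model workflow.
#'
#' @param counts gene x sample integer matrix.
#' @param min_cpm CPM floor (default 1).
#' @param min_samples minimum number of samples at or above the floor
#'   (default 3).
#' @return the filtered count matrix (same samples, fewer genes).
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_samples = 3) {
  assert_count_matrix(counts)
  if (min_samples > ncol(counts))
    stop("min_samples exceeds the number of samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  cpm <- t(t(counts) * 1e6 / lib)
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep))
    stop("no gene passes the expression filter; review min_cpm/min_samples")
  counts[keep, , drop = FALSE]
}

# Upper-quartile count fraction per sample (reference-selection statistic).
uq_fraction <- function(counts, lib) {
  apply(counts, 2L, stats::quantile, probs = 0.75) / lib
}

# One TMM factor: trimmed, precision-weighted mean of M values of `obs`
# against `ref` (both raw count vectors with library sizes).
tmm_pair <- function(obs, lib_obs, ref, lib_ref,
                     trim_m = 0.30, trim_a = 0.05, do_weighting = TRUE) {
  ok <- obs > 0 & ref > 0
  o <- obs[ok] / lib_obs
  r <- ref[ok] / lib_ref
  m <- log2(o / r)
  a <- 0.5 * log2(o * r)
  if (length(m) == 0L || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (sum(keep) < 10L) {
    warning("fewer than 10 genes survive TMM trimming; factor set to 1")
    return(1)
  }
  if (do_weighting) {
    # delta-method (binomial) asymptotic variance of M
    v <- (lib_obs - obs[ok]) / (lib_obs * obs[ok]) +
      (lib_ref - ref[ok]) / (lib_ref * ref[ok])
    2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  } else {
    2^mean(m[keep])
  }
}

#' Trimmed mean of M-values (TMM) normalization
#'
#' Computes per-sample scaling factors that correct for library composition:
#' the reference sample is the one whose upper-quartile count fraction is
#' closest to the mean upper-quartile fraction (smallest index on ties); for
#' every sample, gene-wise log2 expression ratios (M) and average log2
#' abundances (A) against the reference are formed over genes nonzero in
#' both, the most extreme `trim_m` of M and `trim_a` of A are discarded, and
#' the factor is two to the precision-weighted mean of the remaining M
#' values. Factors are rescaled to geometric mean one.
#'
#' @param counts gene x sample integer matrix (typically already filtered).
#' @param trim_m,trim_a total two-sided trim fractions on M and A (defaults
#'   0.30 and 0.05, the canonical TMM settings).
#' @param do_weighting weight M values by inverse delta-method variance
#'   (default); `FALSE` gives the plain trimmed mean.
#' @return a `tmm_norm` list: `tmm_factor`, `library_size`,
#'   `effective_library_size` (their product) per sample, the reference
#'   sample id, and the `cpm` matrix on effective library sizes.
#' @export
compute_tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                                do_weighting = TRUE) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  f75 <- uq_fraction(counts, lib)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    if (i == ref) return(1)
    tmm_pair(counts[, i], lib[i], counts[, ref], lib[ref],
             trim_m, trim_a, do_weighting)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  eff <- lib * f
  out <- list(
    tmm_factor = f, library_size = lib, effective_library_size = eff,
    reference_sample = colnames(counts)[ref]
  )
  out$cpm <- t(t(counts) * 1e6 / eff)
  class(out) <- "tmm_norm"
  out
}

#' Counts per million on effective library sizes
#'
#' @param counts gene x sample matrix.
#' @param norm a `tmm_norm` object from [compute_tmm_factors()] for the same
#'   samples; omit for raw-library-size CPM.
#' @return real matrix `counts * 1e6 / effective_library_size`.
#' @export
compute_cpm <- function(counts, norm = NULL) {
  assert_count_matrix(counts)
  if (is.null(norm)) {
    eff <- colSums(counts)
  } else {
    if (!inherits(norm, "tmm_norm")) stop("norm must be a tmm_norm object")
    if (!identical(colnames(counts), names(norm$tmm_factor)))
      stop("sample sets of counts and normalization result differ")
    eff <- norm$effective_library_size
  }
  if (any(eff == 0)) stop("zero library size")
  t(t(counts) * 1e6 / eff)
}
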
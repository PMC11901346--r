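#' Read a gene-set collection from a GMT file
#'
#' One set per line: set name, description, then tab-separated member gene
#' ids. Lines with fewer than three fields are skipped with a warning;
#' duplicate set names are an error; duplicate members within a line are
#' stored once.
#'
#' @param path GMT file path.
#' @return a `gene_set_collection` list: `sets` (named list of member id
#'   vectors), `descriptions` (named character), `source` (the path).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    warning(sum(short), " GMT line(s) with fewer than 3 fields skipped")
    fields <- fields[!short]
  }
  if (!length(fields)) stop("no valid gene-set lines in ", path)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  desc <- vapply(fields, `[[`, "", 2L)
  names(desc) <- nm
  structure(list(sets = sets, descriptions = desc, source = path),
            class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a `gene_set_collection` (or a named list of gene id
#'   vectors).
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  if (!inherits(collection, "gene_set_collection")) {
    collection <- structure(
      list(sets = collection,
           descriptions = stats::setNames(rep("", length(collection)),
                                          names(collection))),
      class = "gene_set_collection")
  }
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]] %||% "",
            collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation analysis
#'
#' For each set, with universe size `N`, query size `n`, set size within the
#' universe `K` and overlap `k`, computes the upper-tail hypergeometric
#' probability `P(X >= k)` of drawing at least `k` set members in `n` draws
#' without replacement. Sets are retained at `p_value <= p_threshold` with
#' at least `min_overlap` query members; a BH-adjusted column over all
#' scored sets is included for reference (no adjustment is applied to the
#' retention rule).
#'
#' @param query gene ids of interest (e.g. mediated genes). Ids outside the
#'   universe are dropped with a warning.
#' @param universe background gene ids (typically all genes tested).
#' @param sets a `gene_set_collection` from [read_gmt()].
#' @param p_threshold retention threshold on the raw p-value (default 0.05).
#' @param min_overlap minimum overlap count (default 2).
#' @return data.frame sorted by p-value: `set_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `bh_p`, `overlap_genes` (comma-joined).
#' @export
hypergeometric_enrichment <- function(query, universe, sets,
                                      p_threshold = 0.05, min_overlap = 2) {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(universe)
  query <- unique(query)
  if (!length(query)) stop("empty query gene list")
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (!length(query)) stop("no query genes left within the universe")
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    K <- length(members)
    ov <- intersect(members, query)
    k <- length(ov)
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$bh_p <- bh_adjust(tab$p_value)
  tab <- tab[tab$p_value <= p_threshold & tab$k >= min_overlap, , drop = FALSE]
  tab <- tab[order(tab$p_value, tab$set_name), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("set_name", "k", "K", "n", "N", "p_value", "bh_p", "overlap_genes")]
}
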
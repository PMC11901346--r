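test_that("TMM factors are unity for identical and depth-scaled samples", {
  set.seed(1)
  base <- rnbinom(500, mu = 50, size = 5) + 1
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  f <- compute_tmm_factors(m)$tmm_factor
  expect_equal(unname(f), c(1, 1), tolerance = 1e-9)
  # pure depth difference is absorbed by the library size
  m2 <- cbind(s1 = base, s2 = 2L * base)
  rownames(m2) <- paste0("g", seq_len(nrow(m2)))
  f2 <- compute_tmm_factors(m2)$tmm_factor
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-9)
})

test_that("TMM matches an independent trimmed-mean oracle under asymmetry", {
  set.seed(7)
  g <- 1000
  a <- rnbinom(g, mu = 100, size = 10) + 1
  b <- a
  up <- sample(g, 50)                  # 5% of genes 8-fold up in B only
  b[up] <- b[up] * 8L
  m <- cbind(A = a, B = b)
  rownames(m) <- paste0("g", seq_len(g))
  f <- compute_tmm_factors(m)$tmm_factor
  oracle <- tmm_oracle_factor(b, a)    # factor of B against reference A
  expect_equal(unname(f["B"] / f["A"]), unname(oracle), tolerance = 0.05)
  # composition bias direction: the unchanged genes look depleted in B, so
  # B's factor falls below A's
  expect_lt(f[["B"]], f[["A"]])
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  co <- small_cohort(seed = 31, n_samples = 12, n_genes = 800)
  cts <- filter_low_expression(co$counts)
  ours <- compute_tmm_factors(cts)$tmm_factor
  theirs <- edgeR::calcNormFactors(cts, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
})

test_that("TMM factors have geometric mean one and permute with samples", {
  co <- small_cohort(seed = 8, n_samples = 10, n_genes = 500)
  cts <- filter_low_expression(co$counts)
  res <- compute_tmm_factors(cts)
  expect_equal(exp(mean(log(res$tmm_factor))), 1, tolerance = 1e-9)
  expect_equal(res$effective_library_size,
               colSums(cts) * res$tmm_factor)
  perm <- c(3, 1, 2, 7, 10, 4, 6, 5, 9, 8)
  res_p <- compute_tmm_factors(cts[, perm])
  expect_equal(res_p$tmm_factor, res$tmm_factor[perm], tolerance = 1e-12)
  # scaling one sample's counts is absorbed by its library size (only the
  # precision weights move, so agreement is near- rather than bit-exact)
  cts2 <- cts
  cts2[, 2] <- cts2[, 2] * 3L
  expect_equal(compute_tmm_factors(cts2)$tmm_factor, res$tmm_factor,
               tolerance = 0.01)
})

test_that("all-zero samples are rejected by name", {
  m <- toy_counts()
  m[, 2] <- 0L
  expect_error(compute_tmm_factors(m), "s2")
  expect_error(filter_low_expression(m), "s2")
})

test_that("CPM follows its definition", {
  m <- matrix(c(1, 999999, 0, 1000000), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- compute_cpm(m)
  expect_equal(cpm["g1", "s1"], 1)     # count 1 in a 1e6 library
  expect_equal(cpm["g1", "s2"], 0)
  # unit factors: CPM columns sum to exactly 1e6
  co <- small_cohort(seed = 4, n_samples = 6, n_genes = 200)
  expect_equal(unname(colSums(compute_cpm(co$counts))),
               rep(1e6, 6), tolerance = 1e-9)
  expect_error(compute_cpm(co$counts,
                           compute_tmm_factors(co$counts[, 1:4])),
               "sample sets")
})

test_that("low-expression filter is boundary-inclusive and idempotent", {
  # gene at exactly min_cpm in exactly min_samples of 10 is retained
  n <- 10
  m <- rbind(
    boundary = c(rep(1L, 3), rep(0L, 7)),
    rich = rep(1000L, n),
    zero = rep(0L, n)
  )
  colnames(m) <- paste0("s", 1:n)
  # library size 1e6 in every sample so CPM == count
  m <- rbind(m, filler = 1e6L - colSums(m))
  rownames(m)[4] <- "filler"
  cpm <- compute_cpm(m)
  expect_equal(cpm["boundary", "s1"], 1)
  kept <- filter_low_expression(m, min_cpm = 1, min_samples = 3)
  expect_true("boundary" %in% rownames(kept))
  expect_false("zero" %in% rownames(kept))
  expect_identical(filter_low_expression(kept, 1, 3), kept)
  expect_identical(colnames(kept), colnames(m))
})

test_that("low-expression filter matches hand enumeration on the toy matrix", {
  m <- toy_counts()
  # library sizes: 111, 201, 301, 406; CPM(g4) = 1e6/lib > 1 everywhere
  kept <- filter_low_expression(m, min_cpm = 1, min_samples = 3)
  expect_setequal(rownames(kept), c("g2", "g4"))
  kept2 <- filter_low_expression(m, min_cpm = 1, min_samples = 2)
  expect_setequal(rownames(kept2), c("g1", "g2", "g4"))
  expect_error(filter_low_expression(m, min_cpm = 1e9), "no gene passes")
  expect_error(filter_low_expression(m, min_samples = 99), "exceeds")
})
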
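# Independent brute-force oracles used to cross-check the implementation.

# Benjamini-Hochberg by explicit sort / scale / cumulative-min from the
# largest rank, undone back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  scaled <- sorted * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# C(N, n) query draws (feasible for N <= 12).
hyper_oracle <- function(N, K, n, k) {
  if (k <= 0) return(1)
  draws <- utils::combn(N, n)
  in_set <- draws <= K            # items 1..K are the set members
  mean(colSums(in_set) >= k)
}

# Plain trimmed-mean TMM oracle: quantile-threshold trimming on M and A
# (a deliberately different trimming rule from the rank-based one in the
# implementation), precision-weighted mean of the surviving M values.
tmm_oracle_factor <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  lo <- sum(obs); lr <- sum(ref)
  ok <- obs > 0 & ref > 0
  o <- obs[ok] / lo; r <- ref[ok] / lr
  m <- log2(o / r); a <- 0.5 * log2(o * r)
  qm <- stats::quantile(m, c(trim_m, 1 - trim_m))
  qa <- stats::quantile(a, c(trim_a, 1 - trim_a))
  keep <- m >= qm[1] & m <= qm[2] & a >= qa[1] & a <= qa[2]
  w <- 1 / ((lo - obs[ok]) / (lo * obs[ok]) + (lr - ref[ok]) / (lr * ref[ok]))
  2^(sum(m[keep] * w[keep]) / sum(w[keep]))
}

# Sort-and-slice tertile oracle: group sizes from explicit order statistics.
tertile_sizes_oracle <- function(values) {
  n <- length(values)
  s <- sort(values)
  q <- stats::quantile(values, c(1, 2) / 3, type = 7)
  c(low = sum(values <= q[1]), high = sum(values > q[2]))
}

# Small deterministic count fixture with hand-computable CPMs.
toy_counts <- function() {
  m <- matrix(c(
    10, 0, 0, 5,
    100, 200, 300, 400,
    0, 0, 0, 0,
    1, 1, 1, 1
  ), nrow = 4, byrow = TRUE)
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:4))
  m
}

# Moderate synthetic cohort shared by several tests.
small_cohort <- function(seed = 5, n_samples = 160, n_genes = 300, ...) {
  cfg <- sim_config(n_samples = n_samples, n_genes = n_genes, seed = seed, ...)
  ph <- simulate_phenotypes(cfg)
  sim <- simulate_counts(ph, cfg)
  list(config = cfg, phenotypes = ph, counts = sim$counts, truth = sim$truth)
}
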
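# Negative binomial (NB2) log-likelihood; dispersion 0 degrades to Poisson.
nb_loglik <- function(y, mu, dispersion) {
  if (dispersion < 1e-10) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / dispersion, mu = mu, log = TRUE))
  }
}

# NB2 deviance (Poisson limit at dispersion 0); y*log(y/mu) taken as 0 at y=0.
nb_deviance <- function(y, mu, dispersion) {
  yl <- ifelse(y > 0, y * log(y / mu), 0)
  if (dispersion < 1e-10) {
    2 * sum(yl - (y - mu))
  } else {
    2 * sum(yl - (y + 1 / dispersion) *
              log((1 + dispersion * y) / (1 + dispersion * mu)))
  }
}

#' Fit one negative binomial GLM with log link and offsets
#'
#' Maximizes the NB2 log-likelihood at a fixed dispersion by iteratively
#' reweighted least squares with working weights `mu / (1 + dispersion*mu)`.
#' Convergence is declared when the relative deviance change falls below
#' `tol` (default 1e-8) within `maxit` iterations (default 100). A
#' dispersion of zero fits the Poisson model.
#'
#' @param y counts for one gene.
#' @param X design matrix (rows match `y`).
#' @param offset per-sample offsets on the log scale (log effective library
#'   sizes).
#' @param dispersion NB dispersion (>= 0).
#' @param beta_start optional warm-start coefficients.
#' @param tol,maxit convergence controls.
#' @return list: natural-log `coefficients`, `loglik`, `deviance`, `fitted`,
#'   `converged`, `iter`, `flag` (`"ok"` or `"all_zero"`).
#' @export
fit_nb_glm <- function(y, X, offset = rep(0, length(y)), dispersion = 0,
                       beta_start = NULL, tol = 1e-8, maxit = 100L) {
  stopifnot(length(y) == nrow(X), length(offset) == length(y),
            dispersion >= 0)
  p <- ncol(X)
  if (all(y == 0)) {
    return(list(coefficients = stats::setNames(rep(NA_real_, p), colnames(X)),
                loglik = NA_real_, deviance = NA_real_, fitted = rep(0, length(y)),
                converged = FALSE, iter = 0L, flag = "all_zero"))
  }
  if (is.null(beta_start)) {
    mu <- pmax(y, 1 / 6) * 0.5 + mean(y) * 0.5
    eta <- log(mu)
  } else {
    eta <- drop(X %*% beta_start) + offset
    eta <- clamp(eta, -30, 30)
    mu <- exp(eta)
  }
  dev <- nb_deviance(y, mu, dispersion)
  beta <- beta_start
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    w <- mu / (1 + dispersion * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    if (anyNA(beta)) {             # numerically singular weighted design
      beta[is.na(beta)] <- 0
    }
    eta <- clamp(drop(X %*% beta) + offset, -30, 30)
    mu <- exp(eta)
    dev_new <- nb_deviance(y, mu, dispersion)
    if (!is.finite(dev_new)) break
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
       loglik = nb_loglik(y, mu, dispersion), deviance = dev, fitted = mu,
       converged = converged, iter = iter, flag = "ok")
}

# Cox-Reid adjusted profile log-likelihood for one gene at one dispersion.
cr_apl <- function(y, X, offset, dispersion, beta_start = NULL) {
  fit <- fit_nb_glm(y, X, offset, dispersion, beta_start = beta_start,
                    tol = 1e-6, maxit = 50L)
  if (fit$flag != "ok") return(list(apl = -Inf, fit = fit))
  w <- fit$fitted / (1 + dispersion * fit$fitted)
  xtwx <- crossprod(X * sqrt(w))
  ld <- determinant(xtwx, logarithm = TRUE)$modulus
  list(apl = fit$loglik - 0.5 * as.numeric(ld), fit = fit)
}

# Average log2 CPM per gene with a prior count, on raw library sizes.
ave_log_cpm <- function(counts, prior_count = 2) {
  lib <- colSums(counts)
  pc <- prior_count * lib / mean(lib)
  rowMeans(log2(t((t(counts) + pc) * 1e6 / (lib + 2 * pc))))
}

#' Estimate per-gene NB dispersions with trend shrinkage
#'
#' Each gene's dispersion maximizes the Cox-Reid adjusted profile likelihood
#' (the NB log-likelihood penalized by half the log-determinant of the
#' weighted information, removing the bias from estimating the mean
#' coefficients) over log10 dispersion in \[-6, 1\] by bounded scalar search.
#' Gene-wise estimates are then shrunk on the log scale toward a
#' mean-dispersion trend (running median of estimates ordered by average log
#' CPM) with a fixed prior weight of `prior_df` degrees of freedom against
#' the gene's residual degrees of freedom. Genes with fewer positive counts
#' than design columns take the trend value directly.
#'
#' @param counts gene x sample matrix.
#' @param X design matrix used for the means.
#' @param offset log effective library sizes.
#' @param prior_df prior degrees of freedom of the trend (default 10).
#' @param trend shrink toward a running-median trend (default) or, if
#'   `FALSE`, toward the global median.
#' @return list: `dispersion` (shrunken, per gene), `raw` (unshrunken),
#'   `trend` (per gene).
#' @export
estimate_dispersion <- function(counts, X, offset = rep(0, ncol(counts)),
                                prior_df = 10, trend = TRUE) {
  assert_count_matrix(counts)
  stopifnot(nrow(X) == ncol(counts))
  if (ncol(counts) <= ncol(X))
    stop("need more samples than design columns to estimate dispersion")
  G <- nrow(counts)
  raw <- rep(NA_real_, G)
  estimable <- rowSums(counts > 0) > ncol(X)
  for (g in which(estimable)) {
    y <- counts[g, ]
    bs <- NULL                         # warm start across candidate dispersions
    opt <- stats::optimize(
      function(l10) {
        r <- cr_apl(y, X, offset, 10^l10, beta_start = bs)
        if (r$fit$flag == "ok" && !anyNA(r$fit$coefficients))
          bs <<- r$fit$coefficients
        r$apl
      },
      interval = c(-6, 1), maximum = TRUE, tol = 0.02
    )
    raw[g] <- 10^opt$maximum
  }
  # mean-dispersion trend: running median over genes ordered by abundance
  alc <- ave_log_cpm(counts)
  trend_val <- rep(stats::median(raw, na.rm = TRUE), G)
  ok <- !is.na(raw)
  if (trend && sum(ok) >= 20L) {
    o <- order(alc[ok])
    k <- max(5L, min(201L, 2L * floor(sum(ok) * 0.05) + 1L))
    sm <- stats::runmed(log10(raw[ok][o]), k = k, endrule = "median")
    tv <- numeric(sum(ok)); tv[o] <- sm
    trend_ok <- 10^tv
    # genes without their own estimate borrow the trend at their abundance
    trend_val[ok] <- trend_ok
    if (any(!ok)) {
      trend_val[!ok] <- 10^stats::approx(alc[ok][o], sm, xout = alc[!ok],
                                         rule = 2)$y
    }
  }
  d <- ncol(counts) - ncol(X)          # residual df per gene
  shrunk <- ifelse(ok,
                   10^((d * log10(pmax(raw, 1e-6)) +
                          prior_df * log10(pmax(trend_val, 1e-6))) /
                         (d + prior_df)),
                   trend_val)
  names(shrunk) <- names(raw) <- names(trend_val) <- rownames(counts)
  list(dispersion = shrunk, raw = raw, trend = trend_val)
}
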
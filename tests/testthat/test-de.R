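test_that("tertile assignment splits extremes deterministically", {
  td <- assign_tertiles(1:9, "x")
  expect_identical(which(td$group == "low"), 1:3)
  expect_identical(which(td$group == "excluded"), 4:6)
  expect_identical(which(td$group == "high"), 7:9)

  # study-sized cohort: extreme groups near n/3 each, vs a sort-and-slice
  # oracle
  set.seed(12)
  v <- rnorm(416)
  td2 <- assign_tertiles(v, "ldl_c")
  sizes <- tertile_sizes_oracle(v)
  expect_identical(sum(td2$group == "low"), as.integer(sizes["low"]))
  expect_identical(sum(td2$group == "high"), as.integer(sizes["high"]))
  expect_lte(abs(sum(td2$group == "low") - 139), 2)
  expect_lte(abs(sum(td2$group == "high") - 139), 2)

  # ties at the cutpoint fall to the lower bin
  td3 <- assign_tertiles(c(1, 1, 1, 2, 2, 2, 3, 3, 3), "x")
  expect_identical(as.character(td3$group[4:6]), rep("excluded", 3))

  expect_error(assign_tertiles(rep(1, 10), "x"), "distinct")
  expect_error(assign_tertiles(c(rep(1, 8), 2), "x"), "degenerate")
  expect_error(assign_tertiles(c(1, 2), "x"), "3 finite")
})

test_that("design matrices carry group, covariates and mediator columns", {
  set.seed(15)
  ph <- data.frame(
    sample_id = paste0("s", 1:9),
    ldl_c = 1:9, sdldl = c(5, 3, 6, 9, 2, 8, 4, 10, 7),
    age = c(30, 40, 50, 35, 45, 60, 28, 52, 47),
    sex = factor(rep(c("female", "male", "female"), 3),
                 levels = c("female", "male")),
    education = factor(rep("not_available", 9),
                       levels = sdldlmed:::education_levels),
    stringsAsFactors = FALSE
  )
  td <- assign_tertiles(1:9, "x")  # 3 low, 3 high
  dm <- build_design_matrix(ph, td, covariates = character())
  expect_identical(dim(dm$X), c(6L, 2L))
  expect_identical(unname(dm$X[, "group_high"]), c(0, 0, 0, 1, 1, 1))

  # single-level education collapses to dropped dummies with a warning
  expect_warning(
    dm2 <- build_design_matrix(ph, td, covariates = c("age", "sex",
                                                      "education")),
    "education")
  expect_true(all(c("age", "sex_male") %in% colnames(dm2$X)))
  expect_false(any(grepl("education", colnames(dm2$X))))

  # mediator enters as exactly one standardized column
  dm3 <- build_design_matrix(ph, td, covariates = c("age", "sex"),
                             extra_continuous = "sdldl")
  expect_identical(setdiff(colnames(dm3$X), colnames(dm2$X)), "sdldl")
  expect_equal(mean(dm3$X[, "sdldl"]), 0, tolerance = 1e-12)
  expect_equal(sd(dm3$X[, "sdldl"]), 1, tolerance = 1e-12)

  # collinearity is an error naming the offending column
  ph$dup <- ph$age
  expect_error(
    build_design_matrix(ph, td, covariates = "age",
                        extra_continuous = c("dup")),
    "collinear")
})

test_that("NB GLM reproduces closed-form and Poisson-limit fits", {
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  for (phi in c(0, 0.1, 1)) {
    fit <- fit_nb_glm(c(2, 4, 6), X, dispersion = phi)
    expect_true(fit$converged)
    expect_equal(unname(fit$fitted), rep(4, 3), tolerance = 1e-6)
  }
  # dispersion 0 equals an independent Poisson GLM
  set.seed(3)
  n <- 80
  Xf <- cbind(1, rbinom(n, 1, 0.5), rnorm(n))
  colnames(Xf) <- c("(Intercept)", "grp", "cov")
  off <- log(runif(n, 0.5, 2))
  y <- rpois(n, exp(off + 0.5 + 0.7 * Xf[, 2] - 0.3 * Xf[, 3]))
  ours <- fit_nb_glm(y, Xf, off, dispersion = 0)
  ref <- glm(y ~ Xf[, 2] + Xf[, 3] + offset(off), family = poisson())
  expect_equal(unname(ours$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(ours$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)

  # fixed-dispersion NB fit equals the classic NB family GLM
  skip_if_not_installed("MASS")
  phi <- 0.25
  y2 <- rnbinom(n, size = 1 / phi, mu = exp(off + 1 + 0.5 * Xf[, 2]))
  ours2 <- fit_nb_glm(y2, Xf[, 1:2], off, dispersion = phi)
  ref2 <- suppressWarnings(
    glm(y2 ~ Xf[, 2] + offset(off),
        family = MASS::negative.binomial(theta = 1 / phi)))
  expect_equal(unname(ours2$coefficients), unname(coef(ref2)),
               tolerance = 1e-5)

  # symmetry: identical group means give a near-zero group coefficient
  yg <- rep(c(5, 9, 13), 2)
  Xg <- cbind(1, rep(c(0, 1), each = 3))
  colnames(Xg) <- c("(Intercept)", "grp")
  fg <- fit_nb_glm(yg, Xg, dispersion = 0.1)
  expect_equal(unname(fg$coefficients["grp"]), 0, tolerance = 1e-8)

  # all-zero response is flagged
  expect_identical(fit_nb_glm(rep(0, 3), X)$flag, "all_zero")
})

test_that("dispersion estimation recovers known values", {
  set.seed(99)
  n <- 200; G <- 60
  X <- cbind(1, rep(c(0, 1), each = n / 2))
  colnames(X) <- c("(Intercept)", "grp")
  mu <- exp(rnorm(G, log(50), 0.5))
  # Poisson counts: estimates should collapse toward zero
  cp <- t(sapply(mu, function(m) rpois(n, m)))
  dimnames(cp) <- list(paste0("g", 1:G), paste0("s", 1:n))
  est_p <- estimate_dispersion(cp, X, trend = FALSE)
  expect_lt(median(est_p$raw, na.rm = TRUE), 0.01)
  # NB with dispersion 0.1
  cn <- t(sapply(mu, function(m) rnbinom(n, size = 10, mu = m)))
  dimnames(cn) <- dimnames(cp)
  est_n <- estimate_dispersion(cn, X, trend = FALSE)
  expect_gt(median(est_n$raw, na.rm = TRUE), 0.07)
  expect_lt(median(est_n$raw, na.rm = TRUE), 0.13)
  # constant counts sit at the lower search bound
  cc <- matrix(7L, 4, n, dimnames = list(paste0("k", 1:4), colnames(cp)))
  est_c <- estimate_dispersion(rbind(cc, cn[1:30, ]), X)
  expect_lt(max(est_c$raw[1:4]), 1e-4)
})

test_that("BH adjustment matches closed form and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.4)), "0, 1")
  set.seed(6)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    p <- pmin(pmax(p, 1e-12), 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("tertile DE is sign-symmetric, depth-invariant and edgeR-consistent", {
  co <- small_cohort(seed = 17, n_samples = 150, n_genes = 250,
                     frac_null = 0.7, frac_direct_only = 0.15,
                     frac_mediated = 0.15)
  cts <- filter_low_expression(co$counts)
  de <- lrt_de(cts, co$phenotypes, "ldl_c")
  expect_true(all(de$fdr_adjusted_p >= de$p_value - 1e-15))
  expect_true(all(de$lrt_stat >= 0))
  expect_identical(de$direction, ifelse(de$logFC > 0, "up", "down"))
  expect_false(is.unsorted(de$p_value))

  # flipping the phenotype swaps the tertile groups: logFC negates,
  # p-values are preserved
  ph_flip <- co$phenotypes
  ph_flip$ldl_c <- -ph_flip$ldl_c + 2 * mean(ph_flip$ldl_c)
  de_flip <- lrt_de(cts, ph_flip, "ldl_c",
                    dispersions = attr(de, "dispersions"))
  m <- match(de$gene_id, de_flip$gene_id)
  expect_equal(de_flip$logFC[m], -de$logFC, tolerance = 1e-4)
  expect_equal(de_flip$p_value[m], de$p_value, tolerance = 1e-4)

  # doubling every count (and hence library size) leaves logFC stable
  de2 <- lrt_de(cts * 2L, co$phenotypes, "ldl_c",
                dispersions = attr(de, "dispersions"))
  m2 <- match(de$gene_id, de2$gene_id)
  expect_equal(de2$logFC[m2], de$logFC, tolerance = 0.02)

  # constant target phenotype cannot define tertiles
  ph_const <- co$phenotypes
  ph_const$ldl_c <- rep(1, nrow(ph_const))
  expect_error(lrt_de(cts, ph_const, "ldl_c"), "distinct")
  expect_error(lrt_de(cts, co$phenotypes, "nope"), "not found")

  # independent route: edgeR's NB LRT on the same contrast ranks genes the
  # same way (methods differ in dispersion details, not in substance)
  skip_if_not_installed("edgeR")
  td <- assign_tertiles(co$phenotypes$ldl_c, "ldl_c")
  keep <- td$group != "excluded"
  dge <- edgeR::DGEList(cts[, keep])
  dge <- edgeR::calcNormFactors(dge)
  grp <- droplevels(td$group[keep])
  Xe <- model.matrix(~ grp)
  dge <- edgeR::estimateDisp(dge, Xe)
  fit <- edgeR::glmFit(dge, Xe)
  lrt <- edgeR::glmLRT(fit, coef = 2)
  de_plain <- lrt_de(cts, co$phenotypes, "ldl_c", covariates = character())
  mm <- match(de_plain$gene_id, rownames(lrt$table))
  expect_gt(cor(de_plain$logFC, lrt$table$logFC[mm]), 0.98)
  expect_gt(cor(log10(de_plain$p_value),
                log10(pmax(lrt$table$PValue[mm], 1e-300))), 0.95)
})
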
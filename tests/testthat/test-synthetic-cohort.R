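test_that("phenotype simulation is reproducible and respects invariants", {
  cfg <- sim_config(n_samples = 500, seed = 42)
  ph1 <- simulate_phenotypes(cfg)
  ph2 <- simulate_phenotypes(cfg)
  expect_identical(ph1, ph2)
  expect_false(anyDuplicated(ph1$sample_id) > 0)
  expect_true(all(ph1$ldl_c > 0))
  expect_true(all(ph1$sdldl > 0))
  expect_true(all(ph1$age > 0))
  expect_true(all(levels(ph1$sex) == c("female", "male")))
  expect_setequal(levels(ph1$education),
                  c("<=high_school", "some_college", "college_grad",
                    ">graduate", "not_available"))
})

test_that("phenotype moments and LDL-sdLDL correlation are calibrated", {
  ph <- simulate_phenotypes(sim_config(n_samples = 30000, seed = 2))
  expect_lt(abs(mean(ph$ldl_c) - 105) / 105, 0.01)
  expect_lt(abs(sd(ph$ldl_c) - 33) / 33, 0.02)
  expect_lt(abs(cor(ph$ldl_c, ph$sdldl) - 0.4), 0.015)
  # independence case
  ph0 <- simulate_phenotypes(sim_config(n_samples = 30000,
                                        mediator_slope = 0, seed = 3))
  expect_lt(abs(cor(ph0$ldl_c, ph0$sdldl)), 0.015)
})

test_that("sdLDL calibration reaches requested population moments", {
  for (rho in c(-0.3, 0, 0.4, 0.7)) {
    cal <- calibrate_sdldl_model(477, 333, rho)
    expect_equal(unname(cal$achieved["corr"]), rho, tolerance = 1e-3)
    expect_equal(unname(cal$achieved["mean"]), 477, tolerance = 0.5)
    expect_equal(unname(cal$achieved["sd"]), 333, tolerance = 0.5)
  }
  expect_error(calibrate_sdldl_model(477, -1, 0.4), "positive")
  expect_error(calibrate_sdldl_model(477, 333, 1.2), "in \\(-1, 1\\)")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(ldl_sd = 0), "positive")
  expect_error(sim_config(mediator_slope = 1), "-1, 1")
  expect_error(sim_config(frac_null = 0.9, frac_direct_only = 0.2),
               "sum to at most 1")
  expect_error(sim_config(education_probs = rep(0.2, 4)), "5 non-negative")
})

test_that("count simulation is reproducible with integer NB counts", {
  co <- small_cohort(seed = 9)
  co2 <- small_cohort(seed = 9)
  expect_identical(co$counts, co2$counts)
  expect_identical(co$truth, co2$truth)
  expect_true(all(co$counts >= 0))
  expect_true(all(co$counts == round(co$counts)))
  expect_identical(dim(co$counts), c(300L, 160L))
  # truth invariants
  nulls <- co$truth$class == "null"
  expect_true(all(co$truth$beta_direct[nulls] == 0))
  expect_true(all(co$truth$beta_mediator[nulls] == 0))
  expect_true(all(is.na(co$truth$true_pm[nulls])))
  med <- co$truth$class == "mediated"
  expect_true(all(co$truth$beta_direct[med] == 0))
  expect_true(all(co$truth$true_pm[med] == 100))
})

test_that("counts are overdispersed relative to Poisson when dispersion > 0", {
  # constant mean per gene: no phenotype effects, fixed library sizes
  cfg <- sim_config(n_samples = 4000, n_genes = 40, frac_null = 1,
                    frac_direct_only = 0, frac_mediated = 0,
                    dispersion_shape = 20, dispersion_scale = 0.01,
                    lib_size_log_sd = 0, age_effect_sd = 0,
                    sex_effect_sd = 0, seed = 13)
  co <- simulate_counts(simulate_phenotypes(cfg), cfg)
  mu <- rowMeans(co$counts)
  v <- apply(co$counts, 1, var)
  ratio <- v / mu
  expect_gt(median(ratio[mu > 5]), 1.05)
})

test_that("null genes show log-CPM slopes on LDL-C centered at zero", {
  co <- small_cohort(seed = 21, n_samples = 300, frac_null = 1,
                     frac_direct_only = 0, frac_mediated = 0)
  cpm <- compute_cpm(co$counts)
  z <- scale(co$phenotypes$ldl_c)[, 1]
  keep <- rowMeans(cpm) > 5
  slopes <- apply(log2(cpm[keep, ] + 0.5), 1, function(y) {
    sum((y - mean(y)) * z) / sum(z^2)
  })
  # mean slope indistinguishable from zero at the simulation's precision
  expect_lt(abs(mean(slopes)) / (sd(slopes) / sqrt(length(slopes))), 4)
})

test_that("ground-truth proportion mediated follows the path decomposition", {
  expect_equal(true_proportion_mediated(1, 0, 0.4), 0)
  expect_equal(true_proportion_mediated(0, 1, 0.4), 100)
  expect_equal(true_proportion_mediated(0.3, 0.75, 0.4), 50)
  expect_true(is.na(true_proportion_mediated(0, 0, 0.4)))
  # clamping: opposing paths
  expect_equal(true_proportion_mediated(-0.1, 1, 0.4), 100)

  # independent OLS oracle: regress a noiseless linear outcome on the
  # simulated phenotypes with and without the mediator at large n
  ph <- simulate_phenotypes(sim_config(n_samples = 200000, seed = 77))
  zl <- scale(ph$ldl_c)[, 1]; zs <- scale(ph$sdldl)[, 1]
  bd <- 0.3; bm <- 0.75
  eta <- bd * zl + bm * zs
  total <- coef(lm(eta ~ zl))[["zl"]]
  direct <- coef(lm(eta ~ zl + zs))[["zl"]]
  pm_ols <- 100 * (1 - direct / total)
  expect_equal(pm_ols, 50, tolerance = 2)
  expect_equal(true_proportion_mediated(bd, bm, 0.4), 50, tolerance = 1e-12)
})
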
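#' Simulation configuration for the synthetic cohort
#'
#' Bundles and validates every tunable of the synthetic cohort generator.
#' Defaults reproduce the study conditions the generator is calibrated to:
#' LDL-C mean 105, SD 33 mg/dL; sdLDL mean 477, SD 333 assay units with a
#' Pearson correlation of 0.4 to LDL-C; age mean 48, SD 12 years; 69% female;
#' the five-level education margin including an explicit "not_available"
#' level; and 10% lipid-lowering medication use.
#'
#' Gene expression is generated as negative binomial counts whose log-mean
#' depends on standardized LDL-C directly (`beta_direct`) and through
#' standardized sdLDL (`beta_mediator`); see [simulate_counts()].
#'
#' @param n_samples number of cohort samples.
#' @param n_genes number of genes.
#' @param ldl_mean,ldl_sd LDL-C moments in mg/dL (truncated at zero).
#' @param sdldl_mean,sdldl_sd target sdLDL moments after zero-truncation, in
#'   assay units (the magnitudes printed for this assay suggest NMR particle
#'   counts in nmol/L rather than mg/dL; the generator treats the units as
#'   opaque).
#' @param mediator_slope target Pearson correlation between LDL-C and sdLDL;
#'   equivalently the slope of standardized sdLDL on standardized LDL-C, the
#'   `a` path of the mediation model. Must lie in (-1, 1).
#' @param prop_female proportion of female samples.
#' @param age_mean,age_sd age moments in years (truncated at zero).
#' @param education_probs probabilities of the five education levels, in the
#'   order `<=high_school, some_college, college_grad, >graduate,
#'   not_available`.
#' @param lipid_med_prob probability of lipid-lowering medication use.
#' @param frac_null,frac_direct_only,frac_mediated gene-class proportions;
#'   the remainder to 1 is the `mixed` class (both paths active).
#' @param direct_effect_sd,mediated_effect_sd typical magnitude (natural-log
#'   scale per phenotype SD) of the per-gene direct and mediated coefficients;
#'   magnitudes are drawn log-normally around these values with log-SD 0.3 and
#'   a random sign.
#' @param dispersion_shape,dispersion_scale gamma parameters of the per-gene
#'   NB dispersion distribution (defaults give mean dispersion 0.1).
#' @param lib_size_log_mean,lib_size_log_sd log-normal library size
#'   parameters.
#' @param age_effect_sd,sex_effect_sd SDs of small per-gene age (per SD of
#'   age) and sex (male shift) nuisance coefficients, so covariate adjustment
#'   is exercised without dominating.
#' @param baseline_log_sd SD of the per-gene baseline log relative abundance.
#' @param seed integer seed; all stage seeds are derived from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 400L, n_genes = 2000L,
                       ldl_mean = 105, ldl_sd = 33,
                       sdldl_mean = 477, sdldl_sd = 333,
                       mediator_slope = 0.4,
                       prop_female = 0.69,
                       age_mean = 48, age_sd = 12,
                       education_probs = c(0.06, 0.15, 0.17, 0.20, 0.42),
                       lipid_med_prob = 0.10,
                       frac_null = 0.90, frac_direct_only = 0.04,
                       frac_mediated = 0.04,
                       direct_effect_sd = 0.20, mediated_effect_sd = 0.35,
                       dispersion_shape = 2, dispersion_scale = 0.05,
                       lib_size_log_mean = log(2e6), lib_size_log_sd = 0.3,
                       age_effect_sd = 0.02, sex_effect_sd = 0.05,
                       baseline_log_sd = 1.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_samples >= 2, n_genes >= 1)
    if (ldl_sd <= 0 || sdldl_sd <= 0 || age_sd <= 0)
      stop("phenotype SDs must be positive")
    if (abs(mediator_slope) >= 1)
      stop("mediator_slope (target correlation) must lie in (-1, 1)")
    fracs <- c(frac_null, frac_direct_only, frac_mediated)
    if (any(fracs < 0) || any(fracs > 1) || sum(fracs) > 1 + 1e-12)
      stop("gene-class fractions must lie in [0,1] and sum to at most 1")
    if (length(education_probs) != 5L || any(education_probs < 0))
      stop("education_probs must be 5 non-negative probabilities")
    if (abs(sum(education_probs) - 1) > 1e-6)
      stop("education_probs must sum to 1")
    stopifnot(prop_female >= 0, prop_female <= 1,
              lipid_med_prob >= 0, lipid_med_prob <= 1,
              dispersion_shape > 0, dispersion_scale >= 0,
              direct_effect_sd >= 0, mediated_effect_sd >= 0)
  })
  cfg$n_samples <- as.integer(cfg$n_samples)
  cfg$n_genes <- as.integer(cfg$n_genes)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

# Moments of a normal(mu, sig) truncated below at 0, per quadrature node.
trunc0_moments <- function(mu, sig) {
  alpha <- -mu / sig
  lam <- exp(stats::dnorm(alpha, log = TRUE) -
               stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sig * lam
  v <- sig^2 * (1 + alpha * lam - lam^2)
  list(mean = m, var = pmax(v, 0))
}

#' Calibrate the zero-truncated sdLDL model
#'
#' The generator draws sdLDL conditional on standardized LDL-C `z` as a
#' normal truncated below at zero. Truncation shifts the marginal mean,
#' shrinks the SD, and attenuates the correlation, so the *pre*-truncation
#' parameters are solved numerically (Gauss-grid quadrature over `z` plus
#' Nelder-Mead) such that the *post*-truncation population mean, SD and
#' Pearson correlation with `z` equal the requested targets.
#'
#' @param mean_target,sd_target,corr_target post-truncation population
#'   moments to achieve.
#' @return list with pre-truncation `mu0`, `sigma0`, `rho0` and the achieved
#'   moments.
#' @export
calibrate_sdldl_model <- function(mean_target, sd_target, corr_target) {
  if (sd_target <= 0) stop("sd_target must be positive")
  if (abs(corr_target) >= 1) stop("corr_target must lie in (-1, 1)")
  # negligible truncation mass: identity calibration
  if (stats::pnorm(0, mean_target, sd_target) < 1e-8)
    return(list(mu0 = mean_target, sigma0 = sd_target, rho0 = corr_target,
                achieved = c(mean = mean_target, sd = sd_target,
                             corr = corr_target)))
  z <- seq(-8, 8, length.out = 801L)
  w <- stats::dnorm(z); w <- w / sum(w)
  moments <- function(par) {
    mu0 <- par[1L]; s0 <- exp(par[2L]); r0 <- tanh(par[3L])
    mu_c <- mu0 + s0 * r0 * z
    s_c <- s0 * sqrt(1 - r0^2)
    tm <- trunc0_moments(mu_c, s_c)
    m <- sum(w * tm$mean)
    ez2 <- sum(w * (tm$var + tm$mean^2))
    v <- ez2 - m^2
    cz <- sum(w * z * tm$mean)          # Cov(z, S); Var(z)=1
    c(mean = m, sd = sqrt(max(v, 0)), corr = cz / sqrt(max(v, 1e-12)))
  }
  target <- c(mean_target, sd_target, corr_target)
  obj <- function(par) {
    m <- moments(par)
    sum(((m - target) / c(sd_target, sd_target, 1))^2)
  }
  start <- c(mean_target, log(sd_target), atanh(corr_target))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-14))
  got <- moments(fit$par)
  if (abs(got["corr"] - corr_target) > 1e-3 ||
      abs(got["mean"] - mean_target) / sd_target > 1e-3)
    stop("sdLDL calibration failed to reach the requested moments; ",
         "the target correlation/moments may be infeasible under ",
         "zero-truncation")
  list(mu0 = fit$par[1L], sigma0 = exp(fit$par[2L]), rho0 = tanh(fit$par[3L]),
       achieved = got)
}

#' Simulate the phenotype table of a synthetic cohort
#'
#' LDL-C is drawn from a zero-truncated normal; sdLDL is linear in
#' standardized LDL-C plus independent normal noise, truncated at zero, with
#' pre-truncation coefficients calibrated (see [calibrate_sdldl_model()]) so
#' the population mean, SD and correlation with LDL-C equal the configured
#' targets. Age, sex, education and medication use are drawn from the
#' configured margins.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with columns `sample_id`, `ldl_c`, `sdldl`, `age`,
#'   `sex`, `education`, `on_lipid_med`.
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "phenotypes"))
  n <- config$n_samples

  # zero-truncated normals by inverse-CDF so a fixed seed is reproducible
  rtnorm0 <- function(n, mu, sig) {
    lo <- stats::pnorm(0, mu, sig)
    stats::qnorm(lo + stats::runif(n) * (1 - lo), mu, sig)
  }
  ldl <- rtnorm0(n, config$ldl_mean, config$ldl_sd)
  z <- (ldl - config$ldl_mean) / config$ldl_sd

  cal <- calibrate_sdldl_model(config$sdldl_mean, config$sdldl_sd,
                               config$mediator_slope)
  mu_c <- cal$mu0 + cal$sigma0 * cal$rho0 * z
  s_c <- cal$sigma0 * sqrt(1 - cal$rho0^2)
  sdldl <- rtnorm0(n, mu_c, s_c)

  age <- rtnorm0(n, config$age_mean, config$age_sd)
  sex <- factor(ifelse(stats::runif(n) < config$prop_female,
                       "female", "male"), levels = sex_levels)
  education <- factor(sample(education_levels, n, replace = TRUE,
                             prob = config$education_probs),
                      levels = education_levels)
  on_lipid_med <- stats::runif(n) < config$lipid_med_prob

  data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    ldl_c = ldl, sdldl = sdldl, age = age,
    sex = sex, education = education, on_lipid_med = on_lipid_med,
    stringsAsFactors = FALSE
  )
}

#' Ground-truth proportion mediated
#'
#' For per-SD-standardized phenotypes the total LDL-C effect on a gene's
#' log-mean decomposes as direct + mediated: `beta_direct +
#' beta_mediator * a`, where `a` is the slope of standardized sdLDL on
#' standardized LDL-C. The ground-truth proportion mediated is the mediated
#' share of the total, as a percentage clamped to \[0, 100\]; it is undefined
#' (`NA`) when the total effect is zero.
#'
#' @param truth a `SimulationTruth` data.frame from [simulate_counts()], or a
#'   numeric vector of direct effects.
#' @param beta_mediator,mediator_slope used when `truth` is a numeric vector
#'   of direct effects; `mediator_slope` defaults to the value recorded in
#'   `attr(truth, "mediator_slope")`.
#' @return percent mediated per gene in \[0, 100\], `NA` where undefined.
#' @export
true_proportion_mediated <- function(truth, beta_mediator = NULL,
                                     mediator_slope = NULL) {
  if (is.data.frame(truth)) {
    bd <- truth$beta_direct
    bm <- truth$beta_mediator
    a <- mediator_slope %||% attr(truth, "mediator_slope")
  } else {
    bd <- truth; bm <- beta_mediator; a <- mediator_slope
  }
  if (is.null(a)) stop("mediator_slope not supplied and not found on truth")
  total <- bd + bm * a
  # grouping (x/total) first keeps the pure-mediation limit exactly 100
  pm <- ifelse(total == 0, NA_real_, 100 * ((bm * a) / total))
  clamp(pm, 0, 100)
}

#' Simulate negative binomial read counts with planted mediation structure
#'
#' For gene `g` and sample `i`, counts are drawn NB with mean
#' `mu_gi = L_i * exp(b0_g + bd_g * z(ldl_i) + bm_g * z(sdldl_i) + nuisance)`
#' and gene dispersion `phi_g`, where `L_i` is a log-normal library-size
#' factor, `z()` standardizes empirically over the cohort, and the nuisance
#' term holds small per-gene age and sex effects. Genes are partitioned into
#' `null` (both coefficients zero), `direct_only`, `mediated` (direct path
#' zero) and `mixed` classes.
#'
#' @param phenotypes a phenotype table from [simulate_phenotypes()].
#' @param config the same [sim_config()].
#' @return list with `counts` (integer gene x sample matrix) and `truth`
#'   (per-gene data.frame: `gene_id`, `class`, `beta_direct`,
#'   `beta_mediator`, `dispersion`, `true_pm`), with the `a` path stored in
#'   `attr(truth, "mediator_slope")`.
#' @export
simulate_counts <- function(phenotypes, config) {
  stopifnot(inherits(config, "sim_config"), nrow(phenotypes) >= 2)
  set.seed(derive_seed(config$seed, "counts"))
  n <- nrow(phenotypes); G <- config$n_genes

  n_dir <- floor(config$frac_direct_only * G)
  n_med <- floor(config$frac_mediated * G)
  n_mixed <- floor(max(0, 1 - config$frac_null - config$frac_direct_only -
                         config$frac_mediated) * G)
  n_null <- G - n_dir - n_med - n_mixed
  stopifnot(n_null >= 0)
  classes <- sample(rep(c("null", "direct_only", "mediated", "mixed"),
                        c(n_null, n_dir, n_med, n_mixed)))

  # effect magnitudes log-normal around the configured typical size, random sign
  draw_effect <- function(k, typical) {
    if (k == 0L) return(numeric(0))
    sample(c(-1, 1), k, replace = TRUE) * typical * exp(stats::rnorm(k, 0, 0.3))
  }
  bd <- numeric(G); bm <- numeric(G)
  i_dir <- classes %in% c("direct_only", "mixed")
  i_med <- classes %in% c("mediated", "mixed")
  bd[i_dir] <- draw_effect(sum(i_dir), config$direct_effect_sd)
  bm[i_med] <- draw_effect(sum(i_med), config$mediated_effect_sd)

  phi <- stats::rgamma(G, shape = config$dispersion_shape,
                       scale = config$dispersion_scale)
  b0 <- stats::rnorm(G, 0, config$baseline_log_sd)
  b0 <- b0 - log(sum(exp(b0)))          # log relative abundance, sums to 1
  age_coef <- stats::rnorm(G, 0, config$age_effect_sd)
  sex_coef <- stats::rnorm(G, 0, config$sex_effect_sd)

  L <- stats::rlnorm(n, config$lib_size_log_mean, config$lib_size_log_sd)
  zl <- zstd(phenotypes$ldl_c)
  zs <- zstd(phenotypes$sdldl)
  za <- zstd(phenotypes$age)
  male <- as.numeric(phenotypes$sex == "male")

  eta <- outer(b0, log(L), `+`) +
    outer(bd, zl) + outer(bm, zs) + outer(age_coef, za) + outer(sex_coef, male)
  mu <- exp(pmin(eta, 30))
  counts <- matrix(0L, G, n)
  pois <- phi < 1e-12
  if (any(pois))
    counts[pois, ] <- stats::rpois(sum(pois) * n, mu[pois, , drop = FALSE])
  if (any(!pois))
    counts[!pois, ] <- stats::rnbinom(sum(!pois) * n,
                                      size = rep(1 / phi[!pois], n),
                                      mu = mu[!pois, , drop = FALSE])
  gene_ids <- sprintf("g%05d", seq_len(G))
  dimnames(counts) <- list(gene_ids, phenotypes$sample_id)
  if (max(counts) < .Machine$integer.max) storage.mode(counts) <- "integer"

  truth <- data.frame(
    gene_id = gene_ids, class = classes,
    beta_direct = bd, beta_mediator = bm, dispersion = phi,
    stringsAsFactors = FALSE
  )
  attr(truth, "mediator_slope") <- config$mediator_slope
  truth$true_pm <- true_proportion_mediated(truth)
  list(counts = counts, truth = truth)
}
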
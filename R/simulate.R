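# Synthetic-cohort generator.
#
# Structural model (all variants independent, Hardy-Weinberg):
#   Z_j ~ Binomial(2, maf_j)                     instruments / other variants
#   M   ~ per-config distributions               measured confounders
#   L   = sum_j gamma_j (Z_j - 2 maf_j) + alpha' Mstd + V,  V ~ N(0, sd_V^2)
#   D   = 1{L > tau},  tau the empirical quantile hitting the target prevalence
#   P(Y=1 | .) = r0 * exp(beta_L * L + delta' Mstd + sum_j pi_j Z_j)
# with gamma rescaled so Var(sum_j gamma_j Z_j) = theta2 and
# sd_V^2 = 1 - theta2 - Var(alpha' Mstd), making Var(L) = 1. Confounders
# enter standardized by their theoretical moments so alpha and delta are
# per-SD effects. pi_j are direct (exclusion-restriction-violating)
# pleiotropic log-RR effects on the outcome; a variant may instead shift a
# named confounder, the via-confounder pleiotropy pathway.

#' Specify a measured confounder for simulation
#'
#' @param name Confounder name (column name in the phenotype table).
#' @param dist One of `"normal"`, `"bernoulli"`, `"lognormal"`.
#' @param mean,sd Parameters for `dist = "normal"`.
#' @param prob Success probability for `dist = "bernoulli"`.
#' @param meanlog,sdlog Parameters for `dist = "lognormal"`.
#' @param type `"continuous"` or `"categorical"` — how the confounder
#'   screen will test it (Spearman vs chi-square).
#' @param effect_liability Effect on the exposure liability per 1 SD of the
#'   confounder (liability-SD units).
#' @param effect_outcome Log relative risk of the outcome per 1 SD of the
#'   confounder.
#' @return A `confounder_spec` list.
#' @export
confounder_spec <- function(name, dist = c("normal", "bernoulli", "lognormal"),
                            mean = 0, sd = 1, prob = 0.5,
                            meanlog = 0, sdlog = 1,
                            type = if (dist[1] == "bernoulli") "categorical"
                                   else "continuous",
                            effect_liability = 0, effect_outcome = 0) {
  dist <- match.arg(dist)
  stopifnot(type %in% c("continuous", "categorical"))
  structure(list(name = name, dist = dist, mean = mean, sd = sd, prob = prob,
                 meanlog = meanlog, sdlog = sdlog, type = type,
                 effect_liability = effect_liability,
                 effect_outcome = effect_outcome),
            class = "confounder_spec")
}

conf_moments <- function(spec) {
  switch(spec$dist,
    normal = c(mean = spec$mean, sd = spec$sd),
    bernoulli = c(mean = spec$prob, sd = sqrt(spec$prob * (1 - spec$prob))),
    lognormal = {
      m <- exp(spec$meanlog + spec$sdlog^2 / 2)
      c(mean = m, sd = m * sqrt(exp(spec$sdlog^2) - 1))
    })
}

draw_confounder <- function(spec, n) {
  switch(spec$dist,
    normal = stats::rnorm(n, spec$mean, spec$sd),
    bernoulli = stats::rbinom(n, 1L, spec$prob),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog))
}

#' Build and validate a simulation configuration
#'
#' @param n_individuals Cohort size.
#' @param snps Data frame with one row per variant: `id`, `maf` in (0,1),
#'   `gamma` (relative liability weight; rescaled internally so the genetic
#'   share of liability variance equals `theta2`), and optionally
#'   `pleiotropy_outcome` (direct log-RR on the outcome per allele),
#'   `pleiotropy_confounder` (name of a confounder the variant shifts, or
#'   `NA`) and `pleiotropy_confounder_effect` (shift in confounder SDs per
#'   allele, default 0).
#' @param theta2 Liability heritability: fraction of liability variance
#'   carried by the modelled variants, in `[0, 1)`.
#' @param exposure_prevalence Target marginal prevalence of the binary
#'   exposure, in (0,1).
#' @param beta_liability Log relative risk of the outcome per 1 SD of
#'   exposure liability (the causal effect the estimators target).
#' @param outcome_baseline_risk Baseline outcome risk `r0`, in (0,1). Give
#'   either this or `outcome_target_prevalence`.
#' @param outcome_target_prevalence If supplied, `r0` is solved at
#'   simulation time so the marginal outcome prevalence matches this target;
#'   the realized baseline is recorded in `true_parameters`.
#' @param confounders List of [confounder_spec()] objects (possibly empty).
#' @param missing_genotype_rate Completely-at-random missing-call rate in
#'   `[0, 1)`.
#' @param exposure_name,outcome_name Column names used in the phenotype
#'   table.
#' @param seed Integer seed governing all randomness in
#'   [simulate_cohort()].
#' @return A validated `simulation_config` object.
#' @export
simulation_config <- function(n_individuals, snps, theta2,
                              exposure_prevalence, beta_liability,
                              outcome_baseline_risk = NULL,
                              outcome_target_prevalence = NULL,
                              confounders = list(),
                              missing_genotype_rate = 0,
                              exposure_name = "exposure",
                              outcome_name = "outcome",
                              seed = 1L) {
  snps <- as.data.frame(snps)
  stopifnot(all(c("id", "maf", "gamma") %in% names(snps)))
  if (is.null(snps$pleiotropy_outcome)) snps$pleiotropy_outcome <- 0
  if (is.null(snps$pleiotropy_confounder))
    snps$pleiotropy_confounder <- NA_character_
  if (is.null(snps$pleiotropy_confounder_effect))
    snps$pleiotropy_confounder_effect <- 0
  snps$id <- as.character(snps$id)
  if (anyDuplicated(snps$id)) stop("duplicate SNP ids in config")
  if (any(snps$maf <= 0 | snps$maf >= 1)) stop("maf must lie in (0,1)")
  if (!(theta2 >= 0 && theta2 < 1)) stop("theta2 must lie in [0,1)")
  if (!(exposure_prevalence > 0 && exposure_prevalence < 1))
    stop("exposure_prevalence must lie in (0,1)")
  if (is.null(outcome_baseline_risk) == is.null(outcome_target_prevalence))
    stop("give exactly one of outcome_baseline_risk or ",
         "outcome_target_prevalence")
  for (r in c(outcome_baseline_risk, outcome_target_prevalence))
    if (!(r > 0 && r < 1)) stop("outcome risk/prevalence must lie in (0,1)")
  if (!(missing_genotype_rate >= 0 && missing_genotype_rate < 1))
    stop("missing_genotype_rate must lie in [0,1)")
  if (length(confounders)) {
    stopifnot(all(vapply(confounders, inherits, TRUE, "confounder_spec")))
    names(confounders) <- vapply(confounders, `[[`, "", "name")
  }
  bad_pc <- !is.na(snps$pleiotropy_confounder) &
    !(snps$pleiotropy_confounder %in% names(confounders))
  if (any(bad_pc))
    stop("pleiotropy_confounder names unknown confounder: ",
         paste(snps$pleiotropy_confounder[bad_pc], collapse = ", "))

  # rescale gamma so the genetic share of liability variance is theta2
  var_per_snp <- snps$gamma^2 * 2 * snps$maf * (1 - snps$maf)
  g2_raw <- sum(var_per_snp)
  if (theta2 > 0 && g2_raw <= 0)
    stop("theta2 > 0 requires at least one SNP with nonzero gamma")
  snps$gamma_scaled <- if (theta2 > 0) snps$gamma * sqrt(theta2 / g2_raw)
                       else 0 * snps$gamma
  alpha <- vapply(confounders, `[[`, 0, "effect_liability")
  c2 <- sum(alpha^2)
  if (theta2 + c2 >= 1)
    stop("theta2 + confounder liability variance (", round(theta2 + c2, 3),
         ") must be < 1; reduce effect_liability values")
  structure(list(
    n_individuals = as.integer(n_individuals), snps = snps, theta2 = theta2,
    exposure_prevalence = exposure_prevalence,
    beta_liability = beta_liability,
    outcome_baseline_risk = outcome_baseline_risk,
    outcome_target_prevalence = outcome_target_prevalence,
    confounders = confounders,
    missing_genotype_rate = missing_genotype_rate,
    exposure_name = exposure_name, outcome_name = outcome_name,
    sd_environment = sqrt(1 - theta2 - c2),
    seed = as.integer(seed)), class = "simulation_config")
}

#' Calibrate the liability threshold for a target prevalence
#'
#' Returns the empirical threshold `tau` such that the fraction of
#' liabilities strictly above `tau` is the closest achievable to the target
#' prevalence; `tau` is the corresponding order statistic of the sample.
#'
#' @param liabilities Numeric vector of latent liabilities (non-degenerate).
#' @param target_prevalence Target fraction above threshold, in (0,1).
#' @return The threshold `tau`.
#' @export
#' @examples
#' calibrate_threshold(c(-2, -1, 0, 1, 2), 0.5)  # the median, 0
calibrate_threshold <- function(liabilities, target_prevalence) {
  stopifnot(is.numeric(liabilities), length(liabilities) > 1)
  if (!(target_prevalence > 0 && target_prevalence < 1))
    stop("target_prevalence must lie in (0,1)")
  if (max(liabilities) == min(liabilities))
    stop("liabilities are constant: threshold is not identifiable")
  n <- length(liabilities)
  m <- min(max(round(n * target_prevalence), 0L), n - 1L)
  sort(liabilities, decreasing = TRUE)[m + 1L]
}

#' Simulate a cohort under the liability-threshold / log-linear model
#'
#' Draws genotypes, confounders, latent liability, the thresholded binary
#' exposure and the log-linear binary outcome per the configuration; fully
#' deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort`: list with `genotypes` (a
#'   [genotype_matrix()] with missing calls injected), `phenotypes` (data
#'   frame: `sample_id`, exposure, outcome, confounders), `liability` (the
#'   latent vector, for diagnostics), and `true_parameters` (the config plus
#'   realized threshold, baseline risk and prevalences).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  snps <- config$snps
  p <- nrow(snps)

  Z <- matrix(0, n, p, dimnames = list(NULL, snps$id))
  for (j in seq_len(p)) Z[, j] <- stats::rbinom(n, 2L, snps$maf[j])

  # confounders: raw draws + standardized versions (theoretical moments)
  Mstd <- matrix(0, n, length(config$confounders))
  Mraw <- data.frame(row.names = seq_len(n))
  if (length(config$confounders)) {
    colnames(Mstd) <- names(config$confounders)
    for (k in seq_along(config$confounders)) {
      sp <- config$confounders[[k]]
      x <- draw_confounder(sp, n)
      mo <- conf_moments(sp)
      Mstd[, k] <- (x - mo["mean"]) / mo["sd"]
    }
    # via-confounder pleiotropy: variant shifts the named confounder
    for (j in which(!is.na(snps$pleiotropy_confounder))) {
      cn <- snps$pleiotropy_confounder[j]
      Mstd[, cn] <- Mstd[, cn] + snps$pleiotropy_confounder_effect[j] * Z[, j]
    }
    for (k in seq_along(config$confounders)) {
      mo <- conf_moments(config$confounders[[k]])
      Mraw[[names(config$confounders)[k]]] <-
        mo["mean"] + mo["sd"] * Mstd[, k]
    }
  }

  alpha <- vapply(config$confounders, `[[`, 0, "effect_liability")
  delta <- vapply(config$confounders, `[[`, 0, "effect_outcome")
  G <- drop(sweep(Z, 2, 2 * snps$maf) %*% snps$gamma_scaled)
  V <- stats::rnorm(n, 0, config$sd_environment)
  L <- G + (if (length(alpha)) drop(Mstd %*% alpha) else 0) + V

  tau <- calibrate_threshold(L, config$exposure_prevalence)
  D <- as.integer(L > tau)

  lin <- config$beta_liability * L +
    (if (length(delta)) drop(Mstd %*% delta) else 0) +
    drop(Z %*% snps$pleiotropy_outcome)
  h <- exp(lin)
  r0 <- if (!is.null(config$outcome_target_prevalence))
    config$outcome_target_prevalence / mean(h)
  else config$outcome_baseline_risk
  risk <- r0 * h
  if (any(risk >= 1)) {
    stop("log-linear outcome model yields risk >= 1 (max ",
         format(max(risk), digits = 4), ") for ", sum(risk >= 1),
         " individual(s); reduce outcome_baseline_risk (", format(r0),
         "), beta_liability (", format(config$beta_liability),
         "), confounder effect_outcome or pleiotropy_outcome values",
         call. = FALSE)
  }
  Y <- stats::rbinom(n, 1L, risk)

  if (config$missing_genotype_rate > 0) {
    mask <- stats::runif(n * p) < config$missing_genotype_rate
    Z[matrix(mask, n, p)] <- NA_real_
  }

  sample_ids <- sprintf("S%06d", seq_len(n))
  meta <- data.frame(id = snps$id, chromosome = 1L,
                     position = seq_len(p) * 10000L,
                     effect_allele = "A", other_allele = "G")
  pheno <- data.frame(sample_id = sample_ids)
  pheno[[config$exposure_name]] <- D
  pheno[[config$outcome_name]] <- Y
  for (nm in names(Mraw)) pheno[[nm]] <- Mraw[[nm]]

  tp <- unclass(config)
  tp$tau <- tau
  tp$realized_baseline_risk <- r0
  tp$realized_exposure_prevalence <- mean(D)
  tp$realized_outcome_prevalence <- mean(Y)
  structure(list(genotypes = genotype_matrix(Z, meta, sample_ids),
                 phenotypes = pheno, liability = L, true_parameters = tp),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tp <- x$true_parameters
  cat("<synthetic_cohort> n = ", n_individuals(x$genotypes), ", ",
      n_snps(x$genotypes), " SNPs\n", sep = "")
  cat(sprintf("  %s prevalence %.4f (target %.4f), %s prevalence %.4f\n",
              tp$exposure_name, tp$realized_exposure_prevalence,
              tp$exposure_prevalence, tp$outcome_name,
              tp$realized_outcome_prevalence))
  cat(sprintf("  theta2 = %.3f, beta_liability = %.4f, tau = %.4f\n",
              tp$theta2, tp$beta_liability, tp$tau))
  invisible(x)
}

#' Default biobank-scale simulation configuration
#'
#' The bundled study design: 88,347 individuals; gout (exposure) at 3.68%
#' prevalence driven by 5 variants carrying liability heritability
#' `theta2 = 0.047`, one of which (`rs671_like`) also shifts serum
#' creatinine (via-confounder pleiotropy); hypertension (outcome) at 13.52%
#' marginal prevalence with 10 direct-effect variants (per-allele log-RR
#' 0.09) that serve as instruments for the reverse direction; measured
#' confounders age, sex, BMI and creatinine with margins matching the
#' cohort description (age 51.1 (11.12) years, 31.9% male, BMI 24.25
#' (3.83), creatinine mean 0.71); plus null variants so instrument
#' selection is non-trivial. The causal effect of gout liability on
#' hypertension is `beta_liability = log(1.10)` per liability SD; there is
#' no reverse (hypertension on gout) effect.
#'
#' @param n_individuals Cohort size (default 88,347).
#' @param beta_liability Causal log-RR per liability SD (default
#'   `log(1.10)`).
#' @param n_null_snps Number of additional null variants (default 25).
#' @param missing_genotype_rate Missing-call rate (default 0.02).
#' @param htn_log_rr Per-allele log-RR of the 10 direct outcome variants
#'   (default 0.09, sized so the reverse-direction genetic share carries a
#'   liability heritability near 0.013 at the default prevalence).
#' @param seed Seed.
#' @return A [simulation_config()].
#' @export
default_biobank_config <- function(n_individuals = 88347,
                                   beta_liability = log(1.10),
                                   n_null_snps = 25,
                                   missing_genotype_rate = 0.02,
                                   htn_log_rr = 0.09,
                                   seed = 1L) {
  gout_snps <- data.frame(
    id = c("rs671_like", paste0("rs_gout", 1:4)),
    maf = c(0.17, 0.30, 0.25, 0.40, 0.35),
    gamma = c(1.0, 0.85, 0.70, 0.90, 0.80),
    pleiotropy_outcome = 0,
    pleiotropy_confounder = c("creatinine", NA, NA, NA, NA),
    pleiotropy_confounder_effect = c(0.08, 0, 0, 0, 0))
  htn_snps <- data.frame(
    id = paste0("rs_htn", 1:10),
    maf = c(0.20, 0.25, 0.30, 0.35, 0.40, 0.22, 0.28, 0.32, 0.38, 0.26),
    gamma = 0, pleiotropy_outcome = htn_log_rr,
    pleiotropy_confounder = NA_character_,
    pleiotropy_confounder_effect = 0)
  null_snps <- if (n_null_snps > 0) data.frame(
    id = paste0("rs_null", seq_len(n_null_snps)),
    maf = round(seq(0.05, 0.45, length.out = n_null_snps), 3),
    gamma = 0, pleiotropy_outcome = 0,
    pleiotropy_confounder = NA_character_,
    pleiotropy_confounder_effect = 0) else NULL
  confs <- list(
    confounder_spec("age", "normal", mean = 51.1, sd = 11.12,
                    effect_liability = 0.12, effect_outcome = 0.20),
    confounder_spec("sex", "bernoulli", prob = 0.319,
                    effect_liability = 0.25, effect_outcome = 0.12),
    confounder_spec("bmi", "normal", mean = 24.25, sd = 3.83,
                    effect_liability = 0.18, effect_outcome = 0.15),
    # lognormal matched to creatinine mean 0.71, sd 0.31
    confounder_spec("creatinine", "lognormal", meanlog = -0.430,
                    sdlog = 0.418, effect_liability = 0.10,
                    effect_outcome = 0.05))
  simulation_config(
    n_individuals = n_individuals,
    snps = rbind(gout_snps, htn_snps, null_snps),
    theta2 = 0.047,
    exposure_prevalence = 0.0368,
    beta_liability = beta_liability,
    outcome_target_prevalence = 0.1352,
    confounders = confs,
    missing_genotype_rate = missing_genotype_rate,
    exposure_name = "gout", outcome_name = "hypertension",
    seed = seed)
}
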
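# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

# Minimal liability-threshold design: k valid instruments, no confounders.
basic_config <- function(n = 20000, k = 4, theta2 = 0.047,
                         beta_liability = log(1.10),
                         exposure_prevalence = 0.0368,
                         outcome_target = 0.1352, seed = 1L, ...) {
  mafs <- rep_len(c(0.30, 0.25, 0.40, 0.35, 0.20), k)
  simulation_config(
    n_individuals = n,
    snps = data.frame(id = paste0("rs", seq_len(k)), maf = mafs,
                      gamma = rep_len(c(1, 0.85, 0.9, 0.8, 0.95), k)),
    theta2 = theta2, exposure_prevalence = exposure_prevalence,
    beta_liability = beta_liability,
    outcome_target_prevalence = outcome_target, seed = seed, ...)
}

# One full IVW pass (probit fit -> outcome scan -> ratios at the estimated
# theta2 -> pooling) on a cohort's pieces; used by calibration/recovery
# loops.
ivw_once <- function(cohort, model = "fixed", adjust = FALSE) {
  ph <- cohort$phenotypes
  tp <- cohort$true_parameters
  D <- ph[[tp$exposure_name]]
  Y <- ph[[tp$outcome_name]]
  Z <- cohort$genotypes$values[, tp$snps$id[tp$snps$gamma != 0],
                               drop = FALSE]
  M <- if (adjust && length(tp$confounders))
    ph[, names(tp$confounders), drop = FALSE] else NULL
  fit <- fit_genetic_share(D, Z, M)
  t2 <- estimate_theta2_lower_bound(fit)
  ob <- outcome_scan(Y, Z, M)
  rt <- liability_wald_ratios(fit, ob, t2)
  ivw_combine(rt, model = model, theta2 = t2)
}

# Genotype matrix with prescribed genotype counts in a single SNP column.
geno_from_counts <- function(n0, n1, n2, id = "rs1", n_missing = 0) {
  z <- c(rep(0, n0), rep(1, n1), rep(2, n2), rep(NA, n_missing))
  genotype_matrix(matrix(z, ncol = 1, dimnames = list(NULL, id)))
}
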
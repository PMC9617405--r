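# Synthetic-cohort generator: threshold calibration, structural model,
# determinism, Hardy-Weinberg conformity of simulated genotypes.

test_that("calibrate_threshold hits the target and is monotone", {
  set.seed(11)
  L <- rnorm(10001)  # odd n: the 50% threshold is the sample median
  expect_equal(calibrate_threshold(L, 0.5), median(L))
  expect_gt(calibrate_threshold(L, 0.01), calibrate_threshold(L, 0.10))

  set.seed(12)
  L2 <- rnorm(100000)
  tau <- calibrate_threshold(L2, 0.0368)
  expect_lt(abs(mean(L2 > tau) - 0.0368), 0.002)

  expect_error(calibrate_threshold(rep(1, 50), 0.1), "constant")
  expect_error(calibrate_threshold(rnorm(10), 1.2), "target_prevalence")
})

test_that("configuration validation rejects inconsistent designs", {
  snps <- data.frame(id = "rs1", maf = 0.3, gamma = 1)
  expect_error(simulation_config(100, snps, theta2 = 1.2,
                                 exposure_prevalence = 0.1,
                                 beta_liability = 0,
                                 outcome_baseline_risk = 0.1), "theta2")
  expect_error(simulation_config(100, snps, theta2 = 0.1,
                                 exposure_prevalence = 0.1,
                                 beta_liability = 0,
                                 outcome_baseline_risk = 0.1,
                                 outcome_target_prevalence = 0.1),
               "exactly one")
  # genetic + confounder liability variance must leave room for environment
  conf <- confounder_spec("x", "normal", effect_liability = 0.9)
  expect_error(simulation_config(100, snps, theta2 = 0.3,
                                 exposure_prevalence = 0.1,
                                 beta_liability = 0,
                                 outcome_baseline_risk = 0.1,
                                 confounders = list(conf)), "must be < 1")
  # theta2 > 0 with no genetic weights is not realisable
  snps0 <- data.frame(id = "rs1", maf = 0.3, gamma = 0)
  expect_error(simulation_config(100, snps0, theta2 = 0.1,
                                 exposure_prevalence = 0.1,
                                 beta_liability = 0,
                                 outcome_baseline_risk = 0.1), "nonzero gamma")
})

test_that("identical config yields a bit-identical cohort", {
  cfg <- basic_config(n = 2000, seed = 99, missing_genotype_rate = 0.05)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$values, b$genotypes$values)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$liability, b$liability)
  # and a different seed changes the draw
  c <- simulate_cohort(basic_config(n = 2000, seed = 100,
                                    missing_genotype_rate = 0.05))
  expect_false(identical(a$phenotypes, c$phenotypes))
})

test_that("exposure is exactly the thresholded liability and margins hit", {
  cfg <- basic_config(n = 30000, seed = 3)
  coh <- simulate_cohort(cfg)
  tp <- coh$true_parameters
  expect_identical(coh$phenotypes$exposure,
                   as.integer(coh$liability > tp$tau))
  se_d <- sqrt(0.0368 * (1 - 0.0368) / 30000)
  expect_lt(abs(mean(coh$phenotypes$exposure) - 0.0368), 3 * se_d)
  se_y <- sqrt(0.1352 * (1 - 0.1352) / 30000)
  expect_lt(abs(mean(coh$phenotypes$outcome) - 0.1352), 3 * se_y)
})

test_that("liability variance decomposition matches the configured theta2", {
  cfg <- basic_config(n = 50000, k = 5, seed = 21)
  coh <- simulate_cohort(cfg)
  expect_lt(abs(var(coh$liability) - 1), 0.02)
  r2 <- summary(lm(coh$liability ~ coh$genotypes$values))$r.squared
  expect_lt(abs(r2 - 0.047), 0.01)
})

test_that("outcome risks above one are rejected with named parameters", {
  cfg <- basic_config(n = 5000, seed = 5, beta_liability = 2,
                      outcome_target = NULL,
                      outcome_baseline_risk = 0.5)
  expect_error(simulate_cohort(cfg), "risk >= 1")
  expect_error(simulate_cohort(cfg), "beta_liability")
})

test_that("simulated genotypes conform to Hardy-Weinberg equilibrium", {
  # 500 variants at n = 10,000: per-SNP exact-test p-values should be
  # (conservatively sub-)uniform; KS against U(0,1) must not reject hard
  cfg <- simulation_config(
    n_individuals = 10000,
    snps = data.frame(id = paste0("s", 1:500),
                      maf = runif(500, 0.05, 0.5), gamma = 0),
    theta2 = 0, exposure_prevalence = 0.1, beta_liability = 0,
    outcome_baseline_risk = 0.1, seed = 42)
  coh <- simulate_cohort(cfg)
  pvals <- apply(coh$genotypes$values, 2, function(z)
    hwe_exact_test(sum(z == 0), sum(z == 1), sum(z == 2)))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("missing calls are injected at the configured rate", {
  cfg <- basic_config(n = 20000, k = 5, seed = 8,
                      missing_genotype_rate = 0.1)
  coh <- simulate_cohort(cfg)
  rate <- mean(is.na(coh$genotypes$values))
  expect_lt(abs(rate - 0.1), 0.005)
})

test_that("null causal effect gives IVW confidence intervals covering 1", {
  hits <- vapply(1:50, function(s) {
    coh <- simulate_cohort(basic_config(n = 10000, beta_liability = 0,
                                        seed = 1000 + s))
    est <- ivw_once(coh)
    est$ci_low <= 1 && est$ci_high >= 1
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})
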
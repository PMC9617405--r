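# Core coarsened-exposure MR estimators: probit genetic-share fit, LRT,
# theta2 bound, outcome scan, Wald ratios, Cochran's Q, IVW, PRS, sweep.

test_that("probit, logistic and log-linear fits match numerical ML on
           small data", {
  set.seed(61)
  n <- 30
  z <- rbinom(n, 2, 0.4)
  x <- rnorm(n)
  d <- rbinom(n, 1, pnorm(-0.5 + 0.5 * z))
  y <- rbinom(n, 1, 0.25 * exp(0.2 * z - 0.25))
  X <- cbind(1, z, x)

  fit <- fit_genetic_share(d, matrix(z, ncol = 1,
                                     dimnames = list(NULL, "rs1")),
                           data.frame(x = x))
  orc <- oracle_glm(X, d, "probit")
  expect_equal(unname(fit$coef["rs1"]), orc$coef[2], tolerance = 1e-6)
  expect_equal(unname(fit$confounder_coef["x"]), orc$coef[3],
               tolerance = 1e-6)
  expect_equal(fit$loglik_full, orc$loglik, tolerance = 1e-8)

  orc_null <- oracle_glm(cbind(1, x), d, "probit")
  expect_equal(fit$loglik_null, orc_null$loglik, tolerance = 1e-8)

  ob <- outcome_scan(y, matrix(z, ncol = 1, dimnames = list(NULL, "rs1")))
  orc_p <- oracle_glm(cbind(1, z), y, "log-poisson")
  expect_equal(ob$beta, orc_p$coef[2], tolerance = 1e-6)

  lg <- coarseMR:::ml_fit(cbind(1, z), d, family = "logit")
  orc_l <- oracle_glm(cbind(1, z), d, "logit")
  expect_equal(unname(lg$coef), orc_l$coef, tolerance = 1e-6)
})

test_that("zero-information instruments give zero coefficients and a null
           LRT", {
  set.seed(62)
  d <- rbinom(100, 1, 0.3)
  Z <- cbind(a = rep(0, 100), b = rep(2, 100))
  fit <- fit_genetic_share(d, Z)
  expect_equal(unname(fit$coef), c(0, 0))
  expect_equal(fit$loglik_full, fit$loglik_null)
  lrt <- instrument_strength_lrt(fit)
  expect_equal(lrt$statistic, 0)
  expect_equal(lrt$p, 1)
  expect_equal(estimate_theta2_lower_bound(fit), 0)
  expect_error(fit_genetic_share(rep(1, 100), Z), "constant")
})

test_that("theta2 lower bound recovers full heritability and attenuates
           under partial instrument coverage", {
  coh <- simulate_cohort(basic_config(n = 100000, k = 5, seed = 63))
  D <- coh$phenotypes$exposure
  Z <- coh$genotypes$values
  fit <- fit_genetic_share(D, Z)
  expect_lt(abs(estimate_theta2_lower_bound(fit) - 0.047), 0.01)

  # instruments explaining only part of the genetic share: bound below truth
  below <- vapply(1:60, function(s) {
    coh <- simulate_cohort(basic_config(n = 15000, k = 4, seed = 6300 + s))
    fit_half <- fit_genetic_share(coh$phenotypes$exposure,
                                  coh$genotypes$values[, 1:2])
    estimate_theta2_lower_bound(fit_half) < 0.047
  }, TRUE)
  expect_gte(mean(below), 0.95)
})

test_that("outcome scan recovers per-allele log-RR and approximates the
           log-OR for rare outcomes", {
  set.seed(64)
  n <- 100000
  z <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, 0.015 * 1.2^z)
  zm <- matrix(z, ncol = 1, dimnames = list(NULL, "rs1"))
  ob <- outcome_scan(y, zm)
  expect_lt(abs(ob$beta - log(1.2)), 3 * ob$se)
  # rare-disease approximation: log-RR within 10% of logistic log-OR
  lg <- coarseMR:::ml_fit(cbind(1, z), y, family = "logit")
  expect_lt(abs(ob$beta - lg$coef[2]) / abs(lg$coef[2]), 0.10)

  # null: mean estimate unbiased
  betas <- vapply(1:300, function(i) {
    zz <- rbinom(5000, 2, 0.3)
    yy <- rbinom(5000, 1, 0.1)
    outcome_scan(yy, matrix(zz, ncol = 1,
                            dimnames = list(NULL, "s")))$beta
  }, 0)
  expect_lt(abs(mean(betas)), 0.01)
})

test_that("robust outcome-scan SEs agree with the sandwich package", {
  skip_if_not_installed("sandwich")
  set.seed(65)
  n <- 3000
  z <- rbinom(n, 2, 0.3)
  m <- rnorm(n)
  y <- rbinom(n, 1, pmin(0.9, 0.1 * exp(0.1 * z + 0.2 * m)))
  ob <- outcome_scan(y, matrix(z, ncol = 1, dimnames = list(NULL, "s")),
                     data.frame(m = m))
  gf <- glm(y ~ z + m, family = poisson())
  se_sand <- sqrt(diag(sandwich::vcovHC(gf, type = "HC0")))[["z"]]
  expect_equal(ob$se, se_sand, tolerance = 1e-6)
})

test_that("liability Wald ratios scale by sqrt(1 - theta2)", {
  set.seed(66)
  coh <- simulate_cohort(basic_config(n = 10000, k = 4, seed = 66))
  D <- coh$phenotypes$exposure
  Y <- coh$phenotypes$outcome
  Z <- coh$genotypes$values
  fit <- fit_genetic_share(D, Z)
  ob <- outcome_scan(Y, Z)
  r0 <- liability_wald_ratios(fit, ob, 0)
  expect_equal(r0$gamma_star, unname(fit$coef))  # theta2 = 0 identity
  r047 <- liability_wald_ratios(fit, ob, 0.047)
  expect_equal(r047$b, r0$b / sqrt(1 - 0.047), tolerance = 1e-12)
  expect_equal(r047$se, r0$se / sqrt(1 - 0.047), tolerance = 1e-12)
  # monotone magnification in theta2 wherever beta_y != 0
  r14 <- liability_wald_ratios(fit, ob, 0.14)
  nz <- r0$beta_y != 0
  expect_true(all(abs(r14$b[nz]) > abs(r047$b[nz])))

  fit$coef["rs1"] <- 0   # unstable ratio excluded with a warning
  expect_warning(rr <- liability_wald_ratios(fit, ob, 0.047), "unstable")
  expect_false("rs1" %in% rr$snp)
})

test_that("Cochran's Q matches hand arithmetic and is calibrated", {
  rt <- data.frame(snp = c("a", "b", "c"),
                   beta_y = NA, se_y = NA, c = NA, gamma_star = NA,
                   b = c(0.10, 0.20, 0.00), se = c(0.05, 0.05, 0.10))
  het <- cochran_q(rt)
  # weights 400/400/100; weighted mean 0.13333; Q = 4.0 by direct arithmetic
  expect_equal(het$Q, 4.0, tolerance = 1e-12)
  expect_equal(het$df, 2L)
  expect_equal(het$p, pchisq(4, 2, lower.tail = FALSE))
  expect_identical(het$model, "fixed")

  same <- data.frame(b = c(0.1, 0.1, 0.1), se = c(0.2, 0.1, 0.3))
  expect_equal(cochran_q(same)$Q, 0)
  expect_equal(cochran_q(same)$p, 1)
  expect_error(cochran_q(same[1, ]), "at least 2")

  # under homogeneity Q ~ chi-square(k-1)
  set.seed(67)
  k <- 10
  rejections <- vapply(1:1000, function(i) {
    se <- runif(k, 0.05, 0.2)
    tab <- data.frame(b = rnorm(k, 0.1, se), se = se)
    cochran_q(tab)$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("IVW pooling matches the precision-weighted oracle", {
  one <- data.frame(snp = "a", b = 0.095, se = 0.04)
  est <- ivw_combine(one, theta2 = 0.047)
  expect_equal(est$estimate, 0.095)
  expect_equal(est$rr, exp(0.095))
  expect_equal(est$ci_low, exp(0.095 - 1.96 * 0.04))
  expect_equal(est$ci_high, exp(0.095 + 1.96 * 0.04))
  expect_identical(est$model, "fixed")

  rt <- data.frame(b = c(0.10, 0.20, 0.00), se = c(0.05, 0.05, 0.10))
  est3 <- ivw_combine(rt, model = "fixed")
  w <- 1 / rt$se^2
  expect_equal(est3$estimate, sum(w * rt$b) / sum(w), tolerance = 1e-12)
  expect_equal(est3$se, sqrt(1 / sum(w)), tolerance = 1e-12)

  # Q <= k-1: random effects collapses onto fixed effects
  same <- data.frame(b = c(0.1, 0.1, 0.1), se = c(0.2, 0.1, 0.3))
  fe <- ivw_combine(same, model = "fixed")
  re <- ivw_combine(same, model = "random")
  expect_equal(re$estimate, fe$estimate)
  expect_equal(re$se, fe$se)
  expect_error(ivw_combine(rt[0, ]), "empty")
})

test_that("the PRS ratio is invariant to rescaling the score", {
  set.seed(68)
  coh <- simulate_cohort(basic_config(n = 20000, k = 4, seed = 68))
  D <- coh$phenotypes$exposure
  Y <- coh$phenotypes$outcome
  Z <- coh$genotypes$values
  w <- coarseMR:::ml_fit(cbind(1, Z), D, family = "logit")$coef[-1]
  s <- drop(Z %*% w)
  est_for <- function(score) {
    sf <- fit_genetic_share(D, matrix(score, ncol = 1,
                                      dimnames = list(NULL, "PRS")))
    ob <- outcome_scan(Y, matrix(score, ncol = 1,
                                 dimnames = list(NULL, "PRS")))
    ob$beta / (sf$coef[["PRS"]] * sqrt(1 - 0.047))
  }
  expect_equal(est_for(s), est_for(7.3 * s), tolerance = 1e-6)
})

test_that("PRS method is unbiased under the null and refolds degenerate
           partitions", {
  set.seed(69)
  rrs <- vapply(1:30, function(s) {
    coh <- simulate_cohort(basic_config(n = 10000, beta_liability = 0,
                                        seed = 6900 + s))
    prs_method(coh$phenotypes$exposure, coh$phenotypes$outcome,
               coh$genotypes$values, theta2 = 0.047, seed = s)$rr
  }, 0)
  expect_lt(abs(mean(log(rrs))), 3 * sd(log(rrs)) / sqrt(30))

  # a single exposure case can never appear in every training fold
  set.seed(70)
  D1 <- c(1, rep(0, 199))
  Z1 <- matrix(rbinom(200, 2, 0.3), ncol = 1,
               dimnames = list(NULL, "s"))
  expect_error(prs_method(D1, rbinom(200, 1, 0.2), Z1, theta2 = 0),
               "both exposure classes")
})

test_that("sensitivity sweep has the right layout and monotone magnitude", {
  coh <- simulate_cohort(basic_config(n = 30000, k = 4, seed = 71))
  sw <- sensitivity_sweep(coh$phenotypes$exposure, coh$phenotypes$outcome,
                          coh$genotypes$values,
                          theta2_grid = c(0.04, 0.07, 0.14), prs_seed = 1)
  # grid of 3 plus the estimated value, two methods per grid point
  expect_equal(nrow(sw), 8)
  expect_equal(sum(sw$estimated), 2)
  for (m in unique(sw$method)) {
    rows <- sw[sw$method == m, ]
    expect_equal(rows$theta2, sort(rows$theta2))
    expect_true(all(diff(abs(rows$log_rr)) > 0))
  }
  # Q is invariant to the theta2 rescaling, so the IVW model choice is too
  ivw_rows <- sw[grepl("IVW", sw$method), ]
  expect_equal(length(unique(round(ivw_rows$Q, 10))), 1)
  expect_length(unique(ivw_rows$model), 1)
})

test_that("adjusted and unadjusted estimates agree when instruments are
           independent of confounders", {
  confs <- list(
    confounder_spec("age", "normal", mean = 50, sd = 10,
                    effect_liability = 0.2, effect_outcome = 0.3),
    confounder_spec("sex", "bernoulli", prob = 0.4,
                    effect_liability = 0.15, effect_outcome = 0.1))
  diffs <- vapply(1:15, function(s) {
    cfg <- basic_config(n = 30000, k = 4, seed = 7200 + s,
                        confounders = confs)
    coh <- simulate_cohort(cfg)
    unadj <- ivw_once(coh, adjust = FALSE)
    adj <- ivw_once(coh, adjust = TRUE)
    adj$estimate - unadj$estimate
  }, 0)
  expect_lt(abs(mean(diffs)), 0.02)
})
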
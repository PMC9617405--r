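# Instrument-confounder independence screen and FDR-based removal.

test_that("BH adjustment matches a literal step-up oracle", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # random p-vectors of length <= 6 on a 0.01 grid
  set.seed(51)
  for (len in 1:6) {
    for (rep_i in 1:25) {
      p <- sample(seq(0.01, 1, by = 0.01), len, replace = TRUE)
      expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
    }
  }
})

test_that("screen computes chi-square and Spearman tests with joint BH", {
  set.seed(52)
  n <- 5000
  Z <- cbind(s1 = rbinom(n, 2, 0.3), s2 = rbinom(n, 2, 0.4))
  gm <- genotype_matrix(Z)
  conf <- data.frame(age = rnorm(n, 50, 10),
                     sex = rbinom(n, 1, 0.4))
  types <- c(age = "continuous", sex = "categorical")
  tab <- confounder_independence(gm, c("s1", "s2"), conf, types)
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$test[tab$confounder == "sex"], "chi-square")
  expect_setequal(tab$test[tab$confounder == "age"], "spearman")
  expect_true(all(tab$p_adj >= tab$p_raw))
  expect_equal(tab$p_adj, oracle_bh(tab$p_raw), tolerance = 1e-12)
  # independent oracle for the pair statistics
  sp <- cor.test(Z[, "s1"], conf$age, method = "spearman", exact = FALSE)
  expect_equal(tab$p_raw[tab$snp == "s1" & tab$confounder == "age"],
               sp$p.value)
  expect_error(confounder_independence(gm, "s1", conf, c(age = "continuous")),
               "not declared")
})

test_that("screen level is near nominal for independent instruments", {
  set.seed(53)
  raw_hits <- adj_hits <- 0
  total <- 0
  for (s in 1:40) {
    n <- 2000
    Z <- sapply(rep(0.3, 5), function(m) rbinom(n, 2, m))
    colnames(Z) <- paste0("s", 1:5)
    conf <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.4),
                       bmi = rnorm(n), creat = rlnorm(n, 0, 0.4))
    tab <- confounder_independence(genotype_matrix(Z), colnames(Z), conf,
                                   c(age = "continuous", sex = "categorical",
                                     bmi = "continuous",
                                     creat = "continuous"))
    raw_hits <- raw_hits + sum(tab$p_raw < 0.05)
    adj_hits <- adj_hits + sum(tab$p_adj < 0.05)
    total <- total + nrow(tab)
  }
  expect_lt(abs(raw_hits / total - 0.05), 0.02)
  expect_lte(adj_hits, raw_hits)
})

test_that("a genuine instrument-confounder association is detected", {
  set.seed(54)
  n <- 20000
  z <- rbinom(n, 2, 0.3)
  conf <- data.frame(creat = rnorm(n) + 0.3 * z,  # 0.3 SD per allele
                     age = rnorm(n))
  gm <- genotype_matrix(cbind(s1 = z, s2 = rbinom(n, 2, 0.3)))
  tab <- confounder_independence(gm, c("s1", "s2"), conf,
                                 c(creat = "continuous",
                                   age = "continuous"))
  expect_lt(tab$p_adj[tab$snp == "s1" & tab$confounder == "creat"], 0.05)
})

test_that("filter_instruments removes exactly the violating SNPs", {
  inst <- instrument_set(paste0("g", 1:5))
  tests <- data.frame(snp = rep(paste0("g", 1:5), each = 2),
                      confounder = rep(c("age", "creat"), 5),
                      test = "spearman", statistic = 0,
                      p_raw = 1, p_adj = 1)
  # one of five instruments fails against a confounder -> four retained
  tests$p_adj[tests$snp == "g3" & tests$confounder == "creat"] <- 0.01
  out <- filter_instruments(inst, tests, alpha = 0.05)
  expect_setequal(out$ids, paste0("g", c(1, 2, 4, 5)))
  expect_identical(out$removed, "g3")
  expect_false(out$provenance$passed_confounder_screen[
    out$provenance$snp == "g3"])

  # none failing -> identity (ten instruments retained)
  inst10 <- instrument_set(paste0("h", 1:10))
  tests10 <- data.frame(snp = paste0("h", 1:10), confounder = "age",
                        test = "spearman", statistic = 0, p_raw = 1,
                        p_adj = 1)
  expect_identical(filter_instruments(inst10, tests10, 0.05)$ids,
                   inst10$ids)

  # alpha = 0 is the identity; larger alpha removes a superset
  tests$p_adj <- seq(0.01, 0.9, length.out = nrow(tests))
  expect_identical(filter_instruments(inst, tests, 0)$ids, inst$ids)
  r1 <- setdiff(inst$ids, filter_instruments(inst, tests, 0.1)$ids)
  r2 <- setdiff(inst$ids, filter_instruments(inst, tests, 0.5)$ids)
  expect_true(all(r1 %in% r2))

  expect_error(filter_instruments(inst, tests[tests$snp != "g1", ], 0.05),
               "cover")
  # raw-p switch
  tr <- transform(tests10, p_raw = 0.01, p_adj = 0.2)
  expect_identical(filter_instruments(inst10, tr, 0.05)$ids, inst10$ids)
  expect_warning(out0 <- filter_instruments(inst10, tr, 0.05,
                                            use_raw_p = TRUE), "every")
  expect_length(out0$ids, 0)
})
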
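# Independent brute-force oracles used to freeze expected values. These
# deliberately avoid the code paths they check: direct numerical likelihood
# maximisation via optim, exact factorial enumeration for the HWE test, and
# a literal step-up loop for Benjamini-Hochberg.

# Numerical ML for GLM-type likelihoods on small model matrices.
oracle_glm <- function(X, y, family = c("logit", "probit", "log-poisson")) {
  family <- match.arg(family)
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    switch(family,
      logit = -sum(y * eta - log1p(exp(eta))),
      probit = {
        p <- pnorm(eta)
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        -sum(y * log(p) + (1 - y) * log(1 - p))
      },
      `log-poisson` = -sum(y * eta - exp(eta)))
  }
  gr <- function(beta) {  # analytic score, negated
    eta <- drop(X %*% beta)
    resid <- switch(family,
      logit = y - plogis(eta),
      probit = {
        p <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
        dnorm(eta) * (y - p) / (p * (1 - p))
      },
      `log-poisson` = y - exp(eta))
    -drop(crossprod(X, resid))
  }
  start <- c(switch(family,
                    logit = qlogis(pmin(pmax(mean(y), 0.05), 0.95)),
                    probit = qnorm(pmin(pmax(mean(y), 0.05), 0.95)),
                    `log-poisson` = log(max(mean(y), 1e-3))),
             rep(0, ncol(X) - 1))
  opt <- optim(start, nll, gr, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  hess <- optimHess(opt$par, nll)
  list(coef = opt$par, vcov = solve(hess), se = sqrt(diag(solve(hess))),
       loglik = -opt$value)
}

# Exact HWE p-value by full enumeration of absolute configuration
# probabilities, P(het = h) = n! 2^h nA! nB! / (nAA! h! nBB! (2n)!),
# including the normalising constant (the probabilities are checked to sum
# to 1, which the in-package renormalising route never computes).
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_alt + n_het
  nb <- 2 * n - na
  prob_of <- function(h) {
    naa <- (nb - h) / 2
    nbb <- (na - h) / 2
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
          h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n))
  }
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  probs <- vapply(hets, prob_of, 0)
  stopifnot(abs(sum(probs) - 1) < 1e-8)
  obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

# Literal BH step-up: adjusted p for the i-th smallest is
# min_{j >= i} m * p_(j) / j, capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * p[o][i:m] / (i:m)))
  }, 0)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}
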
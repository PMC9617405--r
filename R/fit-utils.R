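# Internal maximum-likelihood fitting helpers.
#
# Hot loops (per-SNP scans, replicate simulations, cross-validation folds)
# call stats::glm.fit on prebuilt model matrices instead of formula-interface
# glm(): identical IRLS numerics without model-frame overhead. Everything a
# downstream estimator needs (coefficients, Fisher vcov, log-likelihood,
# robust vcov for the Poisson working model) is extracted here once.

GLM_FAMILIES <- c("logit", "probit", "log-poisson", "log-binomial")

glm_family <- function(family) {
  switch(family,
    "logit"        = stats::binomial(link = "logit"),
    "probit"       = stats::binomial(link = "probit"),
    "log-poisson"  = stats::poisson(link = "log"),
    "log-binomial" = stats::binomial(link = "log"),
    stop("unknown family: ", family)
  )
}

# Bernoulli/Poisson log-likelihood at fitted means (y is 0/1 throughout the
# package, so the Poisson term log(y!) vanishes).
ml_loglik <- function(y, mu, family) {
  if (family %in% c("logit", "probit", "log-binomial")) {
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    sum(y * log(mu) + (1 - y) * log(1 - mu))
  } else {
    sum(y * log(pmax(mu, 1e-300)) - mu)
  }
}

# ML fit of y on model matrix X (must already contain an intercept column).
# Returns coefficients, model-based vcov (inverse Fisher information), HC0
# robust vcov on request, log-likelihood and convergence diagnostics.
ml_fit <- function(X, y, family = "logit", robust = FALSE, start = NULL,
                   maxit = 100) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  fam <- glm_family(family)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = fam, start = start,
                                    control = list(maxit = maxit,
                                                   epsilon = 1e-12))),
    error = function(e) NULL
  )
  if (is.null(fit) && family == "log-binomial") {
    # log link on binomial data needs an interior start; retry from a
    # low-risk intercept with zero slopes
    start <- c(log(max(mean(y), 1e-4) / 2), rep(0, ncol(X) - 1))
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = fam, start = start,
                                      control = list(maxit = maxit))),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    return(list(converged = FALSE, failed = TRUE, coef = rep(NA_real_, ncol(X)),
                se = rep(NA_real_, ncol(X)), vcov = NULL, loglik = NA_real_,
                n = length(y)))
  }
  w <- fit$weights          # IRLS working weights: Fisher info = X' W X
  XtWX <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(XtWX), error = function(e) NULL)
  singular <- is.null(vc) || any(!is.finite(diag(vc)))
  mu <- fit$fitted.values
  out <- list(
    coef = fit$coefficients,
    vcov = vc,
    se = if (singular) rep(NA_real_, ncol(X)) else sqrt(pmax(diag(vc), 0)),
    loglik = ml_loglik(y, mu, family),
    fitted = mu,
    converged = isTRUE(fit$converged) && !singular &&
      all(is.finite(fit$coefficients)),
    failed = FALSE,
    n = length(y)
  )
  if (robust) {
    # HC0 sandwich: A^{-1} (sum_i s_i s_i') A^{-1} with A the Fisher info of
    # the working model and s_i = x_i (y_i - mu_i) the ML score.
    if (!singular) {
      B <- crossprod(X * (y - mu))
      out$vcov_robust <- vc %*% B %*% vc
      out$se_robust <- sqrt(pmax(diag(out$vcov_robust), 0))
    } else {
      out$vcov_robust <- NULL
      out$se_robust <- rep(NA_real_, ncol(X))
    }
  }
  names(out$se) <- colnames(X)
  out
}

# Ridge-penalised logistic fit via IRLS, used as a retry when plain ML fails
# to converge (quasi-separation at low minor-allele counts). The penalty is
# not applied to the intercept.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 200, tol = 1e-10) {
  p <- ncol(X)
  beta <- c(stats::qlogis(pmin(pmax(mean(y), 0.01), 0.99)), rep(0, p - 1))
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(X * sqrt(w)) + pen
    beta_new <- tryCatch(drop(solve(XtWX, crossprod(X, w * z))),
                         error = function(e) beta)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  vc <- tryCatch(solve(crossprod(X * sqrt(w)) + pen), error = function(e) NULL)
  list(coef = beta,
       se = if (is.null(vc)) rep(NA_real_, p) else sqrt(pmax(diag(vc), 0)),
       vcov = vc, loglik = ml_loglik(y, mu, "logit"),
       converged = !is.null(vc), penalized = TRUE, n = length(y))
}

# Mean-impute missing allele counts, column-wise. Standard dosage handling
# for multi-SNP fits (PRS, joint probit) after per-SNP QC has removed
# high-missingness variants.
impute_dosage <- function(Z) {
  if (!anyNA(Z)) return(Z)
  for (j in seq_len(ncol(Z))) {
    nas <- is.na(Z[, j])
    if (any(nas)) Z[nas, j] <- mean(Z[, j], na.rm = TRUE)
  }
  Z
}

# Two-sided normal p-value from an estimate and its SE.
wald_p <- function(est, se) 2 * stats::pnorm(-abs(est / se))

`%||%` <- function(a, b) if (is.null(a)) b else a
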
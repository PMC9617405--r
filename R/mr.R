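# Coarsened-exposure Mendelian randomisation estimators.
#
# The binary exposure D is a thresholded observation of a latent liability
# L = G + V (plus measured-confounder terms when M is supplied), with
# Var(L) = 1 and theta2 = Var(G) the liability heritability. A probit
# regression of D on the instruments identifies c_j = gamma_j / sd(V), the
# per-allele liability effect on the residual (V-normalised) scale;
# multiplying by sqrt(1 - theta2) converts to the total-liability SD scale:
# gamma*_j = c_j * sqrt(1 - theta2). Per-instrument Wald ratios
# b_j = beta_Yj / gamma*_j (outcome log-RR over liability effect) are pooled
# by inverse-variance weighting or through a cross-validated PRS instrument,
# giving the causal log relative risk of the outcome per 1 SD of exposure
# liability.

#' Probit regression of the binary exposure on its instruments
#'
#' Maximum-likelihood probit fit of `D` on the instrument allele counts
#' (plus measured confounders, if any), together with the matching null fit
#' (confounders only, or intercept only) on the same rows. The instrument
#' coefficients `c_j` are liability effects per allele on the
#' residual-liability scale; their empirical genetic-share variance
#' `s2 = var(Z c)` feeds the heritability lower bound
#' [estimate_theta2_lower_bound()].
#'
#' Missing allele counts are mean-imputed (dosage convention for multi-SNP
#' fits; per-SNP QC has already removed high-missingness variants).
#'
#' @param D Binary 0/1 exposure vector; both classes must be present.
#' @param Z Numeric matrix of instrument allele counts (columns named by
#'   SNP id), or a [genotype_matrix()].
#' @param M Optional data frame of measured confounders.
#' @return A `genetic_share_fit`: instrument coefficients `coef` with `se`
#'   and covariance `vcov`, confounder coefficients `confounder_coef`,
#'   log-likelihoods `loglik_full` / `loglik_null`, genetic-share variance
#'   `s2`, `converged`, `n`.
#' @export
fit_genetic_share <- function(D, Z, M = NULL) {
  if (inherits(Z, "genotype_matrix")) Z <- Z$values
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("snp", seq_len(ncol(Z)))
  D <- as.numeric(D)
  stopifnot(length(D) == nrow(Z))
  if (length(unique(stats::na.omit(D))) < 2)
    stop("exposure D is constant: probit fit is undefined")
  Mx <- if (!is.null(M) && ncol(as.data.frame(M)) > 0)
    as.matrix(as.data.frame(M)) else NULL
  ok <- !is.na(D) & (if (is.null(Mx)) TRUE else stats::complete.cases(Mx))
  Z <- impute_dosage(Z[ok, , drop = FALSE])
  D <- D[ok]
  if (!is.null(Mx)) Mx <- Mx[ok, , drop = FALSE]
  k <- ncol(Z)
  # constant columns carry no exposure information: coefficient 0 by
  # convention, excluded from the design so the fit stays full-rank
  zv <- apply(Z, 2, stats::var) == 0
  Zfit <- Z[, !zv, drop = FALSE]
  X_full <- cbind(`(Intercept)` = rep(1, length(D)), Zfit, Mx)
  X_null <- cbind(`(Intercept)` = rep(1, length(D)), Mx)
  full <- ml_fit(X_full, D, family = "probit")
  null <- ml_fit(X_null, D, family = "probit")
  if (isTRUE(full$failed) || !full$converged) {
    bad <- if (!is.null(full$se) && any(!is.finite(full$se)))
      colnames(X_full)[!is.finite(full$se)] else colnames(Zfit)
    stop("probit fit of exposure on instruments failed to converge ",
         "(possible separation); offending column(s): ",
         paste(bad, collapse = ", "))
  }
  kf <- ncol(Zfit)
  cidx <- if (kf) 1 + seq_len(kf) else integer(0)
  cj <- se_c <- setNames(rep(0, k), colnames(Z))
  se_c[] <- NA_real_
  vc <- matrix(0, k, k, dimnames = list(colnames(Z), colnames(Z)))
  if (kf) {
    cj[colnames(Zfit)] <- full$coef[cidx]
    se_c[colnames(Zfit)] <- full$se[cidx]
    vc[colnames(Zfit), colnames(Zfit)] <- full$vcov[cidx, cidx]
  }
  gshare <- drop(Z %*% cj)
  structure(list(
    coef = cj,
    se = se_c,
    vcov = vc,
    confounder_coef = if (is.null(Mx)) numeric(0)
                      else setNames(full$coef[(1 + kf) + seq_len(ncol(Mx))],
                                    colnames(Mx)),
    intercept = unname(full$coef[1]),
    loglik_full = full$loglik,
    loglik_null = null$loglik,
    s2 = stats::var(gshare),
    genetic_share = gshare,
    converged = full$converged && null$converged,
    n = full$n, k = k), class = "genetic_share_fit")
}

#' @export
print.genetic_share_fit <- function(x, ...) {
  cat("<genetic_share_fit> ", x$k, " instrument(s), n = ", x$n, "\n", sep = "")
  cat(sprintf("  s2 = %.5f  theta2 lower bound = %.5f\n", x$s2,
              estimate_theta2_lower_bound(x)))
  lrt <- instrument_strength_lrt(x)
  cat(sprintf("  LRT = %.2f (df = %d, p = %.3g)\n", lrt$statistic, lrt$df,
              lrt$p))
  invisible(x)
}

#' Likelihood-ratio test of instrument strength
#'
#' Tests whether all instrument coefficients in the probit liability
#' regression are zero: `statistic = 2 (ll_full - ll_null)`, chi-square
#' with `k` degrees of freedom.
#'
#' @param fit A [fit_genetic_share()] result.
#' @param k Number of instruments (defaults to `fit$k`).
#' @return List with `statistic`, `df`, `p`.
#' @export
instrument_strength_lrt <- function(fit, k = fit$k) {
  stopifnot(inherits(fit, "genetic_share_fit"))
  stat <- max(0, 2 * (fit$loglik_full - fit$loglik_null))
  list(statistic = stat, df = k,
       p = stats::pchisq(stat, df = k, lower.tail = FALSE))
}

#' Lower bound for the liability heritability
#'
#' With the environmental share normalised to unit variance, the fitted
#' genetic share `sum_j c_j Z_j` has sample variance `s2` on the residual
#' scale, and `theta2_hat = s2 / (s2 + 1)` is the heritability attributable
#' to the measured instruments — a lower bound for the full heritability
#' whenever unmeasured variants carry part of the genetic share.
#'
#' @param fit A [fit_genetic_share()] result.
#' @return `theta2_hat` in `[0, 1)`.
#' @export
estimate_theta2_lower_bound <- function(fit) {
  stopifnot(inherits(fit, "genetic_share_fit"))
  fit$s2 / (fit$s2 + 1)
}

#' Per-instrument outcome associations on the log-RR scale
#'
#' Fits, for each instrument separately, the log-linear model
#' `log P(Y = 1) = a + beta_Yj Z_j + delta' M` using a Poisson working
#' likelihood with HC0 robust (sandwich) standard errors — the standard
#' consistent relative-risk regression for binary outcomes. Set
#' `method = "log-binomial"` for log-binomial ML (may fail to converge; a
#' failed log-binomial fit falls back to the Poisson working model and is
#' flagged).
#'
#' @param Y Binary 0/1 outcome vector, both classes present.
#' @param Z Instrument allele-count matrix or [genotype_matrix()].
#' @param M Optional confounder data frame.
#' @param method `"poisson-robust"` (default) or `"log-binomial"`.
#' @return Data frame: `snp`, `beta` (log-RR per allele), `se`, `n`,
#'   `converged`, `method`.
#' @export
outcome_scan <- function(Y, Z, M = NULL,
                         method = c("poisson-robust", "log-binomial")) {
  method <- match.arg(method)
  if (inherits(Z, "genotype_matrix")) Z <- Z$values
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("snp", seq_len(ncol(Z)))
  Y <- as.numeric(Y)
  stopifnot(length(Y) == nrow(Z))
  if (length(unique(stats::na.omit(Y))) < 2)
    stop("outcome Y is constant: association is undefined")
  Mx <- if (!is.null(M) && ncol(as.data.frame(M)) > 0)
    as.matrix(as.data.frame(M)) else NULL
  rows <- lapply(seq_len(ncol(Z)), function(j) {
    X <- cbind(`(Intercept)` = 1, dosage = Z[, j], Mx)
    ok <- stats::complete.cases(X) & !is.na(Y)
    X <- X[ok, , drop = FALSE]
    y <- Y[ok]
    used <- method
    if (method == "log-binomial") {
      fit <- ml_fit(X, y, family = "log-binomial", robust = FALSE)
      if (isTRUE(fit$failed) || !fit$converged) {
        fit <- ml_fit(X, y, family = "log-poisson", robust = TRUE)
        used <- "poisson-robust-fallback"
      } else {
        fit$se_robust <- fit$se
      }
    } else {
      fit <- ml_fit(X, y, family = "log-poisson", robust = TRUE)
    }
    data.frame(snp = colnames(Z)[j], beta = unname(fit$coef[2]),
               se = unname(fit$se_robust[2]), n = length(y),
               converged = isTRUE(fit$converged), method = used)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Liability-scale Wald ratios
#'
#' Rescales the probit instrument coefficients to the total-liability SD
#' scale, `gamma*_j = c_j sqrt(1 - theta2)`, and forms per-instrument Wald
#' ratios `b_j = beta_Yj / gamma*_j` with first-order delta-method standard
#' errors `se_j = se(beta_Yj) / |gamma*_j|` (uncertainty in `c_j` is not
#' propagated; see the package vignette).
#'
#' @param exposure_fit A [fit_genetic_share()] result.
#' @param outcome_betas Data frame from [outcome_scan()] (columns `snp`,
#'   `beta`, `se`).
#' @param theta2 Liability heritability used for the rescaling, in
#'   `[0, 1)`.
#' @param c_tol Instruments with `|c_j|` below this tolerance are excluded
#'   with a warning (the ratio is unstable). Default 1e-8.
#' @return A `ratio_table` data frame: `snp`, `beta_y`, `se_y`, `c`,
#'   `gamma_star`, `b`, `se`.
#' @export
liability_wald_ratios <- function(exposure_fit, outcome_betas, theta2,
                                  c_tol = 1e-8) {
  stopifnot(inherits(exposure_fit, "genetic_share_fit"),
            theta2 >= 0, theta2 < 1)
  ids <- intersect(names(exposure_fit$coef), outcome_betas$snp)
  if (!length(ids)) stop("no instruments shared between exposure fit and ",
                         "outcome associations")
  cj <- exposure_fit$coef[ids]
  ob <- outcome_betas[match(ids, outcome_betas$snp), ]
  unstable <- abs(cj) < c_tol
  if (any(unstable)) {
    warning("excluding instrument(s) with |c_j| < ", format(c_tol),
            " (unstable ratio): ", paste(ids[unstable], collapse = ", "))
    ids <- ids[!unstable]
    cj <- cj[!unstable]
    ob <- ob[!unstable, , drop = FALSE]
  }
  gamma_star <- cj * sqrt(1 - theta2)
  tab <- data.frame(snp = ids, beta_y = ob$beta, se_y = ob$se,
                    c = unname(cj), gamma_star = unname(gamma_star),
                    b = ob$beta / unname(gamma_star),
                    se = ob$se / abs(unname(gamma_star)), row.names = NULL)
  class(tab) <- c("ratio_table", class(tab))
  tab
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j (b_j - b_FE)^2 / se_j^2` with `b_FE` the fixed-effect
#' (precision-weighted) pooled ratio, referred to chi-square with `k - 1`
#' degrees of freedom. The fixed-effect model is retained when
#' `p >= alpha`, otherwise the (multiplicative) random-effects model.
#'
#' @param ratios A `ratio_table` with at least 2 rows.
#' @param alpha Model-choice level (default 0.05).
#' @return List with `Q`, `df`, `p`, `model` (`"fixed"` or `"random"`).
#' @export
cochran_q <- function(ratios, alpha = 0.05) {
  k <- nrow(ratios)
  if (k < 2) stop("Cochran's Q needs at least 2 instruments")
  w <- 1 / ratios$se^2
  b_fe <- sum(w * ratios$b) / sum(w)
  Q <- sum(w * (ratios$b - b_fe)^2)
  p <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  list(Q = Q, df = k - 1L, p = p,
       model = if (p >= alpha) "fixed" else "random")
}

mr_estimate <- function(method, theta2, estimate, se, extra = list()) {
  est <- list(method = method, theta2 = theta2, estimate = estimate,
              se = se, rr = exp(estimate),
              ci_low = exp(estimate - 1.96 * se),
              ci_high = exp(estimate + 1.96 * se),
              p = wald_p(estimate, se))
  structure(c(est, extra), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (theta2 = %.3f): RR %.3f [%.3f, %.3f], p = %.4g\n",
              x$method, x$theta2, x$rr, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Inverse-variance weighted pooling of Wald ratios
#'
#' Fixed-effect: `b_hat = sum(b_j / se_j^2) / sum(1 / se_j^2)` with
#' `SE = (sum 1/se_j^2)^(-1/2)`. Random-effects: the fixed-effect estimate
#' with its SE inflated by `sqrt(max(1, Q / (k - 1)))` (multiplicative
#' overdispersion). With `model = "auto"` the model is chosen by
#' [cochran_q()]; a single ratio forces the fixed-effect model.
#'
#' @param ratios A `ratio_table` with at least one row.
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @param theta2 The heritability value the ratios were computed at
#'   (recorded in the estimate).
#' @return An `mr_estimate` (method `"IVW-FE"` or `"IVW-RE"`) with the
#'   heterogeneity results attached (`Q`, `Q_df`, `Q_p`).
#' @export
ivw_combine <- function(ratios, model = c("auto", "fixed", "random"),
                        theta2 = NA_real_) {
  model <- match.arg(model)
  k <- nrow(ratios)
  if (!k) stop("empty ratio table")
  w <- 1 / ratios$se^2
  b_hat <- sum(w * ratios$b) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  het <- if (k >= 2) cochran_q(ratios) else
    list(Q = NA_real_, df = 0L, p = NA_real_, model = "fixed")
  if (model == "auto") model <- het$model
  if (k == 1) model <- "fixed"
  se <- if (model == "random")
    se_fe * sqrt(max(1, het$Q / (k - 1))) else se_fe
  mr_estimate(if (model == "random") "IVW-RE" else "IVW-FE", theta2,
              b_hat, se,
              extra = list(Q = het$Q, Q_df = het$df, Q_p = het$p,
                           model = model, k = k))
}

#' Polygenic-risk-score estimator
#'
#' Combines all instruments into a single score instrument. Individuals
#' are partitioned into `n_folds` (seeded); for each fold, instrument
#' weights are the logistic-regression coefficients of `D` on all
#' instruments (plus confounders) fitted on the *other* folds, and each
#' individual's PRS is scored with their out-of-fold weights (set
#' `average_weights = TRUE` to score everyone with the fold-averaged
#' weights instead). The PRS then plays the single-instrument role:
#' probit `D ~ PRS + M` gives `c_S`, log-linear `Y ~ PRS + M` (Poisson
#' working likelihood, robust SE) gives `beta_YS`, and the estimate is
#' `beta_YS / (c_S sqrt(1 - theta2))` with the first-order delta-method SE.
#'
#' @param D,Y Binary exposure and outcome vectors.
#' @param Z Instrument allele-count matrix or [genotype_matrix()].
#' @param M Optional confounder data frame.
#' @param theta2 Liability heritability for the rescaling.
#' @param n_folds Number of cross-validation folds (default 10).
#' @param seed Seed for the fold partition.
#' @param average_weights Score with fold-averaged weights.
#' @param max_refolds Refold attempts if a training fold lacks an exposure
#'   class.
#' @return An `mr_estimate` (method `"PRS"`), with `c_S`, `beta_YS` and
#'   the per-fold weight matrix attached.
#' @export
prs_method <- function(D, Y, Z, M = NULL, theta2, n_folds = 10, seed = 1L,
                       average_weights = FALSE, max_refolds = 10L) {
  if (inherits(Z, "genotype_matrix")) Z <- Z$values
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("snp", seq_len(ncol(Z)))
  stopifnot(n_folds >= 2, length(D) == nrow(Z), length(Y) == nrow(Z))
  D <- as.numeric(D)
  Y <- as.numeric(Y)
  Z <- impute_dosage(Z)
  Mx <- if (!is.null(M) && ncol(as.data.frame(M)) > 0)
    as.matrix(as.data.frame(M)) else NULL
  n <- nrow(Z)
  set.seed(seed)
  folds <- NULL
  for (try in seq_len(max_refolds)) {
    cand <- sample(rep_len(seq_len(n_folds), n))
    ok <- all(vapply(seq_len(n_folds), function(f) {
      d <- D[cand != f]
      length(unique(d)) == 2
    }, TRUE))
    if (ok) {
      folds <- cand
      break
    }
  }
  if (is.null(folds))
    stop("could not build ", n_folds, " folds with both exposure classes ",
         "in every training set after ", max_refolds, " attempts")
  k <- ncol(Z)
  W <- matrix(NA_real_, n_folds, k, dimnames = list(NULL, colnames(Z)))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    X <- cbind(`(Intercept)` = 1, Z[tr, , drop = FALSE],
               if (is.null(Mx)) NULL else Mx[tr, , drop = FALSE])
    fit <- ml_fit(X, D[tr], family = "logit")
    if (isTRUE(fit$failed) || !fit$converged)
      fit <- ridge_logistic(X, D[tr])
    W[f, ] <- fit$coef[1 + seq_len(k)]
  }
  prs <- numeric(n)
  if (average_weights) {
    wbar <- colMeans(W)
    prs <- drop(Z %*% wbar)
  } else {
    for (f in seq_len(n_folds)) {
      idx <- folds == f
      prs[idx] <- drop(Z[idx, , drop = FALSE] %*% W[f, ])
    }
  }
  sfit <- fit_genetic_share(D, matrix(prs, ncol = 1,
                                      dimnames = list(NULL, "PRS")), M)
  obeta <- outcome_scan(Y, matrix(prs, ncol = 1,
                                  dimnames = list(NULL, "PRS")), M)
  c_s <- unname(sfit$coef["PRS"])
  gamma_star <- c_s * sqrt(1 - theta2)
  if (abs(c_s) < 1e-12)
    stop("PRS carries no exposure information (c_S ~ 0)")
  mr_estimate("PRS", theta2, obeta$beta / gamma_star,
              obeta$se / abs(gamma_star),
              extra = list(c_S = c_s, beta_YS = obeta$beta,
                           se_YS = obeta$se, weights = W,
                           n_folds = n_folds,
                           prs_fit = sfit))
}

#' Sensitivity sweep over the liability heritability
#'
#' Recomputes the IVW (model chosen by Cochran's Q — invariant across the
#' grid, since a common rescaling leaves Q unchanged) and PRS causal
#' estimates over a grid of `theta2` values. The probit exposure fit,
#' per-instrument outcome fits and the PRS core fits are computed once;
#' only the `sqrt(1 - theta2)` scaling varies across the grid.
#'
#' @param D,Y,Z,M As in [prs_method()].
#' @param theta2_grid Numeric grid of heritability values in `[0, 1)`;
#'   the data-estimated value [estimate_theta2_lower_bound()] is added and
#'   flagged unless `add_estimate = FALSE`.
#' @param add_estimate Include the estimated `theta2` in the grid.
#' @param prs_seed,n_folds Passed to [prs_method()].
#' @return A `sensitivity_table` data frame: one row per method per grid
#'   value with columns `method`, `theta2`, `estimated`, `log_rr`, `se`,
#'   `rr`, `ci_low`, `ci_high`, `p`, `Q`, `Q_p`, `model`; the underlying
#'   fits are attached as attributes `exposure_fit`, `outcome_betas`,
#'   `lrt`, `theta2_hat`.
#' @export
sensitivity_sweep <- function(D, Y, Z, M = NULL, theta2_grid,
                              add_estimate = TRUE, prs_seed = 1L,
                              n_folds = 10) {
  if (!length(theta2_grid) && !add_estimate)
    stop("theta2 grid is empty")
  stopifnot(all(theta2_grid >= 0 & theta2_grid < 1))
  fit <- fit_genetic_share(D, Z, M)
  theta2_hat <- estimate_theta2_lower_bound(fit)
  obetas <- outcome_scan(Y, Z, M)
  grid <- sort(unique(c(theta2_grid, if (add_estimate) theta2_hat)))
  # PRS core fits are theta2-free; rescale per grid point
  prs0 <- prs_method(D, Y, Z, M, theta2 = 0, n_folds = n_folds,
                     seed = prs_seed)
  rows <- lapply(grid, function(t2) {
    ratios <- liability_wald_ratios(fit, obetas, t2)
    ivw <- ivw_combine(ratios, model = "auto", theta2 = t2)
    sc <- 1 / sqrt(1 - t2)
    prs_est <- mr_estimate("PRS", t2, prs0$estimate * sc, prs0$se * sc)
    est_flag <- isTRUE(all.equal(t2, theta2_hat))
    rbind(
      data.frame(method = ivw$method, theta2 = t2, estimated = est_flag,
                 log_rr = ivw$estimate, se = ivw$se, rr = ivw$rr,
                 ci_low = ivw$ci_low, ci_high = ivw$ci_high, p = ivw$p,
                 Q = ivw$Q, Q_p = ivw$Q_p, model = ivw$model),
      data.frame(method = "PRS", theta2 = t2, estimated = est_flag,
                 log_rr = prs_est$estimate, se = prs_est$se,
                 rr = prs_est$rr, ci_low = prs_est$ci_low,
                 ci_high = prs_est$ci_high, p = prs_est$p,
                 Q = NA_real_, Q_p = NA_real_, model = NA_character_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exposure_fit") <- fit
  attr(out, "outcome_betas") <- obetas
  attr(out, "lrt") <- instrument_strength_lrt(fit)
  attr(out, "theta2_hat") <- theta2_hat
  class(out) <- c("sensitivity_table", class(out))
  out
}
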
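# Instrument selection: per-SNP logistic association scans under several
# covariate-adjustment scenarios, genome-wide significance filtering, LD
# pruning on dosage r^2, and cross-scenario intersection.

#' Per-SNP logistic association scan
#'
#' Fits a maximum-likelihood logistic regression of the binary phenotype on
#' each SNP's additive allele count, separately under each covariate
#' scenario, using per-SNP complete cases. Fits that fail to converge are
#' retried with a small ridge penalty (quasi-separation at low minor-allele
#' counts) and flagged, never silently dropped.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype Binary 0/1 vector, one entry per individual; both
#'   classes must be present.
#' @param covariates Data frame of covariates (same row order), or `NULL`.
#' @param covariate_scenarios List of character vectors naming the
#'   covariates used in each scenario; `character(0)` means unadjusted.
#'   Default: the single unadjusted scenario.
#' @param scenario_labels Optional names for the scenarios (defaults to
#'   `"unadjusted"` or `"adj_<cov1>_<cov2>..."`).
#' @return A data frame of class `association_table` with one row per SNP
#'   per scenario: `snp`, `scenario`, `beta` (log-odds per allele), `se`,
#'   `p`, `n`, `converged`.
#' @export
logistic_scan <- function(genotypes, phenotype, covariates = NULL,
                          covariate_scenarios = list(character(0)),
                          scenario_labels = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  phenotype <- as.numeric(phenotype)
  if (length(phenotype) != n_individuals(genotypes))
    stop("phenotype length must equal the number of individuals")
  if (length(unique(stats::na.omit(phenotype))) < 2)
    stop("phenotype is constant: association scan is undefined")
  if (is.null(scenario_labels))
    scenario_labels <- vapply(covariate_scenarios, function(cv)
      if (!length(cv)) "unadjusted" else paste0("adj_", paste(cv, collapse = "_")),
      "")
  out <- vector("list", length(covariate_scenarios))
  for (s in seq_along(covariate_scenarios)) {
    cv <- covariate_scenarios[[s]]
    if (length(cv)) {
      missing_cv <- setdiff(cv, names(covariates))
      if (length(missing_cv))
        stop("scenario covariates not found: ",
             paste(missing_cv, collapse = ", "))
      Mx <- as.matrix(covariates[, cv, drop = FALSE])
    } else Mx <- NULL
    res <- lapply(seq_len(n_snps(genotypes)), function(j) {
      z <- genotypes$values[, j]
      X <- cbind(`(Intercept)` = 1, dosage = z, Mx)
      ok <- stats::complete.cases(X) & !is.na(phenotype)
      X <- X[ok, , drop = FALSE]
      y <- phenotype[ok]
      if (length(unique(y)) < 2 || length(unique(X[, "dosage"])) < 2)
        return(c(NA_real_, NA_real_, NA_real_, sum(ok), 0))
      fit <- ml_fit(X, y, family = "logit")
      if (!fit$converged) {
        fit <- ridge_logistic(X, y)
        if (!fit$converged)
          return(c(NA_real_, NA_real_, NA_real_, length(y), 0))
      }
      b <- fit$coef[2]
      se <- fit$se[2]
      c(b, se, wald_p(b, se), length(y), 1)
    })
    res <- do.call(rbind, res)
    out[[s]] <- data.frame(snp = genotypes$snp_meta$id,
                           scenario = scenario_labels[s],
                           beta = res[, 1], se = res[, 2], p = res[, 3],
                           n = as.integer(res[, 4]),
                           converged = res[, 5] == 1, row.names = NULL)
  }
  tab <- do.call(rbind, out)
  class(tab) <- c("association_table", class(tab))
  tab
}

#' Greedy LD pruning on dosage correlation
#'
#' Iterates the candidate SNPs in the given rank order (best evidence
#' first) and keeps a SNP iff its squared Pearson correlation of allele
#' counts with every already-kept SNP is below the threshold. r^2 is
#' computed on pairwise-complete individuals (composite LD on dosages;
#' phase is not needed).
#'
#' @param genotypes A [genotype_matrix()].
#' @param candidates Character vector of SNP ids, ranked (e.g. by ascending
#'   GWAS p-value).
#' @param r2_threshold Exclusion threshold in `(0, 1]`: pairs with
#'   `r^2 >= r2_threshold` may not co-occur.
#' @return Character vector of kept SNP ids, in candidate order.
#' @export
ld_prune <- function(genotypes, candidates, r2_threshold) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            r2_threshold > 0, r2_threshold <= 1)
  missing_ids <- setdiff(candidates, genotypes$snp_meta$id)
  if (length(missing_ids))
    stop("candidates not in genotype matrix: ",
         paste(missing_ids, collapse = ", "))
  vals <- genotypes$values[, candidates, drop = FALSE]
  mono <- apply(vals, 2, function(z) stats::var(z, na.rm = TRUE)) %in%
    c(0, NA) | apply(vals, 2, function(z) sum(!is.na(z)) < 2)
  if (any(mono)) {
    warning("excluding monomorphic candidate(s) with undefined r^2: ",
            paste(candidates[mono], collapse = ", "))
    candidates <- candidates[!mono]
    vals <- vals[, candidates, drop = FALSE]
  }
  kept <- character(0)
  for (id in candidates) {
    if (!length(kept)) {
      kept <- id
      next
    }
    r <- stats::cor(vals[, id], vals[, kept, drop = FALSE],
                    use = "pairwise.complete.obs")
    r[is.na(r)] <- 0
    if (all(r^2 < r2_threshold)) kept <- c(kept, id)
  }
  kept
}

#' Select instruments across GWAS scenarios
#'
#' Takes the SNPs reaching the significance threshold in *every* scenario
#' (intersection), warns if the per-scenario significant sets differ, then
#' LD-prunes the intersection with [ld_prune()], ranking by ascending
#' p-value in the first scenario (ties by genomic position, then id).
#'
#' @param tables An `association_table` from [logistic_scan()] (all
#'   scenarios stacked), or a list of per-scenario tables.
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param genotypes A [genotype_matrix()] for LD pruning.
#' @param r2_threshold LD pruning threshold (default 0.001).
#' @return An `instrument_set`: list with `ids` (ordered kept SNPs),
#'   `associations` (exposure association rows for the kept SNPs, all
#'   scenarios) and `provenance` (per-SNP flags `passed_gwas`,
#'   `passed_pruning`, `passed_confounder_screen`, `pleiotropy_suspect`).
#'   An empty intersection yields an empty set with a warning, not an
#'   error.
#' @export
select_instruments <- function(tables, p_threshold = 5e-8, genotypes,
                               r2_threshold = 0.001) {
  if (is.list(tables) && !is.data.frame(tables))
    tables <- do.call(rbind, tables)
  stopifnot(is.data.frame(tables),
            all(c("snp", "scenario", "p") %in% names(tables)))
  scenarios <- unique(tables$scenario)
  sig_sets <- lapply(scenarios, function(s) {
    rows <- tables[tables$scenario == s & !is.na(tables$p), ]
    rows$snp[rows$p < p_threshold]
  })
  hits <- Reduce(intersect, sig_sets)
  if (length(unique(lapply(sig_sets, sort))) > 1)
    warning("significant SNP sets differ across adjustment scenarios; ",
            "using their intersection")
  if (!length(hits)) {
    warning("no SNP reaches p < ", format(p_threshold),
            " in every scenario: empty instrument set")
    return(instrument_set(character(0), tables[0, , drop = FALSE]))
  }
  # rank by p in the first scenario; ties by position then id
  first <- tables[tables$scenario == scenarios[1], ]
  pos <- genotypes$snp_meta$position[match(hits, genotypes$snp_meta$id)]
  pval <- first$p[match(hits, first$snp)]
  hits <- hits[order(pval, pos, hits)]
  kept <- ld_prune(genotypes, hits, r2_threshold)
  prov <- data.frame(snp = hits, passed_gwas = TRUE,
                     passed_pruning = hits %in% kept,
                     passed_confounder_screen = NA,
                     pleiotropy_suspect = FALSE, row.names = NULL)
  instrument_set(kept, tables[tables$snp %in% kept, , drop = FALSE], prov)
}

#' Construct an instrument set
#'
#' @param ids Ordered character vector of instrument SNP ids.
#' @param associations Exposure association rows (as from
#'   [logistic_scan()]) for the instruments.
#' @param provenance Per-SNP provenance flags; a default frame is built if
#'   omitted.
#' @return An `instrument_set` object.
#' @export
instrument_set <- function(ids, associations = NULL, provenance = NULL) {
  ids <- as.character(ids)
  if (is.null(provenance))
    provenance <- data.frame(snp = ids,
                             passed_gwas = rep(NA, length(ids)),
                             passed_pruning = rep(NA, length(ids)),
                             passed_confounder_screen = rep(NA, length(ids)),
                             pleiotropy_suspect = rep(FALSE, length(ids)),
                             row.names = NULL)
  structure(list(ids = ids, associations = associations,
                 provenance = provenance), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("<instrument_set> ", length(x$ids), " instrument(s)",
      if (length(x$ids)) paste0(": ", paste(x$ids, collapse = ", ")), "\n",
      sep = "")
  invisible(x)
}

#' @export
length.instrument_set <- function(x) length(x$ids)
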
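# SNP quality control: call rate, Hardy-Weinberg equilibrium in controls,
# minor allele frequency.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the sum of probabilities of all heterozygote configurations
#' whose conditional probability does not exceed that of the observed
#' configuration. Configuration probabilities are evaluated in log space via
#' log-gamma, so totals in the tens of thousands are no problem. A chi-square (1 df, no continuity correction)
#' variant is available behind `method = "chisq"`.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return The p-value in `(0, 1]`; monomorphic sites (a single attainable
#'   configuration) return 1.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt,
                           method = c("exact", "chisq")) {
  method <- match.arg(method)
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  n_a <- 2 * n_hom_alt + n_het   # minor-allele-side count (symmetric anyway)
  n_b <- 2 * n_hom_ref + n_het
  rare <- min(n_a, n_b)
  if (method == "chisq") {
    p_ref <- n_b / (2 * n)
    expd <- n * c(p_ref^2, 2 * p_ref * (1 - p_ref), (1 - p_ref)^2)
    if (any(expd == 0)) return(1)
    x2 <- sum((counts - expd)^2 / expd)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # heterozygote count shares the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  if (length(hets) <= 1) return(1)
  # log P(het = h | allele counts) up to a constant:
  #   log n! - log((n_a-h)/2)! - log h! - log((n_b-h)/2)! + h log 2
  logp <- lgamma(n + 1) - lgamma((n_a - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_b - hets) / 2 + 1) + hets * log(2)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("heterozygote count incompatible with allele totals")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-10)]))
}

#' QC thresholds
#'
#' Default thresholds: maximum genotype missing rate 0.1, Hardy-Weinberg
#' p-value floor 1e-6 (tested in controls), minimum minor allele frequency
#' 0.01.
#'
#' @param max_missing_rate,hwe_p_min,maf_min Threshold values, each in
#'   `[0, 1]`.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_missing_rate = 0.1, hwe_p_min = 1e-6,
                          maf_min = 0.01) {
  vals <- c(max_missing_rate, hwe_p_min, maf_min)
  if (any(vals < 0 | vals > 1))
    stop("QC thresholds must lie in [0,1]")
  structure(list(max_missing_rate = max_missing_rate, hwe_p_min = hwe_p_min,
                 maf_min = maf_min), class = "qc_thresholds")
}

#' Apply SNP quality-control filters
#'
#' Filters SNPs by call rate, minor allele frequency (both over all
#' individuals) and Hardy-Weinberg equilibrium (tested in controls only).
#' Filters are evaluated in the order call rate, MAF, HWE and the recorded
#' `removal_reason` is the first violated; the kept set does not depend on
#' the order.
#'
#' @param genotypes A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @param control_mask Logical vector over individuals; `TRUE` marks
#'   controls (HWE is computed on these rows only). Must contain at least
#'   one control.
#' @param hwe_method Passed to [hwe_exact_test()].
#' @return List with `genotypes` (kept SNPs only) and `report` (a
#'   `qc_report` data frame: `id`, `call_rate`, `maf`, `hwe_p`, `kept`,
#'   `removal_reason`).
#' @export
apply_qc <- function(genotypes, thresholds = qc_thresholds(), control_mask,
                     hwe_method = c("exact", "chisq")) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  hwe_method <- match.arg(hwe_method)
  if (length(control_mask) != n_individuals(genotypes))
    stop("control_mask length must equal the number of individuals")
  control_mask <- as.logical(control_mask)
  if (!any(control_mask, na.rm = TRUE)) stop("no controls for the HWE test")

  st <- snp_stats(genotypes)
  ctrl <- genotypes$values[which(control_mask), , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(ctrl)), function(j) {
    z <- ctrl[, j]
    z <- z[!is.na(z)]
    if (!length(z)) return(NA_real_)
    hwe_exact_test(sum(z == 0), sum(z == 1), sum(z == 2),
                   method = hwe_method)
  }, 0)

  reason <- rep("", n_snps(genotypes))
  fail_call <- st$call_rate < 1 - thresholds$max_missing_rate
  fail_maf <- !is.na(st$maf) & st$maf < thresholds$maf_min
  fail_maf[is.na(st$maf)] <- TRUE  # no calls at all
  fail_hwe <- !is.na(hwe_p) & hwe_p < thresholds$hwe_p_min
  reason[fail_hwe] <- "hwe"
  reason[fail_maf] <- "maf"
  reason[fail_call] <- "call_rate"
  kept <- reason == ""
  report <- data.frame(id = st$id, call_rate = st$call_rate, maf = st$maf,
                       hwe_p = hwe_p, kept = kept,
                       removal_reason = reason, row.names = NULL)
  class(report) <- c("qc_report", class(report))
  out_geno <- subset_snps(genotypes, st$id[kept])
  list(genotypes = out_geno, report = report)
}
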
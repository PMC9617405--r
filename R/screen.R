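# Instrument-confounder independence screen: chi-square for categorical
# confounders, Spearman rank correlation for continuous ones,
# Benjamini-Hochberg FDR across all (SNP, confounder) pairs jointly, then
# removal of violating instruments.

#' Test instrument independence from measured confounders
#'
#' For each (instrument, confounder) pair runs a chi-square test of
#' independence of the 3-level genotype against a categorical confounder,
#' or a Spearman rank correlation of allele count against a continuous
#' confounder, then Benjamini-Hochberg-adjusts all raw p-values jointly.
#'
#' @param genotypes A [genotype_matrix()].
#' @param instruments An [instrument_set()] (or character vector of SNP
#'   ids).
#' @param confounders Data frame of confounder columns (same row order as
#'   the genotypes).
#' @param confounder_types Named character vector mapping each confounder
#'   column to `"categorical"` or `"continuous"`.
#' @return A `confounder_test_table` data frame: `snp`, `confounder`,
#'   `test`, `statistic`, `p_raw`, `p_adj`. Pairs whose genotype column has
#'   fewer than 2 observed levels are skipped with a warning.
#' @export
confounder_independence <- function(genotypes, instruments, confounders,
                                    confounder_types) {
  ids <- if (inherits(instruments, "instrument_set")) instruments$ids
         else as.character(instruments)
  stopifnot(inherits(genotypes, "genotype_matrix"), is.data.frame(confounders))
  missing_types <- setdiff(names(confounders), names(confounder_types))
  if (length(missing_types))
    stop("confounder type not declared for: ",
         paste(missing_types, collapse = ", "))
  bad <- setdiff(unname(confounder_types[names(confounders)]),
                 c("categorical", "continuous"))
  if (length(bad))
    stop("confounder types must be 'categorical' or 'continuous'")
  rows <- list()
  for (id in ids) {
    z <- genotypes$values[, id]
    if (length(unique(stats::na.omit(z))) < 2) {
      warning("instrument ", id,
              " has < 2 observed genotype levels: tests skipped")
      next
    }
    for (cf in names(confounders)) {
      x <- confounders[[cf]]
      ok <- !is.na(z) & !is.na(x)
      if (confounder_types[[cf]] == "categorical") {
        tt <- suppressWarnings(stats::chisq.test(table(z[ok], x[ok])))
        rows[[length(rows) + 1L]] <-
          data.frame(snp = id, confounder = cf, test = "chi-square",
                     statistic = unname(tt$statistic),
                     p_raw = tt$p.value)
      } else {
        tt <- suppressWarnings(stats::cor.test(z[ok], x[ok],
                                               method = "spearman",
                                               exact = FALSE))
        rows[[length(rows) + 1L]] <-
          data.frame(snp = id, confounder = cf, test = "spearman",
                     statistic = unname(tt$estimate),
                     p_raw = tt$p.value)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(0), confounder = character(0),
               test = character(0), statistic = numeric(0),
               p_raw = numeric(0))
  tab$p_adj <- stats::p.adjust(tab$p_raw, method = "BH")
  rownames(tab) <- NULL
  class(tab) <- c("confounder_test_table", class(tab))
  tab
}

#' Remove instruments associated with measured confounders
#'
#' Drops every instrument whose FDR-adjusted p-value against any measured
#' confounder falls below `alpha` (set `use_raw_p = TRUE` to threshold the
#' raw p-values instead). Removal is recorded in the provenance flags.
#'
#' @param instruments An [instrument_set()].
#' @param tests A `confounder_test_table` from
#'   [confounder_independence()]; must cover all instruments.
#' @param alpha Removal threshold (default 0.05).
#' @param use_raw_p Threshold raw instead of adjusted p-values.
#' @return The filtered [instrument_set()], with `removed` (character
#'   vector) attached as an element. An empty result is allowed (with a
#'   warning).
#' @export
filter_instruments <- function(instruments, tests, alpha = 0.05,
                               use_raw_p = FALSE) {
  stopifnot(inherits(instruments, "instrument_set"))
  uncovered <- setdiff(instruments$ids, tests$snp)
  if (length(uncovered))
    stop("tests do not cover instrument(s): ",
         paste(uncovered, collapse = ", "))
  pcol <- if (use_raw_p) tests$p_raw else tests$p_adj
  offending <- unique(tests$snp[!is.na(pcol) & pcol < alpha])
  removed <- intersect(instruments$ids, offending)
  kept <- setdiff(instruments$ids, removed)
  if (!length(kept))
    warning("confounder screen removed every instrument")
  assoc <- instruments$associations
  if (!is.null(assoc)) assoc <- assoc[assoc$snp %in% kept, , drop = FALSE]
  prov <- instruments$provenance
  prov$passed_confounder_screen <- !(prov$snp %in% offending)
  out <- instrument_set(kept, assoc, prov)
  out$removed <- removed
  out
}
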
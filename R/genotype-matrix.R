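#' Genotype matrix container
#'
#' Holds an individuals-by-SNPs matrix of additive allele counts (0/1/2, `NA`
#' for missing calls) together with per-SNP metadata and sample identifiers.
#' This is the `Z` (and `X`) data every stage of the pipeline consumes.
#'
#' @param values Integer or numeric matrix, individuals in rows, SNPs in
#'   columns. Non-missing entries must be 0, 1 or 2.
#' @param snp_meta Data frame with one row per SNP: columns `id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele`. Missing
#'   columns are filled with placeholders; `id` defaults to column names of
#'   `values`.
#' @param sample_ids Character vector of individual identifiers (defaults to
#'   row names or `ind1..indN`).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `values`, `snp_meta`, `sample_ids`.
#' @export
#' @examples
#' gm <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2,
#'                              dimnames = list(NULL, c("rs1", "rs2"))))
#' n_snps(gm)
genotype_matrix <- function(values, snp_meta = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  bad <- !is.na(values) & !(values %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("genotype value not in {0,1,2,NA} at row ", idx[1], ", column ",
         idx[2], call. = FALSE)
  }
  ids <- colnames(values) %||% paste0("snp", seq_len(ncol(values)))
  if (is.null(snp_meta)) snp_meta <- data.frame(id = ids)
  snp_meta <- as.data.frame(snp_meta)
  if (is.null(snp_meta$id)) snp_meta$id <- ids
  snp_meta$id <- as.character(snp_meta$id)
  if (anyDuplicated(snp_meta$id)) stop("SNP ids must be unique", call. = FALSE)
  if (nrow(snp_meta) != ncol(values))
    stop("snp_meta rows must match genotype columns", call. = FALSE)
  defaults <- list(chromosome = 1L, position = seq_len(nrow(snp_meta)),
                   effect_allele = "A", other_allele = "G")
  for (nm in names(defaults))
    if (is.null(snp_meta[[nm]])) snp_meta[[nm]] <- defaults[[nm]]
  colnames(values) <- snp_meta$id
  if (is.null(sample_ids))
    sample_ids <- rownames(values) %||% paste0("ind", seq_len(nrow(values)))
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length must match genotype rows", call. = FALSE)
  rownames(values) <- NULL
  structure(list(values = values, snp_meta = snp_meta,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param x A `genotype_matrix`.
#' @export
n_snps <- function(x) ncol(x$values)

#' @rdname genotype_matrix
#' @export
n_individuals <- function(x) nrow(x$values)

#' Subset a genotype matrix by SNP id
#'
#' @param x A [genotype_matrix()].
#' @param ids Character vector of SNP ids to keep, in the requested order.
#' @return A `genotype_matrix` restricted to `ids`.
#' @export
subset_snps <- function(x, ids) {
  stopifnot(inherits(x, "genotype_matrix"))
  missing_ids <- setdiff(ids, x$snp_meta$id)
  if (length(missing_ids))
    stop("unknown SNP id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  keep <- match(ids, x$snp_meta$id)
  genotype_matrix(x$values[, keep, drop = FALSE],
                  x$snp_meta[keep, , drop = FALSE], x$sample_ids)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", n_individuals(x), " individuals x ", n_snps(x),
      " SNPs\n", sep = "")
  miss <- mean(is.na(x$values))
  cat("  missing call rate: ", format(round(miss, 4)), "\n", sep = "")
  invisible(x)
}

#' Per-SNP summary statistics
#'
#' Call rate, effect-allele frequency and minor allele frequency per SNP,
#' computed over non-missing calls.
#'
#' @param x A [genotype_matrix()].
#' @return Data frame with columns `id`, `call_rate`, `eaf`, `maf`.
#' @export
snp_stats <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  vals <- x$values
  n_called <- colSums(!is.na(vals))
  eaf <- colMeans(vals, na.rm = TRUE) / 2
  eaf[n_called == 0] <- NA_real_
  data.frame(id = x$snp_meta$id,
             call_rate = n_called / nrow(vals),
             eaf = eaf,
             maf = pmin(eaf, 1 - eaf),
             row.names = NULL)
}
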
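# File interfaces: PLINK .raw-style genotype text, phenotype CSV, and the
# TSV/JSON result artifacts. Everything is plain whitespace/comma text so
# cohorts round-trip exactly and diffs stay readable.

RAW_FIXED_COLS <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")

#' Write genotypes as PLINK .raw-style text
#'
#' Writes a whitespace-delimited table with the standard fixed columns
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one `SNPID_EFFECTALLELE`
#' dosage column per SNP; missing calls are written as `NA`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output file path.
#' @param sex Optional integer vector (1 = male, 2 = female, 0 = unknown)
#'   for the `SEX` column; defaults to 0.
#' @param phenotype Optional vector for the `PHENOTYPE` column (PLINK codes
#'   missing as -9, the default here).
#' @return `path`, invisibly.
#' @seealso [read_raw_genotypes()]
#' @export
write_raw_genotypes <- function(genotypes, path, sex = NULL, phenotype = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- n_individuals(genotypes)
  df <- data.frame(FID = genotypes$sample_ids, IID = genotypes$sample_ids,
                   PAT = 0L, MAT = 0L,
                   SEX = if (is.null(sex)) 0L else as.integer(sex),
                   PHENOTYPE = if (is.null(phenotype)) -9L else phenotype)
  geno <- as.data.frame(genotypes$values)
  names(geno) <- paste0(genotypes$snp_meta$id, "_",
                        genotypes$snp_meta$effect_allele)
  utils::write.table(cbind(df, geno), path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read PLINK .raw-style genotype text
#'
#' Parses the whitespace-delimited `.raw` dosage format (header
#' `FID IID PAT MAT SEX PHENOTYPE` then `SNPID_ALLELE` columns). Dosages
#' must be 0, 1, 2 or `NA`; anything else is a parse error naming the
#' offending row and column.
#'
#' @param path File path.
#' @return A [genotype_matrix()] with the effect allele recovered from each
#'   column-name suffix.
#' @export
read_raw_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  if (length(header) < 6 || !identical(header[1:6], RAW_FIXED_COLS))
    stop("malformed .raw header at line 1 of ", path,
         ": expected columns FID IID PAT MAT SEX PHENOTYPE", call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  snp_cols <- setdiff(names(tab), RAW_FIXED_COLS)
  if (!length(snp_cols)) stop("no SNP columns in ", path, call. = FALSE)
  vals <- matrix(NA_real_, nrow(tab), length(snp_cols))
  for (j in seq_along(snp_cols)) {
    raw <- tab[[snp_cols[j]]]
    ok <- is.na(raw) | raw %in% c("0", "1", "2", "NA", "")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("invalid genotype token '", raw[i], "' at data row ", i,
           ", column '", snp_cols[j], "' of ", path, call. = FALSE)
    }
    vals[, j] <- suppressWarnings(as.numeric(raw))
  }
  # column names are SNPID_EFFECTALLELE; split on the final underscore
  ids <- sub("_[^_]*$", "", snp_cols)
  alleles <- sub("^.*_", "", snp_cols)
  colnames(vals) <- ids
  genotype_matrix(vals,
                  snp_meta = data.frame(id = ids, effect_allele = alleles),
                  sample_ids = tab$IID)
}

#' Write and read a phenotype/covariate table
#'
#' The phenotype table is a plain CSV with a `sample_id` column followed by
#' trait and covariate columns.
#'
#' @param phenotypes Data frame including a `sample_id` column.
#' @param path File path.
#' @return `write_phenotypes()` returns `path` invisibly;
#'   `read_phenotypes()` returns the data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot(is.data.frame(phenotypes), "sample_id" %in% names(phenotypes))
  utils::write.table(phenotypes, path, quote = FALSE, sep = ",",
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path,
                               call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("phenotype file ", path, " lacks a sample_id column", call. = FALSE)
  tab$sample_id <- as.character(tab$sample_id)
  tab
}

#' Write a synthetic cohort to disk
#'
#' Writes the genotype matrix as PLINK .raw-style text, the phenotype table
#' as CSV and the generating configuration (with realized threshold and
#' prevalences) as JSON.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"cohort"`.
#' @return Named character vector of the three paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, paste0(prefix, ".raw")),
             phenotypes = file.path(dir, paste0(prefix, "_phenotypes.csv")),
             config = file.path(dir, paste0(prefix, "_config.json")))
  write_raw_genotypes(cohort$genotypes, paths[["genotypes"]])
  write_phenotypes(cohort$phenotypes, paths[["phenotypes"]])
  tp <- cohort$true_parameters
  tp$confounders <- lapply(tp$confounders, unclass)
  jsonlite::write_json(tp, paths[["config"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Load a cohort from genotype and phenotype files
#'
#' Reads a PLINK .raw-style genotype file and a phenotype CSV and inner-joins
#' them on sample id, reporting how many individuals were dropped from each
#' side. More than 50% unmatched ids on either side is treated as a data
#' error.
#'
#' @param genotype_path Path to the `.raw`-style genotype text file.
#' @param phenotype_path Path to the phenotype CSV.
#' @param quiet Suppress the join-accounting message.
#' @return List with elements `genotypes` (a [genotype_matrix()] restricted
#'   to matched individuals, in phenotype-row order) and `phenotypes` (the
#'   matched data frame).
#' @export
load_cohort <- function(genotype_path, phenotype_path, quiet = FALSE) {
  geno <- read_raw_genotypes(genotype_path)
  pheno <- read_phenotypes(phenotype_path)
  common <- intersect(pheno$sample_id, geno$sample_ids)
  drop_g <- length(geno$sample_ids) - length(common)
  drop_p <- nrow(pheno) - length(common)
  if (!length(common) ||
      drop_g > 0.5 * length(geno$sample_ids) ||
      drop_p > 0.5 * nrow(pheno))
    stop("sample id mismatch: only ", length(common),
         " ids shared between genotype and phenotype files", call. = FALSE)
  if (!quiet && (drop_g || drop_p))
    message("load_cohort: dropped ", drop_g, " genotype-only and ", drop_p,
            " phenotype-only individuals")
  pheno <- pheno[match(common, pheno$sample_id), , drop = FALSE]
  rownames(pheno) <- NULL
  keep <- match(common, geno$sample_ids)
  geno <- genotype_matrix(geno$values[keep, , drop = FALSE], geno$snp_meta,
                          common)
  list(genotypes = geno, phenotypes = pheno)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     na = "NA")
  invisible(path)
}
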
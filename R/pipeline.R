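# Bidirectional pipeline: QC -> multi-scenario GWAS -> intersection + LD
# pruning -> confounder screen -> coarsened-exposure MR in the four
# analysis cells (SNP removal yes/no x measured confounders yes/no) ->
# theta2 sensitivity sweep, for both trait directions.

#' Build and validate an analysis configuration
#'
#' @param exposure,outcome Phenotype column names of the two binary traits
#'   (direction 1 runs exposure -> outcome; direction 2 the reverse).
#' @param confounder_types Named character vector mapping confounder
#'   columns to `"categorical"` or `"continuous"`; may be empty.
#' @param genotype_path,phenotype_path Input files for [load_cohort()]
#'   (may be `NULL` when a cohort object is passed to
#'   [run_bidirectional()] directly).
#' @param qc A [qc_thresholds()].
#' @param gwas_p_threshold Genome-wide significance threshold (default
#'   5e-8).
#' @param r2_threshold LD pruning threshold (default 0.001).
#' @param gwas_scenarios List of covariate-name vectors, one per
#'   adjustment scenario. Default: unadjusted; age + sex; age, sex + BMI
#'   (restricted to confounders actually present).
#' @param theta2_grid_forward,theta2_grid_reverse Sensitivity grids for
#'   the two directions (defaults 0.04/0.07/0.14 and
#'   0.01/0.07/0.14/0.21).
#' @param screen_alpha Confounder-screen removal threshold on the
#'   FDR-adjusted p-values (default 0.05).
#' @param seed Seed for all randomness (PRS folds).
#' @param output_dir Directory for TSV/JSON artifacts, or `NULL` to skip
#'   writing.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(exposure, outcome, confounder_types = c(),
                            genotype_path = NULL, phenotype_path = NULL,
                            qc = qc_thresholds(),
                            gwas_p_threshold = 5e-8, r2_threshold = 0.001,
                            gwas_scenarios = NULL,
                            theta2_grid_forward = c(0.04, 0.07, 0.14),
                            theta2_grid_reverse = c(0.01, 0.07, 0.14, 0.21),
                            screen_alpha = 0.05, seed = 1L,
                            output_dir = NULL) {
  if (identical(exposure, outcome))
    stop("exposure and outcome must name different traits")
  if (!(gwas_p_threshold > 0 && gwas_p_threshold <= 1) ||
      !(r2_threshold > 0 && r2_threshold <= 1) ||
      !(screen_alpha >= 0 && screen_alpha <= 1))
    stop("thresholds out of range")
  stopifnot(inherits(qc, "qc_thresholds"),
            all(theta2_grid_forward >= 0 & theta2_grid_forward < 1),
            all(theta2_grid_reverse >= 0 & theta2_grid_reverse < 1))
  if (is.null(gwas_scenarios)) {
    covs <- names(confounder_types)
    gwas_scenarios <- list(character(0),
                           intersect(c("age", "sex"), covs),
                           intersect(c("age", "sex", "bmi"), covs))
    gwas_scenarios <- unique(gwas_scenarios)
  }
  structure(list(exposure = exposure, outcome = outcome,
                 confounder_types = confounder_types,
                 genotype_path = genotype_path,
                 phenotype_path = phenotype_path, qc = qc,
                 gwas_p_threshold = gwas_p_threshold,
                 r2_threshold = r2_threshold,
                 gwas_scenarios = gwas_scenarios,
                 theta2_grid_forward = theta2_grid_forward,
                 theta2_grid_reverse = theta2_grid_reverse,
                 screen_alpha = screen_alpha, seed = as.integer(seed),
                 output_dir = output_dir), class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path Config file (`.yml`/`.yaml` parsed with yaml, anything else
#'   with jsonlite). Fields mirror the [analysis_config()] arguments; `qc`
#'   may be a mapping with `max_missing_rate`, `hwe_p_min`, `maf_min`.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(lst$qc)) lst$qc <- do.call(qc_thresholds, lst$qc)
  if (!is.null(lst$confounder_types))
    lst$confounder_types <- unlist(lst$confounder_types)
  if (!is.null(lst$gwas_scenarios))
    lst$gwas_scenarios <- lapply(lst$gwas_scenarios, as.character)
  do.call(analysis_config, lst)
}

# Polynomial rolling hash of the serialized config: a provenance stamp
# carried by every output artifact of a run.
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 4294967291
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

run_direction <- function(exposure, outcome, geno, pheno, config, label) {
  D_all <- pheno[[exposure]]
  Y_all <- pheno[[outcome]]
  conf_names <- names(config$confounder_types)
  M_all <- if (length(conf_names)) pheno[, conf_names, drop = FALSE] else NULL

  message("[", label, "] QC on ", n_snps(geno), " SNPs (controls: ",
          sum(D_all == 0, na.rm = TRUE), ")")
  qc <- apply_qc(geno, config$qc, control_mask = D_all == 0)
  message("[", label, "] QC kept ", n_snps(qc$genotypes), "/", n_snps(geno),
          " SNPs")

  tabs <- logistic_scan(qc$genotypes, D_all, covariates = M_all,
                        covariate_scenarios = config$gwas_scenarios)
  inst <- withCallingHandlers(
    select_instruments(tabs, config$gwas_p_threshold, qc$genotypes,
                       config$r2_threshold),
    warning = function(w) {
      message("[", label, "] ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  message("[", label, "] instruments after GWAS + pruning: ",
          length(inst$ids))
  if (!length(inst$ids)) {
    return(list(label = label, estimable = FALSE, exposure = exposure,
                outcome = outcome, qc_report = qc$report,
                associations = tabs, instruments = inst))
  }

  screen <- if (length(conf_names))
    confounder_independence(qc$genotypes, inst, M_all,
                            config$confounder_types)
  else NULL
  inst_removed <- if (!is.null(screen))
    filter_instruments(inst, screen, alpha = config$screen_alpha)
  else {
    x <- inst
    x$removed <- character(0)
    x
  }
  message("[", label, "] confounder screen removed ",
          length(inst_removed$removed), " instrument(s)",
          if (length(inst_removed$removed))
            paste0(" (", paste(inst_removed$removed, collapse = ", "), ")"))

  grid <- if (label == "forward") config$theta2_grid_forward
          else config$theta2_grid_reverse
  Zfull <- subset_snps(qc$genotypes, inst$ids)$values
  cells <- list()
  for (remove in c(FALSE, TRUE)) {
    ids <- if (remove) inst_removed$ids else inst$ids
    for (adjust in c(FALSE, TRUE)) {
      key <- paste0(if (remove) "removed" else "all_snps", ".",
                    if (adjust) "adjusted" else "unadjusted")
      if (!length(ids)) {
        cells[[key]] <- list(estimable = FALSE, instruments = ids)
        next
      }
      Z <- Zfull[, ids, drop = FALSE]
      M <- if (adjust) M_all else NULL
      sweep_tab <- sensitivity_sweep(D_all, Y_all, Z, M, theta2_grid = grid,
                                     prs_seed = config$seed)
      cells[[key]] <- list(
        estimable = TRUE, instruments = ids,
        lrt = attr(sweep_tab, "lrt"),
        theta2_hat = attr(sweep_tab, "theta2_hat"),
        exposure_fit = attr(sweep_tab, "exposure_fit"),
        outcome_betas = attr(sweep_tab, "outcome_betas"),
        sweep = sweep_tab,
        estimate = sweep_tab[sweep_tab$estimated &
                               grepl("^IVW", sweep_tab$method), ],
        prs_estimate = sweep_tab[sweep_tab$estimated &
                                   sweep_tab$method == "PRS", ])
    }
  }
  list(label = label, estimable = TRUE, exposure = exposure,
       outcome = outcome, qc_report = qc$report, associations = tabs,
       instruments = inst, screen = screen,
       instruments_after_screen = inst_removed, cells = cells)
}

#' Run the full bidirectional MR analysis
#'
#' Executes, for each direction (exposure -> outcome and the reverse):
#' SNP QC, the multi-scenario GWAS, significance intersection + LD
#' pruning, the instrument-confounder screen, and the coarsened-exposure
#' MR in all four analysis cells (SNP removal yes/no crossed with measured
#' confounders yes/no), each with its `theta2` sensitivity sweep. A
#' direction whose instrument set comes up empty is reported as not
#' estimable and the run continues. Identical config + seed (and cohort)
#' gives identical output.
#'
#' @param config An [analysis_config()].
#' @param cohort Optional list with `genotypes` and `phenotypes` (e.g. a
#'   [simulate_cohort()] result or [load_cohort()] output); when `NULL`
#'   the cohort is loaded from the config paths.
#' @return A `run_report`: per-direction results (QC report, association
#'   tables, instrument sets, screen table, the four cells), plus
#'   `config`, `config_hash` and `seed`. If `config$output_dir` is set,
#'   TSV tables and a JSON summary are written there.
#' @export
run_bidirectional <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(cohort)) {
    if (is.null(config$genotype_path) || is.null(config$phenotype_path))
      stop("config has no input paths and no cohort was supplied")
    cohort <- load_cohort(config$genotype_path, config$phenotype_path)
  }
  geno <- cohort$genotypes
  pheno <- cohort$phenotypes
  need <- c(config$exposure, config$outcome, names(config$confounder_types))
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))

  report <- list(
    forward = run_direction(config$exposure, config$outcome, geno, pheno,
                            config, "forward"),
    reverse = run_direction(config$outcome, config$exposure, geno, pheno,
                            config, "reverse"))
  out <- structure(list(directions = report, config = config,
                        config_hash = config_hash(config),
                        seed = config$seed,
                        package_version =
                          as.character(utils::packageVersion("coarseMR"))),
                   class = "run_report")
  if (!is.null(config$output_dir)) write_run_report(out, config$output_dir)
  out
}

#' Write the TSV/JSON artifacts of a run
#'
#' @param report A `run_report` from [run_bidirectional()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(config_hash = report$config_hash, seed = report$seed,
                  package_version = report$package_version)
  for (dlab in names(report$directions)) {
    d <- report$directions[[dlab]]
    pre <- file.path(dir, dlab)
    write_tsv(cbind(d$qc_report, config_hash = report$config_hash),
              paste0(pre, "_qc_report.tsv"))
    write_tsv(cbind(as.data.frame(d$associations),
                    config_hash = report$config_hash),
              paste0(pre, "_associations.tsv"))
    if (!is.null(d$screen))
      write_tsv(cbind(as.data.frame(d$screen),
                      config_hash = report$config_hash),
                paste0(pre, "_confounder_tests.tsv"))
    dsum <- list(estimable = d$estimable,
                 instruments = d$instruments$ids %||% character(0))
    if (isTRUE(d$estimable)) {
      sweeps <- lapply(names(d$cells), function(key) {
        cell <- d$cells[[key]]
        if (!isTRUE(cell$estimable)) return(NULL)
        cbind(cell = key, as.data.frame(cell$sweep))
      })
      sw <- do.call(rbind, sweeps)
      write_tsv(cbind(sw, config_hash = report$config_hash),
                paste0(pre, "_sensitivity.tsv"))
      dsum$removed <- d$instruments_after_screen$removed
      dsum$cells <- lapply(d$cells, function(cell) {
        if (!isTRUE(cell$estimable)) return(list(estimable = FALSE))
        list(estimable = TRUE, instruments = cell$instruments,
             lrt = cell$lrt, theta2_hat = cell$theta2_hat,
             ivw = as.list(cell$estimate[1, c("method", "rr", "ci_low",
                                              "ci_high", "p", "Q", "Q_p",
                                              "model")]),
             prs = as.list(cell$prs_estimate[1, c("rr", "ci_low", "ci_high",
                                                  "p")]))
      })
    }
    summary[[dlab]] <- dsum
  }
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> config ", x$config_hash, ", seed ", x$seed, "\n",
      sep = "")
  for (dlab in names(x$directions)) {
    d <- x$directions[[dlab]]
    cat("  ", dlab, " (", d$exposure %||% "?", " -> ", d$outcome %||% "?",
        "): ", sep = "")
    if (!isTRUE(d$estimable)) {
      cat("not estimable (no instruments)\n")
      next
    }
    cell <- d$cells[["all_snps.adjusted"]]
    est <- cell$estimate[1, ]
    cat(sprintf("%d instruments; %s RR %.3f [%.3f, %.3f], p = %.3g\n",
                length(d$instruments$ids), est$method, est$rr, est$ci_low,
                est$ci_high, est$p))
  }
  invisible(x)
}
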
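Package: coarseMR
Title: Bidirectional Mendelian Randomisation with Coarsened Binary Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates liability-scale causal relative risks between pairs of
    binary traits by Mendelian randomisation with coarsened exposures. A binary
    disease state is treated as a thresholded observation of a latent liability
    (the Falconer model); a maximum-likelihood probit regression of disease on
    genetic instruments recovers liability-scale instrument effects, which are
    combined with per-instrument log-linear outcome associations into Wald
    ratios, pooled by fixed- or random-effects inverse-variance weighting
    (chosen by Cochran's Q) or by a cross-validated polygenic-risk-score
    instrument. Includes SNP quality control (call rate, exact Hardy-Weinberg
    test in controls, minor allele frequency), multi-scenario logistic GWAS
    scans with LD pruning, an FDR-controlled instrument-confounder independence
    screen, sensitivity sweeps over the liability heritability parameter, and a
    seeded synthetic-cohort generator emulating a large biobank so the whole
    pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse,
    withr
Config/testthat/edition: 3
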
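---
title: "Liability-scale Mendelian randomisation with coarsened binary exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-scale Mendelian randomisation with coarsened binary exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coarseMR)
```

## The problem

Mendelian randomisation (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure on an outcome.
The standard machinery assumes a continuous exposure measured on a linear
scale. Many clinically central exposures — a gout diagnosis, a
hypertension diagnosis — are binary, and applying continuous-exposure MR
to them yields relative risks that are at best partially identified.

`coarseMR` treats the binary exposure $D$ as a *coarsened* observation of
a latent continuous liability $L$ under the Falconer threshold model:

$$L = G + V, \qquad D = \mathbf{1}\{L > \tau\},$$

where $G = \sum_j \gamma_j Z_j$ is the genetic share carried by the
instrument genotypes $Z_j$ (additive allele counts), $V$ is the
environmental share, and $\tau$ is the threshold that fixes the disease
prevalence. Liability is standardised so $\mathrm{Var}(L) = 1$, and

$$\theta^2 = \mathrm{Var}(G) / \mathrm{Var}(L)$$

is the liability heritability attributable to the modelled variants. The
estimand is the causal log relative risk of the binary outcome $Y$ per
**1 SD of exposure liability**.

## The estimator

1. **Exposure side.** A maximum-likelihood probit regression of $D$ on
   the instruments (plus measured confounders $M$, when requested)
   identifies $c_j = \gamma_j / \sigma_V$, the per-allele liability
   effect on the residual scale with $V$ normalised to unit variance.
   Multiplying by $\sqrt{1 - \theta^2}$ maps back to the total-liability
   SD scale: $\gamma^*_j = c_j \sqrt{1 - \theta^2}$. This scale factor is
   deliberately isolated in `liability_wald_ratios()` so an alternative
   normalisation of $L$ requires a change in exactly one place.
2. **Outcome side.** For each instrument separately, a log-linear model
   $\log P(Y = 1) = a + \beta_{Yj} Z_j + \delta^\top M$ gives the
   per-allele log relative risk. We fit a Poisson working likelihood with
   HC0 robust (sandwich) standard errors rather than log-binomial ML:
   the working-model coefficient is consistent for the same log-RR, and
   log-binomial Newton steps frequently leave the parameter space at
   realistic prevalences. Log-binomial ML remains available behind
   `outcome_scan(method = "log-binomial")`, falling back (flagged) per
   SNP when it fails.
3. **Pooling.** Per-instrument Wald ratios
   $b_j = \beta_{Yj} / \gamma^*_j$, with first-order delta-method
   standard errors $se_j = se(\beta_{Yj}) / |\gamma^*_j|$, are combined
   by inverse-variance weighting. Cochran's $Q$ (chi-square, $k-1$ df)
   selects fixed effects when $p \ge 0.05$ and otherwise the
   multiplicative random-effects form, which inflates the fixed-effect
   standard error by $\sqrt{\max(1, Q/(k-1))}$.
4. **PRS route.** As a second estimator, all instruments are collapsed
   into a polygenic risk score used as a single instrument. Weights are
   logistic-regression coefficients of $D$ on all instruments (plus
   $M$), estimated by 10-fold cross-validation: each individual is
   scored with weights fitted on the other nine folds, which avoids the
   overfitting bias of in-sample weights when no independent dataset is
   available. Fold-averaged weights are available via
   `average_weights = TRUE`; fold-wise out-of-fold scoring is the
   default.
5. **Instrument strength.** Because the Cragg–Donald F statistic is not
   defined for a binary exposure standing in for a latent variable, a
   likelihood-ratio test compares the probit fit with instruments against
   the confounders-only null: $2(\ell_1 - \ell_0) \sim \chi^2_k$ under
   the null that all instrument coefficients vanish.

### Estimating and sweeping $\theta^2$

$\theta^2$ enters only through the deterministic factor
$\sqrt{1-\theta^2}$. The package estimates a **lower bound** from the
probit fit itself: with $s^2$ the sample variance of the fitted genetic
share $\sum_j \hat c_j Z_j$ (residual scale), $\hat\theta^2 = s^2 / (s^2
+ 1)$. When the modelled instruments carry only part of the true genetic
share this under-states $\theta^2$, which is why the analysis reports a
sensitivity sweep rather than a single value: `sensitivity_sweep()`
recomputes both estimators over a user grid (defaults
$\{0.04, 0.07, 0.14\}$ for the forward direction and
$\{0.01, 0.07, 0.14, 0.21\}$ for the reverse, bracketing published
SNP-based heritabilities of urate and blood pressure) plus the
data-estimated value. Since $b_j$ and $se_j$ scale identically in
$\theta^2$, $Q$ and the fixed/random choice are invariant across the
grid, and $|\log \mathrm{RR}|$ is strictly increasing in $\theta^2$ —
the sweep shows how far conclusions are from flipping, not a new fit per
point. Estimation uncertainty in $\hat\theta^2$ is expressed through the
sweep, not propagated into standard errors.

### Ratio standard errors

The delta-method $se_j$ ignores sampling error in $\hat c_j$. In the
regimes this package targets (tens of thousands of individuals,
genome-wide-significant instruments) the outcome association dominates
the ratio variance by an order of magnitude; the LRT guards against the
weak-instrument regime where the omission would bite. Instruments with
$|\hat c_j| < 10^{-8}$ are excluded from the ratio table with a warning
(the ratio is numerically unstable and carries no information).

## Instrument selection and screening

- **QC** (`apply_qc()`): call rate $\le$ 0.1 missing, minor allele
  frequency $\ge$ 0.01, and an exact Hardy–Weinberg test in controls at
  $p \ge 10^{-6}$. The exact test sums the conditional probabilities of
  all heterozygote configurations no more probable than the observed one
  (the field default at stringent thresholds; a chi-square variant sits
  behind `hwe_method = "chisq"` since either reading is defensible).
  Filters are evaluated call-rate → MAF → HWE; the order affects only
  which reason is recorded, never the kept set.
- **GWAS** (`logistic_scan()`, `select_instruments()`): per-SNP logistic
  scans under three covariate scenarios (unadjusted; age + sex; age,
  sex + BMI), intersected at $p < 5\times10^{-8}$ — intersection first,
  then LD pruning, with a warning whenever the scenario-specific
  significant sets disagree. Pruning is greedy keep-best-$p$ on dosage
  $r^2$ (pairwise-complete composite LD; phase is not needed), ranked by
  the unadjusted scan with ties broken by position then id. Fits that
  fail to converge (quasi-separation at low minor-allele counts) are
  retried with a small ridge penalty and flagged, never dropped
  silently.
- **Confounder screen** (`confounder_independence()`,
  `filter_instruments()`): every instrument is tested against every
  measured confounder — chi-square for categorical (sex), Spearman for
  continuous (age, BMI, creatinine) — with Benjamini–Hochberg FDR across
  all pairs jointly. Removal applies the $p < 0.05$ rule to the
  **adjusted** p-values; `use_raw_p = TRUE` switches to raw p-values for
  users who read the removal rule the other way. The screened and
  unscreened instrument sets are both carried forward, giving the four
  analysis cells (removal yes/no × measured confounders yes/no) that
  `run_bidirectional()` reports per direction.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with exactly the structure the
estimators assume, so every pipeline stage is testable without access to
restricted biobank data:

- genotypes $Z_j \sim \mathrm{Binomial}(2, \mathrm{maf}_j)$,
  independent, in Hardy–Weinberg proportions;
- confounders with configurable distributions, standardised internally
  by their theoretical moments so liability and outcome effects are
  per-SD;
- liability $L = \sum_j \gamma_j (Z_j - 2\,\mathrm{maf}_j) +
  \alpha^\top \tilde M + V$ with $\gamma$ rescaled so the genetic share
  is exactly $\theta^2$, $V$ normal (the law the probit stage assumes;
  nothing in the threshold model itself forces it) and
  $\mathrm{Var}(L) = 1$;
- $D = \mathbf 1\{L > \tau\}$ with $\tau$ the empirical quantile hitting
  the target prevalence (`calibrate_threshold()`);
- $P(Y = 1 \mid \cdot) = r_0 \exp(\beta_L L + \delta^\top \tilde M +
  \sum_j \pi_j Z_j)$, with $\pi_j$ direct pleiotropic effects. Risks are
  validated $< 1$ at simulation time and the run aborts naming the
  offending parameters — truncating would silently change the estimand.
  Because a baseline risk is rarely the known quantity, the config may
  instead fix the marginal outcome prevalence
  (`outcome_target_prevalence`), and $r_0$ is solved from the realised
  linear predictors; the realised value is recorded.
- missing genotype calls are injected completely at random
  (`missing_genotype_rate`); downstream, per-SNP fits use complete cases
  and multi-SNP fits mean-impute dosages (the usual PRS convention).

Pleiotropy has two knobs because the mechanism of a real pleiotropic
variant is rarely known: a direct per-allele log-RR on the outcome
(`pleiotropy_outcome`), and a shift of a named confounder in SD units
per allele (`pleiotropy_confounder`/`_effect`), which perturbs both
traits through the confounder's own effects. The bundled
`default_biobank_config()` uses the second for its `rs671_like` variant,
which is what makes the confounder screen detect and remove it.

### What the defaults emulate — and what they do not

`default_biobank_config()` mirrors a large East-Asian biobank design:
88,347 individuals; exposure (gout) prevalence 3.68% with five variants
carrying $\theta^2 = 0.047$; outcome (hypertension) marginal prevalence
13.52% with ten direct-effect variants (per-allele log-RR 0.09, sized so
the reverse-direction probit fit sees a genetic share near
$\theta^2 \approx 0.013$); confounder margins matching the published
cohort description (age 51.1 (SD 11.12) years, 31.9% male, BMI 24.25
(3.83), creatinine mean 0.71 with a lognormal law matched to its
mean/SD); a causal RR of 1.10 per liability SD from gout to
hypertension and no reverse effect; 2% missing calls; and 25 null
variants so instrument selection is non-trivial. Outcome effects of the
confounders (log-RR per SD: age 0.20, sex 0.12, BMI 0.15, creatinine
0.05) are package choices sized to keep every individual log-linear
risk below 1 at biobank scale while preserving strong confounding.

The generator deliberately omits: linkage disequilibrium beyond
explicitly duplicated/correlated columns (pruning is tested with
constructed pairs), population structure and relatedness, genotyping
batch effects, and phenotype misclassification. Passing tests therefore
demonstrate correctness of the estimators *under the stated model*, not
robustness to those real-data complications.

## Numerical choices

- All fits are maximum likelihood through base R's `glm.fit` IRLS
  (convergence tightened to `epsilon = 1e-12`); hot loops pass prebuilt
  model matrices. Small-sample equivalence with direct numerical
  likelihood maximisation is asserted to $10^{-6}$ in the test suite.
- Robust (HC0) variances for the Poisson working model are assembled
  from the score and Fisher pieces of the fit and cross-checked against
  `sandwich::vcovHC` in a unit test.
- The HWE exact test works in log space via `lgamma`, so control sets in
  the tens of thousands are exact, not approximated.
- Ties in threshold calibration: $\tau$ is the order statistic making
  the fraction strictly above it closest to the target prevalence; for a
  symmetric sample and target 0.5 this is the sample median.
- Degenerate inputs fail loudly: constant liabilities (no identifiable
  threshold), constant phenotypes, empty control sets, all-zero genotype
  counts. Zero-variance instrument columns get coefficient 0 (they carry
  no information) rather than poisoning the probit design matrix.
- Every source of randomness — simulation, PRS folds — is governed by an
  explicit seed; identical configuration and seed reproduce results
  byte-for-byte, and every written artifact carries a hash of its
  configuration.

## Problem sizes used in the checks

The bundled statistical checks run at the sizes a single desk CPU
handles comfortably while keeping Monte-Carlo error far below the
tolerances they assert: margins at the full cohort size (88,347);
parameter recovery over 200 replicates of $n = 50{,}000$ with four valid
instruments; IVW level over 500 replicates of $n = 10{,}000$;
LRT null calibration over 500 replicates of $n = 5{,}000$; and the
structural bidirectional run at $n = 40{,}000$ with a decisive causal
effect (RR 1.3 per liability SD), since at the study's own effect size
(RR 1.10) a single realisation has only ~60% power at $\alpha = 0.05$ —
the expected behaviour of the design, worth knowing before reading any
single-seed run.

## Worked example

```{r example, eval = FALSE}
cfg <- default_biobank_config(n_individuals = 30000, seed = 7)
cohort <- simulate_cohort(cfg)

analysis <- analysis_config(
  exposure = "gout", outcome = "hypertension",
  confounder_types = c(age = "continuous", sex = "categorical",
                       bmi = "continuous", creatinine = "continuous"),
  seed = 7)
report <- run_bidirectional(analysis, cohort)
report
```

## Known limitations

- The $\sqrt{1-\theta^2}$ rescaling assumes the probit residual is the
  environmental share of a unit-variance liability; when measured
  confounders explain part of the liability, the adjusted analysis is
  calibrated to the *conditional* liability SD, so adjusted and
  unadjusted estimates differ by a factor bounded by the confounders'
  liability share (small in the bundled designs, and the two analyses
  are reported side by side).
- Wald-ratio standard errors omit first-stage uncertainty (above).
- $\hat\theta^2$ is a lower bound tied to the modelled instruments, not
  a full SNP heritability estimate; the sweep is the primary sensitivity
  statement.
- No MR-Egger, weighted-median or outlier-robust estimators: pleiotropy
  handling is limited to the confounder screen and the explicit
  pleiotropy flags.
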
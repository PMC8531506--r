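---
title: "Single-step nonlinear mixed model GWAS for growth trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step nonlinear mixed model GWAS for growth trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthgwas)
library(dplyr)
```

## The problem

Growth is a longitudinal trait: an animal's body weight is measured
repeatedly between weaning and finishing, and the biology of interest lives
in the whole trajectory, not in any single weighing. Two quantities
summarize a growth curve in livestock genetics: the **mature weight** `A`
(the asymptote, in grams) and the **maturity rate** `K` (per day, governing
how fast the asymptote is approached). The classical *two-step* GWAS first
fits a curve per animal and then treats the fitted `A` and `K` as
pseudo-phenotypes. The *single-step* approach implemented here instead
embeds the SNP effect directly in the fixed effects of a nonlinear mixed
model (NMM), so curve fitting and association testing share one likelihood
— which propagates the measurement error in the curve parameters into the
test instead of discarding it.

## The model

For individual $i$ at day-of-age $t$, with logistic mean curve,

$$
w_{it} \;=\;
\frac{\mu_A + \mathrm{Sex}_i + \mathrm{PC}_i (+\,\mathrm{SNP}_i) + \varepsilon_{A,i}}
{1 + \mu_b \exp\!\big[-(\mu_K + \mathrm{Sex}_i + \mathrm{PC}_i (+\,\mathrm{SNP}_i) + \varepsilon_{K,i})\,t\big]}
+ e_{it},
$$

where $(\varepsilon_{A,i}, \varepsilon_{K,i}) \sim N(0, \Sigma)$ are
individual deviations of mature weight and maturity rate with
$\Sigma = \bigl(\begin{smallmatrix}\sigma^2_A & \sigma_{A,K}\\
\sigma_{A,K} & \sigma^2_K\end{smallmatrix}\bigr)$, and
$e_{it} \sim N(0, \sigma^2_e)$ i.i.d. The time-scale mean $\mu_b$ carries
no covariates and no random effect. Four nested models differ only in
where the SNP dosage enters:

* **M0** — no SNP term (the null);
* **M1** — SNP on both `A` and `K` (`snp_target = "both"`, 2 df);
* **M2** — SNP on `A` only (1 df);
* **M3** — SNP on `K` only (1 df).

Each SNP is tested by a likelihood-ratio test of M1/M2/M3 against a single
shared M0 fit, with the statistic referred to a $\chi^2$ whose degrees of
freedom equal the parameter-count difference. All fits use ML, not REML,
so LRTs between models differing in fixed effects are valid. SNP dosage is
coded additively (0/1/2 copies, centered), giving one coefficient per
targeted parameter; a 2-df genotype-class coding would be an alternative,
but the additive coding is the GWAS default and makes the LRT degrees of
freedom equal the number of SNP coefficients added.

## The likelihood approximation, and how it is checked

The marginal likelihood integrates $(\varepsilon_A, \varepsilon_K)$ out of
a nonlinear mean, which has no closed form. `marginal_loglik()` uses a
first-order conditional expansion: per individual, the conditional mode of
the deviations is found by a damped, fully vectorized Gauss–Newton search;
the mean is linearized at the mode; and the resulting Gaussian marginal is
evaluated in closed form via 2×2 Woodbury identities. Two independent
oracles guard this approximation in the test suite:

* `quadrature_loglik()` — adaptive tensor-product Gauss–Hermite quadrature
  (21 nodes per dimension, centered and scaled at the conditional mode),
  itself cross-checked against plain Monte-Carlo integration;
* the exact i.i.d. Gaussian likelihood, which both functions must match to
  `1e-8` when $\Sigma = 0$.

On the standard 5-individual fixture the linearized and quadrature
log-likelihoods agree to better than 0.1 (the suite enforces 0.5 in
total), and the approximation error is shared between nested models, so it
largely cancels in likelihood ratios — the calibration test below is the
operational check of that claim.

Maximization is BFGS on a scaled parameter vector with forward-difference
gradients. $\Sigma$ is optimized through an unconstrained transform (log
standard deviations and atanh correlation), $\mu_b$ and $\sigma_e$ through
logs. Convergence uses a relative log-likelihood tolerance of `1e-8` and a
200-iteration cap; the conditional-mode search is warm-started from the
previous outer evaluation, and per-SNP scan fits are warm-started at the M0
solution with a zero SNP coefficient. Fits that fail return
`converged = FALSE` rather than raising; the scan records such SNPs with
missing p-values, which propagate to missing q-values and are excluded
from the FDR input. Overflowing exponentials in the logistic mean are
clamped (exponent capped at 300) and yield a penalized likelihood rather
than `NaN`s.

## Growth-curve screening

Before any association work, five classical families compete on the pooled
records (`fit_growth_families()`): logistic, Gompertz, Brody,
Von Bertalanffy and Richards. Screening uses population-level nonlinear
least squares — fast, and sufficient to rank families — while the selected
family is refit as the full NMM for the scan. `select_model()` picks the
lowest AIC among converged fits (ties: lower BIC, then fewer parameters).
The four-parameter Richards family is notoriously ill-conditioned near
logistic-shaped data (its shape parameter is weakly identified there); it
is fitted on its logistic-compatible branch
$A[1 + b e^{-Kt}]^{m}$ and its frequent non-convergence is reported, not
raised — mirroring how such fits behave on real rabbit growth data. On
cohorts generated from the logistic model at the package's default
parameters, the suite requires the logistic family to win by AIC in at
least 90% of 50 replicates.

## Quality control

Phenotypes pass three screens in a fixed order (`qc_phenotypes()`):

1. **3-SD rule** — per time point, records more than three standard
   deviations from that time point's mean are masked. Moments are computed
   once, before any masking (a single screen, not an iterative one);
   iterating would make the rule's outcome depend on scan order.
2. **<5% decrease rule** — weight may drop by less than 5% between
   consecutive records; a larger drop masks the *later* record. Once a gap
   exists, the comparison uses the nearest earlier surviving record — the
   conservative reading of "consecutive" for gapped series.
3. **Missingness drop** — individuals with more than two missing values
   over the seven-point schedule are removed (boundary kept at exactly
   two).

Whether the 3-SD screen should run before or after the decrease rule is
genuinely open; this package fixes the order above, on the argument that a
gross outlier should not be allowed to trigger (or hide) a decrease
violation against its neighbours.

Genotypes pass call-rate, MAF, and Hardy–Weinberg filters with *strict*
inequalities (missingness < 0.1 per SNP and < 0.2 per individual,
MAF > 0.05, exact-test p > 1e-8 — a SNP at MAF exactly 0.05 is removed),
then frequency-based imputation, greedy LD pruning (r² > 0.9 against any
retained SNP among the 50 most recent, per chromosome), and PCA on the
column-standardized dosage matrix for structure covariates. The HWE test
is the conditional exact test, validated against full enumeration. The
imputer draws each missing call from the SNP's observed genotype
frequencies: the pipeline only needs complete dosages for LD pruning and
PCA, and scan SNPs are near-complete after the call-rate filter, so a
haplotype-model imputer would add an external dependency for no measurable
benefit here. The LD statistic and window are not uniquely determined by
common practice; r² with a 50-SNP window is the PLINK-like default.

## FDR control

`fdr_adjust()` defaults to Storey q-values: $\hat\pi_0$ estimated on the
λ-grid 0.05–0.90 (step 0.05) with a cubic-spline smoother evaluated at the
largest λ, and $q = \min(\hat\pi_0 \times \mathrm{BH}, 1)$. Forcing
$\hat\pi_0 = 1$ reproduces Benjamini–Hochberg exactly, and the function
falls back to BH (with a warning) when fewer than 100 p-values are
available or $\hat\pi_0$ is unstable (> 1 or < 0.1). FDR is applied
separately within each hypothesis family (M1, M2, M3): the three scans ask
different biological questions and are reported as separate Manhattan
panels, so mixing their p-value mixtures would distort each family's
$\hat\pi_0$.

## QTL definition

Significant SNPs are clustered per chromosome by single linkage on
inter-SNP gaps: consecutive sorted SNPs at most 100 kb apart join one
cluster, and each cluster's interval is `[min - 100kb, max + 100kb]`
(floored at 1). This is deliberately *not* interval merging: two clusters
separated by a gap just over 100 kb keep distinct — possibly overlapping —
intervals. The reference worked example in the test suite (45 significant
SNPs from a published meat-rabbit growth study, shipped as a plain-text
fixture) pins this behaviour: the gap rule reproduces all 24 printed QTL
intervals bit-exactly, including the overlapping pair around 13.4 Mb
created by a 101,332 bp gap, whereas interval merging would not. Gene
overlap is 1-based inclusive at both ends and strand-agnostic; SNP
locations are called hierarchically (UTR over exon over intron over
intergenic) on any overlapping transcript.

## The synthetic cohort generator

`sim_config()` + `simulate_trajectories()` generate cohorts with exactly
the statistical structure the NMM assumes — bivariate-normal deviations on
`A` and `K`, logistic means, i.i.d. residuals — so parameter recovery,
type-I error and power are all testable without external data. Defaults
describe a meat-rabbit-like design:

| parameter | default | why |
|---|---|---|
| `n_individuals` | 400 | a commercial crossbred cohort after QC |
| `time_points` | 35, 42, 49, 56, 63, 70, 84 | weaning-to-finishing weighing schedule |
| `mu_A` | 2615.45 g | reference fitted mature weight |
| `mu_K` | 0.054 /day | reference fitted maturity rate |
| `mu_b` | 15.35 | solved so the mean curve passes through the 788.05 g day-35 mean (`solve_mu_b()`) |
| `sd_A` | 210 g | CV ≈ 8%, a plausible between-animal spread |
| `sd_K` | 0.0054 | CV ≈ 10% |
| `sigma_AK` | 0 | no reported estimate; independence is the neutral default |
| `sd_e` | 60 g | a few percent of body weight, typical scale error |
| MAF | U(0.05, 0.5) | post-QC panel |

The variance components and `mu_b` have no published reference values, so
the defaults above are the package's own calibration choices, fixed once:
they make the simulated day-35 cohort mean and spread resemble the
reference descriptive statistics. Genotypes are independent SNPs under
Hardy–Weinberg — LD is deliberately absent, matching the post-pruning
panel the scan actually sees (use `inject_duplicate_snps()` to exercise
the pruner). Optional island-model structure perturbs subpopulation allele
frequencies for PCA tests; it is off by default since the scan's reference
use case shows no stratification. `corrupt_cohort()` injects exactly the
three artefacts QC removes, with a manifest for sensitivity tests;
injected outliers sit 6–7 pre-corruption SDs out so they stay detectable
after they inflate the time-point SD themselves.

What passing tests on these cohorts does **not** show: robustness to
model misspecification (non-logistic truth, heteroscedastic or
autocorrelated residuals, non-normal deviations), to LD between scan SNPs,
or to polygenic background (the model carries no genomic relationship
matrix — there is no pedigree in the reference design). Results on real
data inherit those caveats.

## Problem sizes used in the checks

The suite's stochastic checks run at the documented study conditions:
parameter recovery at 400 individuals × 7 time points (population-average
`mu_A` within 2% and `mu_K` within 5%; sex enters centered so the
intercept is the population mean); LRT null calibration over 1000
simulated null SNPs at 200 individuals (empirical type-I error in
[0.03, 0.07] at α = 0.05, Kolmogorov–Smirnov uniformity at α = 0.01);
model selection over 50 replicates at 400 individuals. These sizes were
chosen so each check constrains what it claims — e.g. 1000 null SNPs give
a binomial SE of about 0.007 on the type-I error, tight enough for the
[0.03, 0.07] band to be meaningful.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(
  n_individuals = 200, n_snps = 50,
  causal_snps = tibble::tibble(snp = 7, beta_A = 150, beta_K = 0.004),
  seed = 42
)
bundle <- simulate_trajectories(cfg)

pheno <- qc_phenotypes(bundle$phenotypes)
geno <- filter_snps(bundle$genotypes) |> impute_genotypes(seed = 1) |> ld_prune()

fits <- fit_growth_families(pheno)
best <- select_model(fits)            # logistic, on these cohorts

cov <- dplyr::distinct(pheno, individual_id, sex)
scan <- run_scan(pheno, geno, covariates = cov, q_method = "BH")
hits <- call_significant(scan, hypothesis = "M1")
qtls <- cluster_snps_to_qtls(hits) # |> overlap_genes(read_gene_models(...))
autoplot(scan)
```

## Known limitations

* The linearized likelihood is an approximation; its error grows with
  $\sigma^2_K$ (curvature in `K` is the dominant nonlinearity). The
  quadrature oracle bounds it on small fixtures but is too slow for scans.
* M0 is fitted once and reused for every SNP. The null model contains no
  SNP term, so it is SNP-invariant — unless per-SNP missingness changes
  the phenotyped subset, in which case a per-SNP refit would be needed
  (dosages are mean-imputed per SNP instead).
* Standard errors come from the numerical Hessian of the approximate
  likelihood and are reported only on request (`se = TRUE`).
* No polygenic random effect, no REML, no Bayesian fitting; external-tool
  stages (sequencing-level variant filters, haplotype imputation,
  enrichment against live annotation databases) are out of scope.
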
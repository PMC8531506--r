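#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the simulated study design: cohort size, the
#' weighing schedule, the marker panel, the logistic growth-curve means
#' (mature weight `mu_A` in grams, maturity rate `mu_K` per day, time-scale
#' `mu_b`), the bivariate individual-deviation (co)variances on A and K, the
#' residual variance, fixed sex effects, causal SNP effects, optional island
#' population structure, and the corruption rates consumed by
#' [corrupt_cohort()].
#'
#' Defaults reproduce a meat-rabbit-like design: 400 individuals weighed at
#' 35, 42, 49, 56, 63, 70 and 84 days of age, mean curve
#' \eqn{w(t) = 2615.45 / (1 + 15.35 e^{-0.054 t})} (which passes through the
#' observed day-35 mean of 788 g), individual standard deviations of 210 g
#' on A (CV about 8%) and 0.0054 on K (CV about 10%), zero A-K covariance,
#' and a 60 g residual standard deviation.
#'
#' @param n_individuals Number of individuals.
#' @param time_points Strictly increasing days of age at which weights are
#'   recorded.
#' @param n_snps Number of biallelic SNPs to simulate.
#' @param maf_low,maf_high Bounds for the per-SNP minor allele frequency,
#'   drawn uniformly; both in (0, 0.5].
#' @param mu_A,mu_K,mu_b Population means of the logistic parameters.
#' @param sigma2_A,sigma2_K,sigma_AK Variances and covariance of the
#'   individual deviations (eps_A, eps_K); the implied 2x2 matrix must be
#'   positive semi-definite.
#' @param sigma2_e Residual variance of a single weighing (g^2).
#' @param sex_effect_A,sex_effect_K Additive fixed effect of sex (coded 0/1)
#'   on A and K.
#' @param causal_snps Optional tibble/data.frame with columns `snp`
#'   (column index into the genotype matrix), `beta_A` (grams per allele)
#'   and `beta_K` (per day per allele).
#' @param n_subpops,subpop_divergence Island-model structure: number of
#'   subpopulations and the standard deviation of the per-subpopulation
#'   allele-frequency perturbation. `n_subpops = 1` (default) disables
#'   structure.
#' @param n_chromosomes Number of synthetic autosomes the panel is spread
#'   over.
#' @param missing_rate,outlier_rate,decrease_rate Corruption rates in [0, 1]
#'   used by [corrupt_cohort()].
#' @param seed Integer seed; every downstream draw is a deterministic
#'   function of it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_genotypes()], [simulate_trajectories()],
#'   [corrupt_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 50, n_snps = 20, seed = 1)
#' cfg$mu_A
sim_config <- function(n_individuals = 400,
                       time_points = c(35, 42, 49, 56, 63, 70, 84),
                       n_snps = 1000,
                       maf_low = 0.05, maf_high = 0.5,
                       mu_A = 2615.45, mu_K = 0.054, mu_b = 15.35,
                       sigma2_A = 210^2, sigma2_K = 0.0054^2, sigma_AK = 0,
                       sigma2_e = 60^2,
                       sex_effect_A = 0, sex_effect_K = 0,
                       causal_snps = NULL,
                       n_subpops = 1, subpop_divergence = 0,
                       n_chromosomes = 2,
                       missing_rate = 0, outlier_rate = 0, decrease_rate = 0,
                       seed = 1L) {
  stop_cfg <- function(msg) abort(msg, class = "growthgwas_config_error")

  if (n_individuals < 1) stop_cfg("`n_individuals` must be >= 1.")
  if (n_snps < 1) stop_cfg("`n_snps` must be >= 1.")
  if (length(time_points) < 1 || any(diff(time_points) <= 0)) {
    stop_cfg("`time_points` must be strictly increasing.")
  }
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop_cfg("MAF bounds must satisfy 0 < maf_low <= maf_high <= 0.5.")
  }
  if (sigma2_A < 0 || sigma2_K < 0 || sigma2_e < 0) {
    stop_cfg("Variances must be non-negative.")
  }
  if (sigma_AK^2 > sigma2_A * sigma2_K + 1e-12) {
    stop_cfg("[[sigma2_A, sigma_AK], [sigma_AK, sigma2_K]] must be positive semi-definite.")
  }
  rates <- c(missing_rate, outlier_rate, decrease_rate)
  if (any(rates < 0 | rates > 1)) stop_cfg("Corruption rates must lie in [0, 1].")
  if (n_subpops < 1) stop_cfg("`n_subpops` must be >= 1.")
  if (!is.null(causal_snps)) {
    causal_snps <- as_tibble(causal_snps)
    need <- c("snp", "beta_A", "beta_K")
    if (!all(need %in% names(causal_snps))) {
      stop_cfg("`causal_snps` needs columns snp, beta_A, beta_K.")
    }
    if (any(causal_snps$snp < 1 | causal_snps$snp > n_snps)) {
      stop_cfg("`causal_snps$snp` indices out of range.")
    }
  }

  structure(list(
    n_individuals = as.integer(n_individuals),
    time_points = as.numeric(time_points),
    n_snps = as.integer(n_snps),
    maf_low = maf_low, maf_high = maf_high,
    mu_A = mu_A, mu_K = mu_K, mu_b = mu_b,
    sigma2_A = sigma2_A, sigma2_K = sigma2_K, sigma_AK = sigma_AK,
    sigma2_e = sigma2_e,
    sex_effect_A = sex_effect_A, sex_effect_K = sex_effect_K,
    causal_snps = causal_snps,
    n_subpops = as.integer(n_subpops), subpop_divergence = subpop_divergence,
    n_chromosomes = as.integer(n_chromosomes),
    missing_rate = missing_rate, outlier_rate = outlier_rate,
    decrease_rate = decrease_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  cohort:   ", x$n_individuals, "individuals x", length(x$time_points),
      "time points (days", paste(x$time_points, collapse = ", "), ")\n")
  cat("  panel:    ", x$n_snps, "SNPs, MAF U(", x$maf_low, ",", x$maf_high,
      ") on", x$n_chromosomes, "chromosomes\n")
  cat("  curve:    mu_A =", x$mu_A, " mu_K =", x$mu_K, " mu_b =", x$mu_b, "\n")
  cat("  variance: sd_A =", sqrt(x$sigma2_A), " sd_K =", sqrt(x$sigma2_K),
      " cov_AK =", x$sigma_AK, " sd_e =", sqrt(x$sigma2_e), "\n")
  ncausal <- if (is.null(x$causal_snps)) 0 else nrow(x$causal_snps)
  cat("  effects:  ", ncausal, "causal SNP(s); sex effects (A, K) = (",
      x$sex_effect_A, ",", x$sex_effect_K, ")\n")
  invisible(x)
}

#' Covariance matrix of the individual deviations implied by a config
#' @param config A [sim_config()] object.
#' @return The 2x2 matrix [[sigma2_A, sigma_AK], [sigma_AK, sigma2_K]].
#' @export
sim_sigma <- function(config) {
  matrix(c(config$sigma2_A, config$sigma_AK, config$sigma_AK, config$sigma2_K),
         2, 2)
}

#' Time-scale parameter that anchors the mean curve at an observed weight
#'
#' Solves \eqn{w = A / (1 + b e^{-K t})} for `b`, useful to calibrate
#' `mu_b` so the simulated mean trajectory passes through a known
#' time-point mean (e.g. the day-35 cohort mean).
#'
#' @param A,K Mature weight (g) and maturity rate (per day).
#' @param t Day of age.
#' @param w Target mean weight at `t` (g).
#' @return The time-scale parameter b.
#' @export
#' @examples
#' solve_mu_b(A = 2615.45, K = 0.054, t = 35, w = 788.05)
solve_mu_b <- function(A, K, t, w) {
  stopifnot(w > 0, A > w)
  (A / w - 1) / exp(-K * t)
}
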
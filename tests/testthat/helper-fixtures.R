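# Shared fixtures built in code.

# Small cohort with moderate noise: fast to simulate and fit.
small_bundle <- function(n = 40, seed = 11, ...) {
  args <- list(n_individuals = n, n_snps = 4, sigma2_A = 80^2,
               sigma2_K = 0.003^2, sigma2_e = 40^2, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_trajectories(do.call(sim_config, args))
}

sex_covariates <- function(bundle) {
  dplyr::distinct(bundle$phenotypes, individual_id, sex)
}

# 5-individual, 7-time-point instance used for likelihood-oracle checks.
oracle_fixture <- function() {
  b <- small_bundle(n = 5, seed = 11)
  list(
    phenotypes = b$phenotypes,
    params = list(beta_A = 2615.45, beta_K = 0.054, mu_b = 15.35,
                  Sigma = matrix(c(80^2, 0, 0, 0.003^2), 2, 2),
                  sigma2_e = 40^2)
  )
}

# Hand-written gene models on a toy chromosome: one gene with exon/UTR
# structure, one bare gene span.
toy_gene_models <- function() {
  tibble::tribble(
    ~type,             ~chrom,  ~start,   ~end,     ~strand, ~gene_id, ~gene_name,
    "gene",            "OCU2",  7300000,  7350000,  "+",     "g1",     "LDB2like",
    "mRNA",            "OCU2",  7300000,  7350000,  "+",     "g1",     "LDB2like",
    "five_prime_UTR",  "OCU2",  7300000,  7300100,  "+",     "g1",     "LDB2like",
    "exon",            "OCU2",  7300000,  7301000,  "+",     "g1",     "LDB2like",
    "exon",            "OCU2",  7340000,  7341000,  "+",     "g1",     "LDB2like",
    "three_prime_UTR", "OCU2",  7340900,  7341000,  "+",     "g1",     "LDB2like",
    "gene",            "OCU2",  9000000,  9050000,  "-",     "g2",     "GENE2"
  )
}

# Brute-force HWE exact test: enumerate every heterozygote count compatible
# with the allele counts via exact log-factorial probabilities.
hwe_enumerate <- function(n_homref, n_het, n_homalt) {
  n <- n_homref + n_het + n_homalt
  n_rare <- 2 * min(n_homref, n_homalt) + n_het
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- match(n_het, hets)
  sum(pr[pr <= pr[obs] * (1 + 1e-10)])
}
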
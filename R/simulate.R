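#' Simulate a genotype panel under Hardy-Weinberg equilibrium
#'
#' Draws independent biallelic SNPs: each SNP gets an allele frequency
#' uniform in `[maf_low, maf_high]` and genotypes are Binomial(2, p) per
#' individual. With `n_subpops > 1`, an island model perturbs each
#' subpopulation's allele frequency by a Normal(0, `subpop_divergence`)
#' deviate (clamped to [0.01, 0.99]), creating the allele-frequency
#' differentiation that genotype PCA should pick up. Positions are strictly
#' increasing within synthetic chromosomes, with inter-SNP gaps uniform
#' between 5 and 40 kb. Linkage disequilibrium is not simulated, matching a
#' post-LD-pruning panel; use [inject_duplicate_snps()] to create perfect-LD
#' pairs for pruning tests.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] with attributes `true_maf` (the drawn base
#'   allele frequencies) and `subpop` (per-individual subpopulation index).
#' @export
#' @examples
#' gm <- simulate_genotypes(sim_config(n_individuals = 20, n_snps = 5, seed = 1))
#' dim(gm)
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_snps
  with_seed(config$seed, {
    maf <- runif(m, config$maf_low, config$maf_high)
    subpop <- sample(rep_len(seq_len(config$n_subpops), n))
    if (config$n_subpops > 1 && config$subpop_divergence > 0) {
      pmat <- vapply(seq_len(config$n_subpops), function(k) {
        pmin(pmax(maf + rnorm(m, 0, config$subpop_divergence), 0.01), 0.99)
      }, numeric(m)) # m x n_subpops
      D <- matrix(rbinom(n * m, 2L, t(pmat[, subpop, drop = FALSE])),
                  nrow = n, ncol = m, byrow = FALSE)
    } else {
      D <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
    }
    rownames(D) <- sprintf("ind%04d", seq_len(n))
    chrom_idx <- sort(rep_len(seq_len(config$n_chromosomes), m))
    chrom <- sprintf("chr%d", chrom_idx)
    pos <- unlist(lapply(split(seq_len(m), chrom_idx), function(ix) {
      cumsum(sample(5000:40000, length(ix), replace = TRUE))
    }), use.names = FALSE)
    snps <- tibble(
      snp_id = sprintf("snp%05d", seq_len(m)),
      chrom = chrom, pos = as.integer(pos)
    )
    colnames(D) <- snps$snp_id
    out <- geno_matrix(D, snps)
    attr(out, "true_maf") <- maf
    attr(out, "subpop") <- subpop
    out
  })
}

#' Append exact duplicates of existing SNP columns
#'
#' Test helper for LD pruning: each duplicated SNP is reinserted right
#' after its template (position + 1), giving a pair in perfect LD (r^2 = 1).
#'
#' @param gm A [geno_matrix()].
#' @param snp_idx Column indices to duplicate.
#' @return A [geno_matrix()] with the duplicate columns inserted.
#' @export
inject_duplicate_snps <- function(gm, snp_idx) {
  D <- gm$dosages
  snps <- gm$snps
  for (j in sort(snp_idx, decreasing = TRUE)) {
    dup <- snps[j, ]
    dup$snp_id <- paste0(dup$snp_id, "_dup")
    dup$pos <- dup$pos + 1L
    snps <- bind_rows(snps[seq_len(j), ], dup,
                      if (j < nrow(snps)) snps[(j + 1):nrow(snps), ])
    D <- cbind(D[, seq_len(j), drop = FALSE],
               matrix(D[, j], ncol = 1, dimnames = list(NULL, dup$snp_id)),
               if (j < ncol(D)) D[, (j + 1):ncol(D), drop = FALSE])
  }
  geno_matrix(D, snps)
}

#' Simulate longitudinal growth trajectories from the logistic mixed model
#'
#' For each individual i a bivariate-normal deviation (eps_A, eps_K) is
#' drawn with the configured covariance; the individual curve parameters are
#' \deqn{A_i = \mu_A + sex_i \beta_{sex,A} + \sum_j \beta_{A,j} g_{ij} + \epsilon_{A,i}}
#' and analogously for K. Weights follow
#' \deqn{w_{it} = A_i / (1 + \mu_b e^{-K_i t}) + e_{it}, \quad e_{it} \sim N(0, \sigma^2_e),}
#' i.e. exactly the data-generating process the null nonlinear mixed model
#' assumes. Sex is Bernoulli(1/2), coded 0/1.
#'
#' @param config A [sim_config()].
#' @param genotypes A [geno_matrix()] with `config$n_individuals` rows;
#'   generated via [simulate_genotypes()] if omitted.
#' @return A `cohort_bundle`: list with `phenotypes` (long tibble
#'   individual_id, sex, day, weight_g on the complete id x day grid),
#'   `genotypes`, and `truth` (the config plus a per-individual tibble of
#'   realized sex, subpopulation, eps_A, eps_K, A, K).
#' @export
#' @examples
#' b <- simulate_trajectories(sim_config(n_individuals = 10, n_snps = 4, seed = 7))
#' head(b$phenotypes)
simulate_trajectories <- function(config, genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(genotypes)) genotypes <- simulate_genotypes(config)
  n <- config$n_individuals
  if (nrow(genotypes$dosages) != n) {
    abort("`genotypes` must have one row per configured individual.",
          class = "growthgwas_config_error")
  }
  tp <- config$time_points
  Sigma <- sim_sigma(config)

  with_seed(config$seed + 1L, {
    sex <- rbinom(n, 1L, 0.5)
    eps <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = Sigma)
    eps <- matrix(eps, ncol = 2)
    A <- config$mu_A + config$sex_effect_A * sex + eps[, 1]
    K <- config$mu_K + config$sex_effect_K * sex + eps[, 2]
    if (!is.null(config$causal_snps)) {
      for (r in seq_len(nrow(config$causal_snps))) {
        dos <- genotypes$dosages[, config$causal_snps$snp[r]]
        dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
        A <- A + config$causal_snps$beta_A[r] * dos
        K <- K + config$causal_snps$beta_K[r] * dos
      }
    }
    mu <- outer(A, rep(1, length(tp))) /
      (1 + config$mu_b * exp(-outer(K, tp)))
    W <- mu + matrix(rnorm(n * length(tp), 0, sqrt(config$sigma2_e)),
                     n, length(tp))
    ids <- rownames(genotypes$dosages)
    phenotypes <- tibble(
      individual_id = rep(ids, each = length(tp)),
      sex = rep(sex, each = length(tp)),
      day = rep(tp, times = n),
      weight_g = as.vector(t(W))
    )
    truth <- list(
      config = config,
      individuals = tibble(
        individual_id = ids, sex = sex,
        subpop = (attr(genotypes, "subpop") %||% rep(1L, n)),
        eps_A = eps[, 1], eps_K = eps[, 2], A = A, K = K
      )
    )
    structure(list(phenotypes = phenotypes, genotypes = genotypes,
                   truth = truth),
              class = "cohort_bundle")
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> ", length(unique(x$phenotypes$individual_id)),
      " individuals, ", nrow(x$phenotypes), " weight records, ",
      ncol(x$genotypes$dosages), " SNPs\n", sep = "")
  if (!is.null(attr(x, "corruptions"))) {
    cat("  corrupted: ", nrow(attr(x, "corruptions")), " record(s)\n", sep = "")
  }
  invisible(x)
}

#' Inject the corruption patterns phenotype QC is designed to remove
#'
#' Applies three kinds of damage at the rates in `config`, on disjoint
#' record sets:
#' * `outlier_rate`: the weight is replaced by its time-point mean plus
#'   (6 + U) pre-corruption SDs (random sign, U uniform on \[0, 1\]), so each
#'   injected value exceeds the 3-SD screen by a wide margin even after the
#'   injected outliers themselves inflate the time-point SD;
#' * `decrease_rate`: a record (not at the first time point) is replaced by
#'   85% of the nearest earlier non-missing weight, violating the <5%
#'   consecutive-decrease allowance;
#' * `missing_rate`: the weight is set to `NA`.
#'
#' @param bundle A `cohort_bundle` from [simulate_trajectories()].
#' @param config A [sim_config()] carrying the rates (defaults to the
#'   bundle's own config).
#' @return The bundle with corrupted `phenotypes` and a `corruptions`
#'   attribute: a manifest tibble (individual_id, day, kind, original,
#'   corrupted, plus the pre-corruption time-point mean/SD for outliers).
#' @export
corrupt_cohort <- function(bundle, config = bundle$truth$config) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  rates <- c(config$missing_rate, config$outlier_rate, config$decrease_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("Corruption rates must lie in [0, 1].", class = "growthgwas_config_error")
  }
  ph <- bundle$phenotypes
  if (all(rates == 0)) {
    attr(bundle, "corruptions") <- tibble(
      individual_id = character(), day = numeric(), kind = character(),
      original = numeric(), corrupted = numeric(),
      tp_mean = numeric(), tp_sd = numeric()
    )
    return(bundle)
  }

  with_seed(config$seed + 2L, {
    stats0 <- ph |>
      group_by(.data$day) |>
      summarise(tp_mean = mean(.data$weight_g, na.rm = TRUE),
                tp_sd = sd(.data$weight_g, na.rm = TRUE))
    nrec <- nrow(ph)
    idx_all <- seq_len(nrec)
    manifest <- list()

    take <- function(pool, rate) {
      k <- round(rate * nrec)
      sample(pool, min(k, length(pool)))
    }

    out_idx <- take(idx_all, config$outlier_rate)
    if (length(out_idx)) {
      st <- stats0[match(ph$day[out_idx], stats0$day), ]
      sign <- sample(c(-1, 1), length(out_idx), replace = TRUE)
      newv <- st$tp_mean + sign * (6 + runif(length(out_idx))) * st$tp_sd
      newv <- pmax(newv, 1) # weights stay positive; still far outside 3 SD
      manifest$outlier <- tibble(
        individual_id = ph$individual_id[out_idx], day = ph$day[out_idx],
        kind = "outlier", original = ph$weight_g[out_idx], corrupted = newv,
        tp_mean = st$tp_mean, tp_sd = st$tp_sd
      )
      ph$weight_g[out_idx] <- newv
    }

    pool <- setdiff(idx_all, out_idx)
    first_day <- min(ph$day)
    drop_idx <- take(pool[ph$day[pool] > first_day], config$decrease_rate)
    if (length(drop_idx)) {
      newv <- vapply(drop_idx, function(i) {
        prev <- ph |>
          filter(.data$individual_id == ph$individual_id[i],
                 .data$day < ph$day[i], !is.na(.data$weight_g)) |>
          arrange(.data$day)
        if (nrow(prev) == 0) return(NA_real_)
        0.85 * prev$weight_g[nrow(prev)]
      }, numeric(1))
      ok <- !is.na(newv)
      drop_idx <- drop_idx[ok]; newv <- newv[ok]
      manifest$decrease <- tibble(
        individual_id = ph$individual_id[drop_idx], day = ph$day[drop_idx],
        kind = "decrease", original = ph$weight_g[drop_idx], corrupted = newv,
        tp_mean = NA_real_, tp_sd = NA_real_
      )
      ph$weight_g[drop_idx] <- newv
    }

    pool <- setdiff(pool, drop_idx)
    mis_idx <- take(pool, config$missing_rate)
    if (length(mis_idx)) {
      manifest$missing <- tibble(
        individual_id = ph$individual_id[mis_idx], day = ph$day[mis_idx],
        kind = "missing", original = ph$weight_g[mis_idx],
        corrupted = NA_real_, tp_mean = NA_real_, tp_sd = NA_real_
      )
      ph$weight_g[mis_idx] <- NA_real_
    }

    bundle$phenotypes <- ph
    attr(bundle, "corruptions") <- bind_rows(manifest)
    bundle
  })
}
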
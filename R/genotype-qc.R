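#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts that are no
#' more probable than the observed one. Probabilities follow the standard
#' recurrence over heterozygote counts of matching parity.
#'
#' @param n_homref,n_het,n_homalt Genotype counts.
#' @return The exact p-value (1 for monomorphic SNPs).
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)   # modal het count -> p = 1
#' hwe_exact_test(50, 0, 50)    # extreme deficit  -> p ~ 1e-30
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  if (any(c(n_homref, n_het, n_homalt) < 0)) abort("Counts must be >= 0.")
  n <- n_homref + n_het + n_homalt
  if (n == 0) abort("HWE test undefined for zero individuals.")
  # rare allele count (conditioning statistic), total alleles 2n
  n_rare <- 2 * min(n_homref, n_homalt) + n_het
  if (n_rare == 0) return(1)

  # heterozygote counts share the parity of the rare-allele count
  het_vals <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  probs <- numeric(length(het_vals))
  # start at the mid value and fill by the recurrence
  # P(h+2)/P(h) = [ (n_rare-h)(2n-n_rare-h) ] / [ (h+2)(h+1) ] applied on
  # log scale via the ratio for hom counts
  mid <- which.min(abs(het_vals - n_rare * (2 * n - n_rare) / (2 * n)))
  logp <- numeric(length(het_vals))
  logp[mid] <- 0
  if (mid < length(het_vals)) {
    for (k in mid:(length(het_vals) - 1)) {
      h <- het_vals[k]
      hr <- (n_rare - h) / 2          # rare homozygotes at h
      hc <- (2 * n - n_rare - h) / 2  # common homozygotes at h
      logp[k + 1] <- logp[k] + log(4 * hr * hc) - log((h + 2) * (h + 1))
    }
  }
  if (mid > 1) {
    for (k in mid:2) {
      h <- het_vals[k]
      hr <- (n_rare - h) / 2 + 1
      hc <- (2 * n - n_rare - h) / 2 + 1
      logp[k - 1] <- logp[k] + log(h * (h - 1)) - log(4 * hr * hc)
    }
  }
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- match(n_het, het_vals)
  if (is.na(obs)) abort("Observed heterozygote count inconsistent with allele counts.")
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-10)]))
}

#' SNP and individual filtering
#'
#' Applies the panel-level quality-control thresholds in a fixed order:
#' SNP call rate, individual call rate, minor allele frequency, exact
#' Hardy-Weinberg test. All inequalities are strict: a SNP survives when
#' its missing fraction is lower than `max_snp_missing`, its MAF is higher
#' than `min_maf` and its HWE p-value is higher than `hwe_p_floor`;
#' individuals survive when their missing fraction is lower than
#' `max_ind_missing`.
#'
#' @param gm A [geno_matrix()].
#' @param max_snp_missing,max_ind_missing,min_maf,hwe_p_floor Thresholds.
#' @return The filtered [geno_matrix()]; attribute `filter_report` holds a
#'   tibble of SNPs/individuals removed per stage.
#' @export
filter_snps <- function(gm, max_snp_missing = 0.1, max_ind_missing = 0.2,
                        min_maf = 0.05, hwe_p_floor = 1e-8) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (ncol(gm$dosages) == 0) abort("Empty genotype matrix.")
  stages <- list()

  miss_snp <- colMeans(is.na(gm$dosages))
  keep <- miss_snp < max_snp_missing
  stages$snp_call_rate <- sum(!keep)
  gm <- gm[, keep]
  if (ncol(gm$dosages) == 0) abort("All SNPs removed by call-rate filter.")

  miss_ind <- rowMeans(is.na(gm$dosages))
  keep_ind <- miss_ind < max_ind_missing
  stages$ind_call_rate <- sum(!keep_ind)
  gm <- gm[keep_ind, ]

  info <- tidy(gm)
  keep <- info$maf > min_maf
  stages$maf <- sum(!keep)
  gm <- gm[, keep]
  if (ncol(gm$dosages) == 0) abort("All SNPs removed by MAF filter.")

  info <- tidy(gm)
  hwe_p <- mapply(hwe_exact_test, info$n_homref, info$n_het, info$n_homalt)
  keep <- hwe_p > hwe_p_floor
  stages$hwe <- sum(!keep)
  gm <- gm[, keep]
  if (ncol(gm$dosages) == 0) abort("All SNPs removed by HWE filter.")

  attr(gm, "filter_report") <- tibble(
    stage = names(stages), n_removed = unlist(stages, use.names = FALSE)
  )
  gm
}

#' Frequency-based imputation of missing genotypes
#'
#' Each missing dosage is drawn from the SNP's observed genotype frequency
#' distribution. This keeps allele and genotype frequencies unbiased and is
#' sufficient to complete the matrix for LD pruning and PCA; it does not
#' borrow haplotype information across SNPs.
#'
#' @param gm A [geno_matrix()].
#' @param seed Integer seed; imputation is deterministic given it.
#' @return The completed [geno_matrix()] (no missing entries).
#' @export
impute_genotypes <- function(gm, seed = 1L) {
  stopifnot(inherits(gm, "geno_matrix"))
  D <- gm$dosages
  if (!anyNA(D)) return(gm)
  if (any(colMeans(is.na(D)) == 1)) {
    abort("Fully missing SNP: filter before imputing.")
  }
  with_seed(seed, {
    for (j in which(colSums(is.na(D)) > 0)) {
      obs <- D[!is.na(D[, j]), j]
      miss <- which(is.na(D[, j]))
      D[miss, j] <- sample(obs, length(miss), replace = TRUE)
    }
  })
  geno_matrix(D, gm$snps)
}

#' Greedy LD pruning by pairwise dosage correlation
#'
#' Scans SNPs left to right within each chromosome; a SNP is dropped when
#' its squared Pearson correlation with any already-retained SNP among the
#' nearest `window` retained SNPs exceeds `r2_max`. Guarantees that no
#' retained in-window pair has r^2 above the threshold.
#'
#' @param gm A complete (imputed) [geno_matrix()].
#' @param r2_max Squared-correlation threshold above which the later SNP is
#'   discarded.
#' @param window Number of most recent retained SNPs compared against.
#' @return The pruned [geno_matrix()]; attribute `prune_report` gives per
#'   chromosome counts.
#' @export
ld_prune <- function(gm, r2_max = 0.9, window = 50) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (anyNA(gm$dosages)) abort("LD pruning requires a complete (imputed) matrix.")
  keep <- logical(ncol(gm$dosages))
  for (ch in unique(gm$snps$chrom)) {
    idx <- which(gm$snps$chrom == ch)
    idx <- idx[order(gm$snps$pos[idx])]
    retained <- integer(0)
    for (j in idx) {
      cmp <- tail(retained, window)
      drop <- FALSE
      if (length(cmp)) {
        sj <- sd(gm$dosages[, j])
        if (sj > 0) {
          r <- suppressWarnings(cor(gm$dosages[, j], gm$dosages[, cmp, drop = FALSE]))
          r[is.na(r)] <- 0
          drop <- any(r^2 > r2_max)
        }
      }
      if (!drop) retained <- c(retained, j)
      keep[j] <- !drop
    }
  }
  out <- gm[, keep]
  attr(out, "prune_report") <- tibble(
    n_input = ncol(gm$dosages), n_removed = sum(!keep), n_retained = sum(keep)
  )
  out
}

#' Principal components of the genotype matrix
#'
#' Columns are standardized (mean 0, unit variance; zero-variance SNPs
#' dropped) and decomposed by singular values; the leading component scores
#' are returned as covariates for association models, together with the
#' full explained-variance spectrum.
#'
#' @param gm A complete [geno_matrix()].
#' @param n_components Number of leading components to return as scores.
#' @return Object of class `pca_covariates`: list with `scores` (tibble:
#'   individual_id, PC1..PCk), `explained_fraction` (length k) and
#'   `explained_all` (full spectrum, sums to 1).
#' @export
pca_genotypes <- function(gm, n_components = 5) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (anyNA(gm$dosages)) abort("PCA requires a complete (imputed) matrix.")
  n <- nrow(gm$dosages)
  if (n < n_components + 1) abort("Need more individuals than components.")
  sds <- apply(gm$dosages, 2, sd)
  X <- scale(gm$dosages[, sds > 0, drop = FALSE])
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  if (n_components > length(pc$sdev)) {
    abort("`n_components` exceeds the rank of the genotype matrix.")
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  names(scores) <- paste0("PC", seq_len(n_components))
  structure(list(
    scores = bind_cols(tibble(individual_id = rownames(gm$dosages)), scores),
    explained_fraction = explained[seq_len(n_components)],
    explained_all = explained
  ), class = "pca_covariates")
}

#' @export
print.pca_covariates <- function(x, ...) {
  k <- length(x$explained_fraction)
  cat("<pca_covariates> ", nrow(x$scores), " individuals, ", k,
      " components explaining ",
      sprintf("%.1f%%", 100 * sum(x$explained_fraction)),
      " of genotypic variance\n", sep = "")
  invisible(x)
}
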
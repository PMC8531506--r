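test_that("HWE exact test matches full enumeration for n <= 50", {
  cases <- expand.grid(hr = c(0, 1, 2, 5, 12, 25), het = c(0, 1, 4, 10, 25),
                       ha = c(0, 1, 3, 13, 25))
  cases <- cases[rowSums(cases) > 0 & rowSums(cases) <= 50, ]
  for (i in seq_len(nrow(cases))) {
    got <- hwe_exact_test(cases$hr[i], cases$het[i], cases$ha[i])
    want <- hwe_enumerate(cases$hr[i], cases$het[i], cases$ha[i])
    expect_lt(abs(got - want), 1e-12)
  }
})

test_that("HWE exact test handles the documented reference cases", {
  expect_equal(hwe_exact_test(25, 50, 25), 1)          # modal het count
  expect_equal(hwe_exact_test(1, 0, 0), 1)             # monomorphic
  expect_lt(hwe_exact_test(50, 0, 50), 1e-8)           # total het deficit
  expect_lt(hwe_exact_test(48, 4, 48), 1e-8)           # near-total deficit
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

make_gm <- function(D, chrom = NULL) {
  m <- ncol(D)
  geno_matrix(D, tibble::tibble(
    snp_id = sprintf("s%03d", 1:m),
    chrom = chrom %||% rep("chr1", m),
    pos = as.integer(seq_len(m) * 1000)
  ))
}

test_that("filter_snps applies strict thresholds in the documented order", {
  set.seed(42)
  n <- 100
  good <- rbinom(n, 2, 0.3)
  miss15 <- good; miss15[1:15] <- NA               # 15% missing
  maf5 <- c(rep(1, 10), rep(0, 90))                # MAF exactly 0.05
  hwe_bad <- c(rep(0, 48), rep(1, 4), rep(2, 48))  # het deficit, p < 1e-8
  D <- cbind(good, miss15, maf5, hwe_bad)
  colnames(D) <- NULL
  gm <- make_gm(D)
  out <- filter_snps(gm)
  expect_equal(out$snps$snp_id, "s001")
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_removed[rep$stage == "snp_call_rate"], 1)
  expect_equal(rep$n_removed[rep$stage == "maf"], 1)
  expect_equal(rep$n_removed[rep$stage == "hwe"], 1)

  # idempotence
  out2 <- filter_snps(out)
  expect_identical(out2$dosages, out$dosages)

  # individuals with high missingness are dropped
  D2 <- matrix(rbinom(20 * 10, 2, 0.4), 20, 10)
  D2[1, 3:10] <- NA   # individual 1: 80% missing
  gm2 <- make_gm(D2)
  out3 <- filter_snps(gm2, max_snp_missing = 0.5)
  expect_equal(nrow(out3$dosages), 19)

  expect_error(filter_snps(make_gm(matrix(c(rep(1, 10), rep(0, 90)), 100, 1))),
               "MAF")
})

test_that("imputation is frequency-based, seeded, and degenerate-safe", {
  D <- matrix(2, 30, 2)
  D[1:10, 1] <- NA
  gm <- make_gm(D)
  imp <- impute_genotypes(gm, seed = 7)
  expect_true(all(imp$dosages == 2))  # only dosage 2 observed

  set.seed(99)
  D2 <- matrix(rbinom(200 * 3, 2, 0.4), 200, 3)
  D2[sample(600, 60)] <- NA
  gm2 <- make_gm(D2)
  i1 <- impute_genotypes(gm2, seed = 5)
  i2 <- impute_genotypes(gm2, seed = 5)
  expect_identical(i1$dosages, i2$dosages)
  expect_false(anyNA(i1$dosages))
  # observed entries untouched
  expect_identical(i1$dosages[!is.na(D2)], D2[!is.na(D2)])

  # no missing -> identity
  D3 <- matrix(rbinom(40, 2, 0.5), 20, 2)
  gm3 <- make_gm(D3)
  expect_identical(impute_genotypes(gm3, seed = 1)$dosages, gm3$dosages)

  D4 <- matrix(NA_real_, 10, 1)
  expect_error(impute_genotypes(make_gm(D4), seed = 1), "Fully missing")
})

test_that("LD pruning removes duplicates and leaves independent SNPs alone", {
  set.seed(17)
  D <- matrix(rbinom(1000 * 30, 2, 0.4), 1000, 30)
  gm <- make_gm(D)
  dup <- inject_duplicate_snps(gm, c(5, 12))
  pruned <- ld_prune(dup)
  expect_false(any(grepl("_dup", pruned$snps$snp_id)))
  expect_equal(ncol(pruned$dosages), 30)
  expect_equal(attr(pruned, "prune_report")$n_removed, 2)

  # postcondition: no retained in-window pair above the threshold
  Dp <- pruned$dosages
  r2 <- cor(Dp)^2
  diag(r2) <- 0
  expect_lt(max(r2), 0.9)
})

test_that("genotype PCA matches an eigendecomposition oracle and separates structure", {
  set.seed(31)
  D <- matrix(rbinom(60 * 80, 2, 0.35), 60, 80)
  gm <- make_gm(D)
  pca <- pca_genotypes(gm, n_components = 5)

  expect_lt(abs(sum(pca$explained_all) - 1), 1e-9)
  expect_true(all(diff(pca$explained_all) < 1e-12))
  expect_true(all(pca$explained_all >= 0 & pca$explained_all <= 1))

  # oracle: eigen of the correlation-scaled covariance
  X <- scale(D)
  ev <- eigen(crossprod(X) / (nrow(X) - 1))
  expect_equal(pca$explained_all[1:5],
               (ev$values / sum(ev$values))[1:5], tolerance = 1e-8)
  sc_or <- X %*% ev$vectors[, 1:2]
  got <- as.matrix(pca$scores[, c("PC1", "PC2")])
  for (k in 1:2) {
    expect_lt(min(max(abs(got[, k] - sc_or[, k])),
                  max(abs(got[, k] + sc_or[, k]))), 1e-8)
  }

  # duplicated individuals get identical scores
  gm2 <- make_gm(rbind(D, D))
  p2 <- pca_genotypes(gm2, n_components = 2)
  s <- as.matrix(p2$scores[, -1])
  expect_equal(s[1:60, ], s[61:120, ], ignore_attr = TRUE)

  # two-island structure shows up on PC1
  cfg <- sim_config(n_individuals = 120, n_snps = 300, n_subpops = 2,
                    subpop_divergence = 0.15, seed = 23)
  gms <- simulate_genotypes(cfg)
  sp <- attr(gms, "subpop")
  ps <- pca_genotypes(gms, n_components = 2)
  pc1 <- ps$scores$PC1
  expect_gt(abs(mean(pc1[sp == 1]) - mean(pc1[sp == 2])),
            sd(pc1[sp == 1]) + sd(pc1[sp == 2]))

  expect_error(pca_genotypes(gm, n_components = 61), "rank|components")
})
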
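test_that("BH adjustment matches hand-computed q-values", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(fdr_adjust(p, method = "BH"),
               c(0.004, 0.02, 0.8 / 30, 0.8))
  # all p = 1 -> all q = 1
  expect_equal(fdr_adjust(rep(1, 5), method = "BH"), rep(1, 5))
})

test_that("Storey q-values with pi0 = 1 reduce exactly to BH", {
  set.seed(3)
  p <- c(runif(200), runif(20, 0, 0.001))
  expect_equal(fdr_adjust(p, method = "storey", pi0 = 1),
               fdr_adjust(p, method = "BH"))
})

test_that("Storey pi0 shrinks q-values on a mostly-null mixture", {
  set.seed(8)
  p <- c(runif(900), rbeta(100, 0.1, 10))
  pi0 <- estimate_pi0(p)
  expect_true(is.finite(pi0) && pi0 < 1 && pi0 > 0.6)
  q_st <- fdr_adjust(p, method = "storey")
  q_bh <- fdr_adjust(p, method = "BH")
  expect_true(all(q_st <= q_bh + 1e-12))
  expect_equal(q_st, pmin(pi0 * q_bh, 1))
})

test_that("small panels fall back to BH with a warning; NAs propagate", {
  p <- c(0.01, NA, 0.5, 0.2)
  expect_warning(q <- fdr_adjust(p, method = "storey"), "BH")
  expect_true(is.na(q[2]))
  # the NA must not count toward m
  expect_equal(q[!is.na(p)], p.adjust(p[!is.na(p)], "BH"))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("call_significant respects threshold boundaries and hypothesis", {
  rec <- tibble::tibble(snp_id = sprintf("s%d", 1:4),
                        hypothesis = c("M1", "M1", "M2", "M1"),
                        q_value = c(0.01, 0.05, 0.02, NA))
  expect_equal(call_significant(rec)$snp_id, c("s1", "s3"))   # 0.05 not < 0.05
  expect_equal(call_significant(rec, hypothesis = "M1")$snp_id, "s1")
  expect_equal(nrow(call_significant(rec, q_threshold = 1)), 3) # NA stays out
  expect_equal(nrow(call_significant(rec, q_threshold = 1e-4)), 0)
})

test_that("scan detects a strong two-parameter signal and ranks it first", {
  cfg <- sim_config(n_individuals = 300, n_snps = 12, maf_low = 0.25,
                    maf_high = 0.5,
                    causal_snps = tibble::tibble(snp = 5, beta_A = 150,
                                                 beta_K = 0.004),
                    seed = 91)
  b <- simulate_trajectories(cfg)
  cov <- sex_covariates(b)
  sc <- run_scan(b$phenotypes, b$genotypes, covariates = cov,
                 hypotheses = "M1", q_method = "BH")
  m1 <- sc[sc$hypothesis == "M1", ]
  expect_equal(nrow(m1), 12)
  expect_true(all(m1$converged))
  expect_equal(m1$snp_id[which.min(m1$p_value)], "snp00005")
  expect_lt(m1$p_value[m1$snp_id == "snp00005"], 1e-6)
  # q order-consistent with p within the hypothesis
  ord <- order(m1$p_value)
  expect_true(all(diff(m1$q_value[ord]) >= -1e-12))
})

test_that("scan output is invariant to SNP ordering and skips monomorphics", {
  cfg <- sim_config(n_individuals = 60, n_snps = 6, seed = 71)
  b <- simulate_trajectories(cfg)
  gm <- b$genotypes
  gm$dosages[, 2] <- 2  # force monomorphic
  cov <- sex_covariates(b)
  m0 <- fit_nmm(b$phenotypes, covariates = cov)

  sc <- run_scan(b$phenotypes, gm, covariates = cov, hypotheses = "M2",
                 q_method = "BH", m0 = m0)
  expect_equal(attr(sc, "skipped")$snp_id, "snp00002")
  expect_false("snp00002" %in% sc$snp_id)

  perm <- c(4, 1, 6, 3, 2, 5)
  gm_perm <- gm[, perm]
  sc_perm <- run_scan(b$phenotypes, gm_perm, covariates = cov,
                      hypotheses = "M2", q_method = "BH", m0 = m0)
  a <- sc |> dplyr::arrange(snp_id)
  bb <- sc_perm |> dplyr::arrange(snp_id)
  expect_equal(a$p_value, bb$p_value, tolerance = 1e-8)
  expect_equal(a$q_value, bb$q_value, tolerance = 1e-8)

  # empty hypothesis set -> empty records
  sc0 <- run_scan(b$phenotypes, gm, covariates = cov, hypotheses = character(0),
                  m0 = m0)
  expect_equal(nrow(sc0), 0)
})

test_that("M1 statistic dominates M2 and M3 against the shared null", {
  cfg <- sim_config(n_individuals = 120, n_snps = 4, seed = 37)
  b <- simulate_trajectories(cfg)
  cov <- sex_covariates(b)
  sc <- run_scan(b$phenotypes, b$genotypes, covariates = cov, q_method = "BH")
  wide <- sc |>
    dplyr::select(snp_id, hypothesis, statistic) |>
    tidyr::pivot_wider(names_from = hypothesis, values_from = statistic)
  tol <- 1e-2
  expect_true(all(wide$M1 >= wide$M2 - tol))
  expect_true(all(wide$M1 >= wide$M3 - tol))
})

test_that("FDR among significant calls stays controlled with true effects present", {
  # 5% of the panel carries a large two-parameter effect; at n = 400 chance
  # genotype correlation between null and causal SNPs is too weak to leak
  # real signal into the null calls, so the pooled FDR reflects calibration.
  fp <- 0L; calls <- 0L; tp <- 0L
  for (r in 1:5) {
    cfg <- sim_config(n_individuals = 400, n_snps = 40, maf_low = 0.25,
                      maf_high = 0.5,
                      causal_snps = tibble::tibble(snp = c(9, 23),
                                                   beta_A = 150,
                                                   beta_K = 0.004),
                      seed = 500 + r)
    b <- simulate_trajectories(cfg)
    cov <- sex_covariates(b)
    sc <- run_scan(b$phenotypes, b$genotypes, covariates = cov,
                   hypotheses = "M1", q_method = "BH")
    hit <- call_significant(sc, hypothesis = "M1")
    calls <- calls + nrow(hit)
    tp <- tp + sum(hit$snp_id %in% c("snp00009", "snp00023"))
    fp <- fp + sum(!hit$snp_id %in% c("snp00009", "snp00023"))
  }
  expect_gte(tp, 8)              # strong effects are found
  expect_lte(fp / max(calls, 1), 0.10)
})

test_that("manhattan autoplot builds without error", {
  rec <- structure(
    tibble::tibble(snp_id = sprintf("s%d", 1:20),
                   chrom = rep(c("chr1", "chr2"), each = 10),
                   pos = rep(seq(1e5, 1e6, length.out = 10), 2),
                   hypothesis = "M1",
                   statistic = rchisq(20, 2), df = 2,
                   p_value = runif(20), q_value = runif(20),
                   converged = TRUE),
    class = c("gwas_scan", class(tibble::tibble())))
  p <- ggplot2::autoplot(rec)
  expect_s3_class(p, "ggplot")
})
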
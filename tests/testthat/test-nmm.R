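test_that("with Sigma = 0 both likelihoods equal the exact iid computation", {
  fx <- oracle_fixture()
  par_z <- fx$params
  par_z$Sigma <- matrix(0, 2, 2)
  f <- growth_curve("logistic", fx$phenotypes$day, par_z$beta_A,
                    par_z$beta_K, par_z$mu_b)
  ll_direct <- sum(dnorm(fx$phenotypes$weight_g, f,
                         sqrt(par_z$sigma2_e), log = TRUE))
  expect_equal(marginal_loglik(par_z, fx$phenotypes), ll_direct,
               tolerance = 1e-8)
  expect_equal(quadrature_loglik(par_z, fx$phenotypes), ll_direct,
               tolerance = 1e-8)
})

test_that("linearized likelihood tracks the Gauss-Hermite oracle", {
  fx <- oracle_fixture()
  ll_lin <- marginal_loglik(fx$params, fx$phenotypes)
  ll_q21 <- quadrature_loglik(fx$params, fx$phenotypes, n_nodes = 21)
  expect_lt(abs(ll_lin - ll_q21), 0.5)

  # quadrature is internally converged: 11 vs 21 nodes
  ll_q11 <- quadrature_loglik(fx$params, fx$phenotypes, n_nodes = 11)
  expect_lt(abs(ll_q11 - ll_q21), 1e-4)
})

test_that("quadrature oracle agrees with Monte-Carlo integration", {
  fx <- oracle_fixture()
  ll_q <- quadrature_loglik(fx$params, fx$phenotypes, n_nodes = 21)
  S <- fx$params$Sigma
  L <- t(chol(S))
  nd <- 100000
  ids <- sort(unique(fx$phenotypes$individual_id))
  set.seed(2024)
  tot <- 0
  se2 <- 0
  for (i in ids) {
    d <- fx$phenotypes[fx$phenotypes$individual_id == i, ]
    eps <- L %*% matrix(rnorm(2 * nd), 2)
    A <- fx$params$beta_A + eps[1, ]
    K <- fx$params$beta_K + eps[2, ]
    cll <- rowSums(vapply(seq_along(d$day), function(k) {
      dnorm(d$weight_g[k],
            A / (1 + fx$params$mu_b * exp(-K * d$day[k])),
            sqrt(fx$params$sigma2_e), log = TRUE)
    }, numeric(nd)))
    mx <- max(cll)
    wgt <- exp(cll - mx)
    tot <- tot + mx + log(mean(wgt))
    se2 <- se2 + var(wgt) / (nd * mean(wgt)^2)  # delta-method SE of log-mean
  }
  expect_lt(abs(ll_q - tot), 3 * sqrt(se2))
})

test_that("a zero-coefficient SNP column leaves the likelihood unchanged", {
  fx <- oracle_fixture()
  ll0 <- marginal_loglik(fx$params, fx$phenotypes)
  ids <- sort(unique(fx$phenotypes$individual_id))
  dos <- setNames(c(0, 1, 2, 1, 0), ids)
  par_snp <- fx$params
  par_snp$beta_A <- c(par_snp$beta_A, 0)
  par_snp$beta_K <- c(par_snp$beta_K, 0)
  ll1 <- marginal_loglik(par_snp, fx$phenotypes, snp = dos,
                         snp_target = "both")
  expect_equal(ll1, ll0, tolerance = 1e-10)
})

test_that("parameter validation rejects malformed inputs", {
  fx <- oracle_fixture()
  bad <- fx$params
  bad$Sigma <- matrix(c(1, 2, 2, 1), 2, 2)  # not PSD
  expect_error(marginal_loglik(bad, fx$phenotypes), "PSD")
  bad2 <- fx$params
  bad2$beta_A <- c(1, 2)                     # wrong length
  expect_error(marginal_loglik(bad2, fx$phenotypes), "length")
  ph1 <- fx$phenotypes[fx$phenotypes$day == 35, ]
  expect_error(nmm_data(ph1), "time points")
})

test_that("M0 fitting recovers the generating parameters", {
  cfg <- sim_config(n_individuals = 150, n_snps = 2, seed = 77)
  b <- simulate_trajectories(cfg)
  fit <- fit_nmm(b$phenotypes, covariates = sex_covariates(b))
  expect_true(fit$converged)
  expect_lt(abs(fit$coef_A[["(Intercept)"]] - 2615.45) / 2615.45, 0.02)
  expect_lt(abs(fit$coef_K[["(Intercept)"]] - 0.054) / 0.054, 0.05)
  expect_lt(abs(fit$mu_b - 15.35) / 15.35, 0.1)
  # variance components land in the right range
  expect_lt(abs(sqrt(fit$Sigma[1, 1]) - 210) / 210, 0.3)
  expect_lt(abs(sqrt(fit$sigma2_e) - 60) / 60, 0.15)

  # refitting from the solution moves the likelihood by < tol
  fit2 <- fit_nmm(b$phenotypes, covariates = sex_covariates(b), start = fit)
  expect_lt(abs(fit2$logLik - fit$logLik), 1e-4 * abs(fit$logLik))

  # degenerate data error
  expect_error(fit_nmm(b$phenotypes[b$phenotypes$day == 35, ]),
               "time points")
})

test_that("parameter counts give the documented LRT degrees of freedom", {
  b <- small_bundle(n = 25, seed = 41)
  cov <- sex_covariates(b)
  ids <- sort(unique(b$phenotypes$individual_id))
  dos <- b$genotypes$dosages[ids, 1]; names(dos) <- ids
  m0 <- fit_nmm(b$phenotypes, covariates = cov)
  m1 <- fit_nmm(b$phenotypes, covariates = cov, snp = dos,
                snp_target = "both", start = m0)
  m2 <- fit_nmm(b$phenotypes, covariates = cov, snp = dos,
                snp_target = "A", start = m0)
  m3 <- fit_nmm(b$phenotypes, covariates = cov, snp = dos,
                snp_target = "K", start = m0)
  expect_equal(m1$n_params - m0$n_params, 2)
  expect_equal(m2$n_params - m0$n_params, 1)
  expect_equal(m3$n_params - m0$n_params, 1)

  # nesting: alternatives cannot fit worse than the null (up to tolerance)
  tol <- 1e-3
  expect_gte(m1$logLik, m0$logLik - tol)
  expect_gte(m2$logLik, m0$logLik - tol)
  expect_gte(m3$logLik, m0$logLik - tol)
  expect_gte(m1$logLik, m2$logLik - tol)
  expect_gte(m1$logLik, m3$logLik - tol)
})

test_that("lrt computes the closed-form chi-square tail", {
  mk <- function(ll, k, conv = TRUE) {
    structure(list(logLik = ll, n_params = k, converged = conv,
                   snp_target = "none"), class = "nmm_fit")
  }
  out <- lrt(mk(-50, 13), mk(-52, 11))
  expect_equal(out$statistic, 4)
  expect_equal(out$df, 2)
  expect_equal(out$p_value, exp(-2), tolerance = 1e-12)

  same <- lrt(mk(-50, 12), mk(-50, 11))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # numeric slip below the null is clamped at zero
  clip <- lrt(mk(-50.0001, 12), mk(-50, 11))
  expect_equal(clip$statistic, 0)

  nc <- lrt(mk(-50, 12, conv = FALSE), mk(-52, 11))
  expect_false(nc$available)
  expect_true(is.na(nc$p_value))

  expect_error(lrt(mk(-50, 11), mk(-50, 12)), "nested")
})

test_that("standard errors cover a known SNP effect", {
  cfg <- sim_config(n_individuals = 150, n_snps = 3, maf_low = 0.3,
                    maf_high = 0.5,
                    causal_snps = tibble::tibble(snp = 1, beta_A = 150,
                                                 beta_K = 0.004),
                    seed = 55)
  b <- simulate_trajectories(cfg)
  ids <- sort(unique(b$phenotypes$individual_id))
  dos <- b$genotypes$dosages[ids, 1]; names(dos) <- ids
  m0 <- fit_nmm(b$phenotypes, covariates = sex_covariates(b))
  m1 <- fit_nmm(b$phenotypes, covariates = sex_covariates(b), snp = dos,
                snp_target = "both", start = m0, se = TRUE)
  expect_true(m1$converged)
  expect_true(is.finite(m1$se_A[["snp"]]) && m1$se_A[["snp"]] > 0)
  expect_lt(abs(m1$coef_A[["snp"]] - 150) / m1$se_A[["snp"]], 3)
  expect_lt(abs(m1$coef_K[["snp"]] - 0.004) / m1$se_K[["snp"]], 3)
})

test_that("the fit agrees with an independent mixed-model implementation", {
  b <- simulate_trajectories(sim_config(n_individuals = 60, n_snps = 2,
                                        seed = 17))
  fit <- fit_nmm(b$phenotypes)
  nl <- nlme::nlme(weight_g ~ A / (1 + bb * exp(-K * day)),
                   fixed = A + K + bb ~ 1,
                   random = A + K ~ 1 | individual_id,
                   data = as.data.frame(b$phenotypes),
                   start = c(A = 2600, K = 0.054, bb = 15),
                   method = "ML",
                   control = nlme::nlmeControl(maxIter = 100,
                                               returnObject = TRUE))
  fe <- nlme::fixef(nl)
  expect_lt(abs(fit$coef_A[[1]] - fe[["A"]]) / fe[["A"]], 0.02)
  expect_lt(abs(fit$coef_K[[1]] - fe[["K"]]) / fe[["K"]], 0.02)
  expect_lt(abs(fit$mu_b - fe[["bb"]]) / fe[["bb"]], 0.05)
  expect_lt(abs(fit$logLik - as.numeric(stats::logLik(nl))), 1)
})

test_that("tidy and glance expose the fitted NMM", {
  b <- small_bundle(n = 25, seed = 61)
  fit <- fit_nmm(b$phenotypes, covariates = sex_covariates(b))
  td <- tidy(fit)
  expect_true(all(c("sigma2_A", "sigma2_K", "sigma_AK", "sigma2_e") %in%
                    td$term[td$part == "variance"]))
  expect_equal(glance(fit)$n_params, 2 + 2 + 5)
})
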
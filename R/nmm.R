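#' Nonlinear mixed model for logistic growth trajectories
#'
#' The association engine embeds SNP effects directly in the fixed effects
#' of a logistic growth curve. For individual i at day t,
#' \deqn{w_{it} = \frac{\eta_{A,i} + \epsilon_{A,i}}
#'   {1 + \mu_b \exp[-(\eta_{K,i} + \epsilon_{K,i})\, t]} + e_{it},}
#' where \eqn{\eta_{A,i} = x_i' \beta_A} and \eqn{\eta_{K,i} = x_i' \beta_K}
#' are linear predictors (intercept, sex, principal components and — in the
#' alternative models — a centered SNP dosage), the individual deviations
#' \eqn{(\epsilon_{A,i}, \epsilon_{K,i})} are bivariate normal with
#' covariance \eqn{\Sigma}, and \eqn{e_{it} \sim N(0, \sigma^2_e)} i.i.d.
#' The time-scale mean \eqn{\mu_b} carries no covariates or random effect.
#'
#' Four nested models differ only in where the SNP enters: M0 nowhere,
#' M1 both parts (`snp_target = "both"`), M2 the A part only (`"A"`),
#' M3 the K part only (`"K"`).
#'
#' The marginal likelihood integrates the bivariate deviations out. The
#' working approximation is a first-order conditional expansion: per
#' individual the conditional mode of \eqn{(\epsilon_A, \epsilon_K)} is
#' found by damped Gauss-Newton, the mean is linearized there, and the
#' resulting Gaussian marginal is evaluated in closed form. An adaptive
#' Gauss-Hermite quadrature version ([quadrature_loglik()]) serves as the
#' accuracy oracle.
#'
#' @name nmm_model
NULL

# ---- data assembly ---------------------------------------------------------

# Build the matrices the likelihood works on: W (individuals x schedule,
# NA = missing), observation mask, time vector, and the A-/K-part design
# matrices. `snp` may be a plain vector in id order or named by id.
nmm_data <- function(phenotypes, covariates = NULL, snp = NULL,
                     snp_target = "none") {
  check_phenotypes(phenotypes)
  ids <- sort(unique(phenotypes$individual_id))
  days <- sort(unique(phenotypes$day))
  n <- length(ids)
  W <- matrix(NA_real_, n, length(days), dimnames = list(ids, days))
  W[cbind(match(phenotypes$individual_id, ids),
          match(phenotypes$day, days))] <- phenotypes$weight_g
  keep <- rowSums(!is.na(W)) > 0
  W <- W[keep, , drop = FALSE]
  ids <- ids[keep]
  n <- length(ids)

  X <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    if (!"individual_id" %in% names(covariates)) {
      abort("`covariates` needs an individual_id column.")
    }
    cv <- covariates[match(ids, covariates$individual_id), , drop = FALSE]
    if (anyNA(cv$individual_id)) abort("Missing covariates for some individuals.")
    num <- cv[setdiff(names(cv), "individual_id")]
    X <- cbind(X, as.matrix(num))
  }
  snp_centered <- NULL
  if (!is.null(snp)) {
    if (!is.null(names(snp))) snp <- snp[ids]
    if (length(snp) != n || anyNA(snp)) {
      abort("`snp` must supply a dosage for every phenotyped individual.")
    }
    snp_centered <- snp - mean(snp)
  }
  XA <- X; XK <- X
  if (!is.null(snp_centered) && snp_target %in% c("both", "A")) {
    XA <- cbind(XA, snp = snp_centered)
  }
  if (!is.null(snp_centered) && snp_target %in% c("both", "K")) {
    XK <- cbind(XK, snp = snp_centered)
  }
  M <- !is.na(W)
  W0 <- W; W0[!M] <- 0
  if (sum(colSums(M) > 0) < 2) abort("Need data at >= 2 distinct time points.")
  if (var(W[M]) == 0) abort("Weights are constant; model is degenerate.")
  list(W = W0, M = M * 1, tvec = days,
       Tmat = matrix(days, n, length(days), byrow = TRUE),
       XA = XA, XK = XK, ids = ids, n = n)
}

# ---- linearized marginal likelihood ----------------------------------------

# Mean, masked residual and masked Jacobian of the logistic mean in the
# individual deviations, all n x T.
nmm_parts <- function(dat, etaA, etaK, mu_b, EA, EK) {
  A <- etaA + EA
  Kv <- etaK + EK
  expo <- -Kv * dat$Tmat
  expo[expo > 300] <- 300
  Ebt <- exp(expo)
  D <- 1 + mu_b * Ebt
  F <- A / D
  R <- (dat$W - F) * dat$M
  JA <- dat$M / D
  JK <- (A * mu_b) * Ebt * dat$Tmat / D^2 * dat$M
  list(F = F, R = R, JA = JA, JK = JK)
}

# Penalized sum of squares only (cheap inner objective; no Jacobians).
nmm_pss <- function(dat, etaA, etaK, mu_b, EA, EK, s2, P11, P12, P22) {
  A <- etaA + EA
  expo <- -(etaK + EK) * dat$Tmat
  expo[expo > 300] <- 300
  R <- (dat$W - A / (1 + mu_b * exp(expo))) * dat$M
  rowSums(R^2) / s2 + P11 * EA^2 + 2 * P12 * EA * EK + P22 * EK^2
}

# FOCE core: conditional modes by damped Gauss-Newton, then the Gaussian
# marginal of the expansion. Returns the log-likelihood plus per-individual
# pieces the quadrature oracle reuses. `mode_start` (n x 2) warm-starts the
# mode search; the fitter threads the previous evaluation's modes through.
nmm_loglik_core <- function(dat, beta_A, beta_K, mu_b, Sigma, sigma2_e,
                            mode_iter = 60, mode_tol = 1e-9, details = FALSE,
                            mode_start = NULL) {
  n <- dat$n
  etaA <- drop(dat$XA %*% beta_A)
  etaK <- drop(dat$XK %*% beta_K)
  ni <- rowSums(dat$M)
  s2 <- sigma2_e
  if (!is.finite(mu_b) || mu_b <= 0 || s2 <= 0) return(list(loglik = -1e10))

  if (max(abs(Sigma)) == 0) {
    # exact i.i.d. Gaussian nonlinear-regression likelihood
    pp <- nmm_parts(dat, etaA, etaK, mu_b, rep(0, n), rep(0, n))
    ll <- -0.5 * (sum(ni) * log(2 * pi * s2) + sum(pp$R^2) / s2)
    if (!is.finite(ll)) ll <- -1e10
    return(list(loglik = ll, modes = matrix(0, n, 2), iid = TRUE))
  }
  detS <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  if (detS <= 0) { # ridge a semi-definite matrix into the interior
    ridge <- 1e-10 * (Sigma[1, 1] + Sigma[2, 2] + 1e-12)
    Sigma <- Sigma + diag(ridge, 2)
    detS <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  }
  P11 <- Sigma[2, 2] / detS; P22 <- Sigma[1, 1] / detS
  P12 <- -Sigma[1, 2] / detS
  scA <- sqrt(Sigma[1, 1]) + 1e-10
  scK <- sqrt(Sigma[2, 2]) + 1e-10

  if (!is.null(mode_start) && nrow(mode_start) == n &&
      all(is.finite(mode_start))) {
    EA <- mode_start[, 1]; EK <- mode_start[, 2]
  } else {
    EA <- numeric(n); EK <- numeric(n)
  }
  obj <- function(EA, EK) nmm_pss(dat, etaA, etaK, mu_b, EA, EK,
                                  s2, P11, P12, P22)
  o_cur <- obj(EA, EK)
  if (!all(is.finite(o_cur))) { # bad warm start: fall back to zero
    EA <- numeric(n); EK <- numeric(n); o_cur <- obj(EA, EK)
  }
  for (it in seq_len(mode_iter)) {
    pp <- nmm_parts(dat, etaA, etaK, mu_b, EA, EK)
    g1 <- rowSums(pp$JA * pp$R) / s2 - (P11 * EA + P12 * EK)
    g2 <- rowSums(pp$JK * pp$R) / s2 - (P12 * EA + P22 * EK)
    h11 <- rowSums(pp$JA^2) / s2 + P11
    h12 <- rowSums(pp$JA * pp$JK) / s2 + P12
    h22 <- rowSums(pp$JK^2) / s2 + P22
    dt <- pmax(h11 * h22 - h12^2, 1e-300)
    dA <- (h22 * g1 - h12 * g2) / dt
    dK <- (h11 * g2 - h12 * g1) / dt
    # damped update: halve the step where the penalized SSR worsens
    step <- rep(1, n)
    o_new <- o_cur
    for (h in 1:15) {
      o_new <- obj(EA + step * dA, EK + step * dK)
      bad <- o_new > o_cur + 1e-12
      if (!any(bad)) break
      step[bad] <- step[bad] / 2
    }
    freeze <- o_new > o_cur + 1e-12
    step[freeze] <- 0
    EA <- EA + step * dA
    EK <- EK + step * dK
    o_cur <- pmin(o_cur, o_new)
    if (max(abs(step * dA) / scA, abs(step * dK) / scK) < mode_tol) break
  }

  pp <- nmm_parts(dat, etaA, etaK, mu_b, EA, EK)
  U <- pp$R + pp$JA * EA + pp$JK * EK
  Saa <- rowSums(pp$JA^2); Sak <- rowSums(pp$JA * pp$JK); Skk <- rowSums(pp$JK^2)
  m11 <- s2 * P11 + Saa; m12 <- s2 * P12 + Sak; m22 <- s2 * P22 + Skk
  detM <- m11 * m22 - m12^2
  q1 <- rowSums(pp$JA * U); q2 <- rowSums(pp$JK * U)
  quad <- (rowSums(U^2) - (m22 * q1^2 - 2 * m12 * q1 * q2 + m11 * q2^2) / detM) / s2
  logdetV <- ni * log(s2) + log(detS) + log(detM) - 2 * log(s2)
  ll_i <- -0.5 * (ni * log(2 * pi) + logdetV + quad)
  ll <- sum(ll_i)
  if (!is.finite(ll)) return(list(loglik = -1e10))
  out <- list(loglik = ll, modes = cbind(EA, EK))
  if (details) {
    out$hess <- cbind(h11 = Saa / s2 + P11, h12 = Sak / s2 + P12,
                      h22 = Skk / s2 + P22)
    out$P <- c(P11, P12, P22); out$detS <- detS
    out$etaA <- etaA; out$etaK <- etaK
  }
  out
}

check_params <- function(params, dat) {
  need <- c("beta_A", "beta_K", "mu_b", "Sigma", "sigma2_e")
  if (!all(need %in% names(params))) {
    abort("`params` needs beta_A, beta_K, mu_b, Sigma, sigma2_e.")
  }
  if (length(params$beta_A) != ncol(dat$XA) ||
      length(params$beta_K) != ncol(dat$XK)) {
    abort("Coefficient lengths do not match the design (intercept, covariates[, snp]).")
  }
  S <- params$Sigma
  if (!is.matrix(S) || any(dim(S) != 2) || abs(S[1, 2] - S[2, 1]) > 1e-12 ||
      S[1, 1] < 0 || S[2, 2] < 0 || S[1, 2]^2 > S[1, 1] * S[2, 2] + 1e-12) {
    abort("`Sigma` must be a symmetric PSD 2x2 matrix.")
  }
  invisible(params)
}

#' Linearized marginal log-likelihood of the growth NMM
#'
#' Evaluates the first-order conditional (mode-expansion) approximation of
#' the marginal log-likelihood at given parameter values. With
#' `Sigma = 0` this is the exact i.i.d. Gaussian nonlinear-regression
#' log-likelihood.
#'
#' @param params List with `beta_A`, `beta_K` (coefficient vectors ordered
#'   intercept, covariates, then SNP if present), `mu_b`, `Sigma` (2x2) and
#'   `sigma2_e`.
#' @param phenotypes Phenotype tibble (`individual_id`, `day`, `weight_g`).
#' @param covariates Optional tibble: `individual_id` plus numeric columns
#'   entering both linear predictors (sex, PCs, ...).
#' @param snp Optional dosage vector (named by id, or in sorted-id order).
#' @param snp_target Where the SNP enters: "none", "both", "A" or "K".
#' @return The approximate marginal log-likelihood (scalar).
#' @seealso [quadrature_loglik()] for the quadrature oracle,
#'   [fit_nmm()] for maximization.
#' @export
marginal_loglik <- function(params, phenotypes, covariates = NULL,
                            snp = NULL, snp_target = "none") {
  snp_target <- match.arg(snp_target, c("none", "both", "A", "K"))
  dat <- nmm_data(phenotypes, covariates, snp, snp_target)
  check_params(params, dat)
  nmm_loglik_core(dat, params$beta_A, params$beta_K, params$mu_b,
                  params$Sigma, params$sigma2_e)$loglik
}

#' Adaptive Gauss-Hermite marginal log-likelihood (oracle)
#'
#' Numerically integrates each individual's conditional likelihood over the
#' bivariate deviation by tensor-product Gauss-Hermite quadrature, centered
#' and scaled at the conditional mode (adaptive). Reference implementation
#' for validating [marginal_loglik()]; quadratic cost in `n_nodes`, meant
#' for small fixtures.
#'
#' @inheritParams marginal_loglik
#' @param n_nodes Nodes per dimension (>= 5).
#' @return The quadrature marginal log-likelihood (scalar).
#' @export
quadrature_loglik <- function(params, phenotypes, covariates = NULL,
                              snp = NULL, snp_target = "none", n_nodes = 21) {
  snp_target <- match.arg(snp_target, c("none", "both", "A", "K"))
  if (n_nodes < 5) abort("Use at least 5 quadrature nodes per dimension.")
  dat <- nmm_data(phenotypes, covariates, snp, snp_target)
  check_params(params, dat)
  S <- params$Sigma
  s2 <- params$sigma2_e
  core <- nmm_loglik_core(dat, params$beta_A, params$beta_K, params$mu_b,
                          S, s2, details = TRUE)
  if (isTRUE(core$iid)) return(core$loglik) # degenerate integral at Sigma = 0

  gh <- pracma::gaussHermite(n_nodes)
  zg <- expand.grid(j = seq_len(n_nodes), k = seq_len(n_nodes))
  z1 <- gh$x[zg$j]; z2 <- gh$x[zg$k]
  lw <- log(gh$w)[zg$j] + log(gh$w)[zg$k] + z1^2 + z2^2

  P11 <- core$P[1]; P12 <- core$P[2]; P22 <- core$P[3]
  ldetS <- log(core$detS)
  total <- 0
  for (i in seq_len(dat$n)) {
    H <- matrix(c(core$hess[i, "h11"], core$hess[i, "h12"],
                  core$hess[i, "h12"], core$hess[i, "h22"]), 2, 2)
    Hinv <- solve(H)
    l11 <- sqrt(Hinv[1, 1]); l21 <- Hinv[2, 1] / l11
    l22 <- sqrt(max(Hinv[2, 2] - l21^2, 1e-300))
    eA <- core$modes[i, 1] + sqrt(2) * l11 * z1
    eK <- core$modes[i, 2] + sqrt(2) * (l21 * z1 + l22 * z2)
    A <- core$etaA[i] + eA
    Kv <- core$etaK[i] + eK
    obs <- dat$M[i, ] == 1
    tv <- dat$tvec[obs]
    w <- dat$W[i, obs]
    expo <- -outer(Kv, tv)
    expo[expo > 300] <- 300
    Fm <- A / (1 + params$mu_b * exp(expo))
    cll <- -0.5 * (length(tv) * log(2 * pi * s2) +
                     rowSums((matrix(w, length(A), length(tv), byrow = TRUE) - Fm)^2) / s2)
    lprior <- -log(2 * pi) - 0.5 * ldetS -
      0.5 * (P11 * eA^2 + 2 * P12 * eA * eK + P22 * eK^2)
    hval <- cll + lprior + lw
    mx <- max(hval)
    total <- total + log(2 * l11 * l22) + mx + log(sum(exp(hval - mx)))
  }
  total
}

# ---- maximum-likelihood fitting --------------------------------------------

#' Optimizer settings for [fit_nmm()]
#' @param max_iter Maximum BFGS iterations.
#' @param reltol Relative log-likelihood convergence tolerance.
#' @param mode_iter,mode_tol Inner Gauss-Newton settings for the
#'   conditional-mode search.
#' @return A list of control values.
#' @export
nmm_control <- function(max_iter = 200, reltol = 1e-8,
                        mode_iter = 60, mode_tol = 1e-9) {
  list(max_iter = max_iter, reltol = reltol,
       mode_iter = mode_iter, mode_tol = mode_tol)
}

# theta layout: beta_A, beta_K, log mu_b, log sdA, log sdK, atanh rho, log sde
theta_pack <- function(beta_A, beta_K, mu_b, Sigma, sigma2_e) {
  sdA <- sqrt(Sigma[1, 1]); sdK <- sqrt(Sigma[2, 2])
  rho <- if (sdA > 0 && sdK > 0) Sigma[1, 2] / (sdA * sdK) else 0
  rho <- min(max(rho, -0.999), 0.999)
  c(beta_A, beta_K, log(mu_b), log(max(sdA, 1e-8)), log(max(sdK, 1e-10)),
    atanh(rho), 0.5 * log(sigma2_e))
}

theta_unpack <- function(theta, pA, pK) {
  beta_A <- theta[seq_len(pA)]
  beta_K <- theta[pA + seq_len(pK)]
  rest <- theta[pA + pK + 1:5]
  sdA <- exp(rest[2]); sdK <- exp(rest[3]); rho <- tanh(rest[4])
  Sigma <- matrix(c(sdA^2, rho * sdA * sdK, rho * sdA * sdK, sdK^2), 2, 2)
  list(beta_A = beta_A, beta_K = beta_K, mu_b = exp(rest[1]),
       Sigma = Sigma, sigma2_e = exp(2 * rest[5]))
}

#' Fit the growth nonlinear mixed model by maximum likelihood
#'
#' Maximizes the linearized marginal log-likelihood over the fixed effects,
#' the unconstrained transform of \eqn{\Sigma} (log standard deviations and
#' atanh correlation) and \eqn{\log \sigma_e} by BFGS on a scaled parameter
#' vector. ML (not REML) is used throughout so likelihood-ratio tests
#' between models differing in fixed effects are valid. Failure to converge
#' is reported through the `converged` flag, never raised.
#'
#' @inheritParams marginal_loglik
#' @param snp_target Which model to fit: `"none"` (M0), `"both"` (M1),
#'   `"A"` (M2) or `"K"` (M3).
#' @param start Starting values: `NULL` (derived from a pooled logistic
#'   fit), a params list as in [marginal_loglik()], or a previous
#'   `nmm_fit` (its solution is reused, with zero inserted for a new SNP
#'   coefficient — the warm start the per-SNP scan relies on).
#' @param se Compute standard errors from the numerical Hessian.
#' @param control See [nmm_control()].
#' @return An `nmm_fit`: coefficient vectors `coef_A`/`coef_K`, `mu_b`,
#'   `Sigma`, `sigma2_e`, `logLik`, `n_params`, `n_obs`,
#'   `n_individuals`, `converged`, `iterations`, optional `se_A`/`se_K`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 40, n_snps = 2, sigma2_e = 30^2, seed = 3)
#' b <- simulate_trajectories(cfg)
#' fit <- fit_nmm(b$phenotypes)
#' glance(fit)
fit_nmm <- function(phenotypes, covariates = NULL, snp = NULL,
                    snp_target = c("none", "both", "A", "K"),
                    start = NULL, se = FALSE, control = nmm_control()) {
  snp_target <- match.arg(snp_target)
  if (snp_target != "none" && is.null(snp)) {
    abort("`snp` dosages required for snp_target != 'none'.")
  }
  dat <- nmm_data(phenotypes, covariates, snp, snp_target)
  pA <- ncol(dat$XA); pK <- ncol(dat$XK)

  if (is.null(start)) {
    pooled <- fit_growth(phenotypes, "logistic")
    if (!pooled$converged) abort("Pooled logistic fit failed; supply `start`.")
    A0 <- pooled$estimates[["A"]]; K0 <- pooled$estimates[["K"]]
    theta0 <- theta_pack(
      c(A0, rep(0, pA - 1)), c(K0, rep(0, pK - 1)),
      pooled$estimates[["b"]],
      matrix(c((0.08 * A0)^2, 0, 0, (0.1 * K0)^2), 2, 2),
      0.6 * pooled$sigma2
    )
  } else if (inherits(start, "nmm_fit")) {
    bA <- start$coef_A; bK <- start$coef_K
    if (length(bA) < pA) bA <- c(bA, rep(0, pA - length(bA)))
    if (length(bK) < pK) bK <- c(bK, rep(0, pK - length(bK)))
    theta0 <- theta_pack(bA[seq_len(pA)], bK[seq_len(pK)], start$mu_b,
                         start$Sigma, start$sigma2_e)
  } else {
    check_params(start, dat)
    theta0 <- theta_pack(start$beta_A, start$beta_K, start$mu_b,
                         start$Sigma, start$sigma2_e)
  }

  scale <- c(rep(50, pA), rep(0.005, pK), 0.05, 0.3, 0.3, 0.3, 0.1)
  cache <- new.env(parent = emptyenv())
  cache$modes <- NULL
  negll <- function(z) {
    p <- theta_unpack(theta0 + scale * z, pA, pK)
    res <- nmm_loglik_core(dat, p$beta_A, p$beta_K, p$mu_b, p$Sigma,
                           p$sigma2_e, control$mode_iter, control$mode_tol,
                           mode_start = cache$modes)
    if (!is.null(res$modes)) cache$modes <- res$modes
    -res$loglik
  }
  np <- length(theta0)
  fd_grad <- function(z) { # forward differences on the scaled parameters
    f0 <- negll(z)
    h <- 1e-6
    vapply(seq_len(np), function(i) {
      z2 <- z; z2[i] <- z2[i] + h
      (negll(z2) - f0) / h
    }, numeric(1))
  }
  opt <- optim(rep(0, np), negll, gr = fd_grad, method = "BFGS",
               control = list(maxit = control$max_iter,
                              reltol = control$reltol))
  theta_hat <- theta0 + scale * opt$par
  p <- theta_unpack(theta_hat, pA, pK)
  ll <- -opt$value
  converged <- opt$convergence == 0 && is.finite(ll) && ll > -1e9

  nm_A <- colnames(dat$XA); nm_K <- colnames(dat$XK)
  out <- list(
    coef_A = setNames(p$beta_A, nm_A), coef_K = setNames(p$beta_K, nm_K),
    mu_b = p$mu_b, Sigma = p$Sigma, sigma2_e = p$sigma2_e,
    logLik = ll, n_params = pA + pK + 5L,
    n_obs = sum(dat$M), n_individuals = dat$n,
    converged = converged, iterations = unname(opt$counts[1]),
    snp_target = snp_target
  )
  if (se) {
    H <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(V)) {
      sev <- sqrt(pmax(diag(V), 0)) * scale
      out$se_A <- setNames(sev[seq_len(pA)], nm_A)
      out$se_K <- setNames(sev[pA + seq_len(pK)], nm_K)
    }
  }
  structure(out, class = "nmm_fit")
}

#' @export
print.nmm_fit <- function(x, ...) {
  lab <- switch(x$snp_target, none = "M0 (no SNP)", both = "M1 (SNP on A and K)",
                A = "M2 (SNP on A)", K = "M3 (SNP on K)")
  cat("<nmm_fit> ", lab, if (!x$converged) "  [NOT converged]", "\n", sep = "")
  cat("  A-part: ", paste(sprintf("%s=%.4g", names(x$coef_A), x$coef_A),
                          collapse = ", "), "\n", sep = "")
  cat("  K-part: ", paste(sprintf("%s=%.4g", names(x$coef_K), x$coef_K),
                          collapse = ", "), "\n", sep = "")
  cat(sprintf("  mu_b %.4f | sd_A %.3g sd_K %.3g rho %.3f | sd_e %.3g\n",
              x$mu_b, sqrt(x$Sigma[1, 1]), sqrt(x$Sigma[2, 2]),
              x$Sigma[1, 2] / (sqrt(x$Sigma[1, 1] * x$Sigma[2, 2]) + 1e-300),
              sqrt(x$sigma2_e)))
  cat(sprintf("  logLik %.3f on %d parameters (%d obs, %d individuals)\n",
              x$logLik, x$n_params, x$n_obs, x$n_individuals))
  invisible(x)
}

#' @method tidy nmm_fit
#' @export
tidy.nmm_fit <- function(x, ...) {
  out <- bind_rows(
    tibble(part = "A", term = names(x$coef_A), estimate = unname(x$coef_A),
           std_error = if (!is.null(x$se_A)) unname(x$se_A) else NA_real_),
    tibble(part = "K", term = names(x$coef_K), estimate = unname(x$coef_K),
           std_error = if (!is.null(x$se_K)) unname(x$se_K) else NA_real_),
    tibble(part = "shape", term = "mu_b", estimate = x$mu_b, std_error = NA_real_),
    tibble(part = "variance",
           term = c("sigma2_A", "sigma_AK", "sigma2_K", "sigma2_e"),
           estimate = c(x$Sigma[1, 1], x$Sigma[1, 2], x$Sigma[2, 2], x$sigma2_e),
           std_error = NA_real_)
  )
  out
}

#' @method glance nmm_fit
#' @export
glance.nmm_fit <- function(x, ...) {
  tibble(snp_target = x$snp_target, logLik = x$logLik, n_params = x$n_params,
         n_obs = x$n_obs, n_individuals = x$n_individuals,
         converged = x$converged, iterations = x$iterations)
}

#' Likelihood-ratio test between nested NMM fits
#'
#' Statistic \eqn{2(\ell_{alt} - \ell_{null})} clamped at zero, referred to
#' a chi-square whose degrees of freedom equal the parameter-count
#' difference. If either fit failed to converge the test is marked
#' unavailable (`p_value = NA`).
#'
#' @param fit_alt,fit_null `nmm_fit` objects, null nested in alternative.
#' @return One-row tibble: statistic, df, p_value, available.
#' @export
lrt <- function(fit_alt, fit_null) {
  stopifnot(inherits(fit_alt, "nmm_fit"), inherits(fit_null, "nmm_fit"))
  df <- fit_alt$n_params - fit_null$n_params
  if (df < 1) abort("`fit_null` must be nested in `fit_alt` (fewer parameters).")
  if (!fit_alt$converged || !fit_null$converged) {
    return(tibble(statistic = NA_real_, df = df, p_value = NA_real_,
                  available = FALSE))
  }
  stat <- max(0, 2 * (fit_alt$logLik - fit_null$logLik))
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE), available = TRUE)
}
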
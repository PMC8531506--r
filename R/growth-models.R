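#' Growth-curve families
#'
#' The five classical fixed-shape growth functions, parameterized by the
#' mature weight `A` (asymptote, g), maturity rate `K` (per day) and
#' time-scale parameter `b`; Richards adds a shape parameter `m`:
#' \describe{
#'   \item{logistic}{\eqn{w(t) = A\,[1 + b e^{-Kt}]^{-1}}}
#'   \item{gompertz}{\eqn{w(t) = A \exp[-b e^{-Kt}]}}
#'   \item{brody}{\eqn{w(t) = A\,[1 - b e^{-Kt}]}}
#'   \item{von_bertalanffy}{\eqn{w(t) = A\,[1 - b e^{-Kt}]^{3}}}
#'   \item{richards}{\eqn{w(t) = A\,[1 - s\, b e^{-Kt}]^{m}} with sign
#'     \eqn{s = \pm 1}; with \eqn{s = -1, m = -1} this is the logistic.}
#' }
#'
#' @param name One of `"logistic"`, `"gompertz"`, `"brody"`,
#'   `"von_bertalanffy"`, `"richards"`.
#' @param sign Richards only: +1 (default) or -1, selecting the sign in
#'   front of the exponential term.
#' @return A `growth_family`: list with `name`, `par_names`, the mean
#'   function `fn(t, params)` and its analytic gradient
#'   `grad(t, params)` (matrix, one column per parameter).
#' @export
#' @examples
#' fam <- growth_family("logistic")
#' fam$fn(35, c(A = 2615.45, K = 0.054, b = 15.35))
growth_family <- function(name = c("logistic", "gompertz", "brody",
                                   "von_bertalanffy", "richards"),
                          sign = 1) {
  name <- match.arg(name)
  fam <- switch(name,
    logistic = list(
      par_names = c("A", "K", "b"),
      fn = function(t, p) p[["A"]] / (1 + p[["b"]] * exp(-p[["K"]] * t)),
      grad = function(t, p) {
        E <- exp(-p[["K"]] * t); D <- 1 + p[["b"]] * E
        cbind(A = 1 / D,
              K = p[["A"]] * p[["b"]] * t * E / D^2,
              b = -p[["A"]] * E / D^2)
      }
    ),
    gompertz = list(
      par_names = c("A", "K", "b"),
      fn = function(t, p) p[["A"]] * exp(-p[["b"]] * exp(-p[["K"]] * t)),
      grad = function(t, p) {
        E <- exp(-p[["K"]] * t); G <- exp(-p[["b"]] * E)
        cbind(A = G,
              K = p[["A"]] * G * p[["b"]] * t * E,
              b = -p[["A"]] * G * E)
      }
    ),
    brody = list(
      par_names = c("A", "K", "b"),
      fn = function(t, p) p[["A"]] * (1 - p[["b"]] * exp(-p[["K"]] * t)),
      grad = function(t, p) {
        E <- exp(-p[["K"]] * t)
        cbind(A = 1 - p[["b"]] * E,
              K = p[["A"]] * p[["b"]] * t * E,
              b = -p[["A"]] * E)
      }
    ),
    von_bertalanffy = list(
      par_names = c("A", "K", "b"),
      fn = function(t, p) p[["A"]] * (1 - p[["b"]] * exp(-p[["K"]] * t))^3,
      grad = function(t, p) {
        E <- exp(-p[["K"]] * t); B <- 1 - p[["b"]] * E
        cbind(A = B^3,
              K = 3 * p[["A"]] * B^2 * p[["b"]] * t * E,
              b = -3 * p[["A"]] * B^2 * E)
      }
    ),
    richards = list(
      par_names = c("A", "K", "b", "m"),
      fn = function(t, p) {
        p[["A"]] * (1 - sign * p[["b"]] * exp(-p[["K"]] * t))^p[["m"]]
      },
      grad = function(t, p) {
        E <- exp(-p[["K"]] * t); B <- 1 - sign * p[["b"]] * E
        cbind(A = B^p[["m"]],
              K = p[["A"]] * p[["m"]] * B^(p[["m"]] - 1) * sign * p[["b"]] * t * E,
              b = -p[["A"]] * p[["m"]] * B^(p[["m"]] - 1) * sign * E,
              m = p[["A"]] * B^p[["m"]] * log(B))
      }
    )
  )
  structure(c(list(name = name, sign = sign), fam), class = "growth_family")
}

#' Evaluate a growth curve
#'
#' @param family Family name or a [growth_family()] object.
#' @param t Days of age (vector).
#' @param A,K,b,m Curve parameters (`m` for Richards only).
#' @inheritParams growth_family
#' @return Mean weight (g) at each `t`.
#' @export
#' @examples
#' growth_curve("logistic", t = 35, A = 2615.45, K = 0.054, b = 15.35)
growth_curve <- function(family, t, A, K, b, m = NULL, sign = 1) {
  fam <- if (inherits(family, "growth_family")) family else growth_family(family, sign)
  p <- c(A = A, K = K, b = b)
  if (fam$name == "richards") {
    if (is.null(m)) abort("Richards needs the shape parameter `m`.")
    p <- c(p, m = m)
  }
  fam$fn(t, p)
}

# Log-linearized starting values per family: A0 = 1.1 max(w), b0/K0 from
# inverting b*exp(-K t) at the first and last time-point means.
growth_start <- function(fam, day, w) {
  A0 <- 1.1 * max(w)
  mw <- tapply(w, day, mean)
  tt <- as.numeric(names(mw))
  t1 <- tt[1]; t2 <- tt[length(tt)]
  w1 <- mw[[1]]; w2 <- mw[[length(tt)]]
  z <- function(wv) { # value of b*exp(-K t) implied at a time point
    switch(fam$name,
      logistic = A0 / wv - 1,
      gompertz = log(A0 / wv),
      brody = 1 - wv / A0,
      von_bertalanffy = 1 - (wv / A0)^(1 / 3),
      richards = A0 / wv - 1 # start from the logistic-like branch
    )
  }
  z1 <- max(z(w1), 1e-6); z2 <- max(z(w2), 1e-8)
  K0 <- max(log(z1 / z2) / (t2 - t1), 1e-4)
  b0 <- z1 * exp(K0 * t1)
  p <- c(A = A0, K = K0, b = b0)
  if (fam$name == "richards") p <- c(p, m = -1)
  p
}

#' Fit one growth-curve family to pooled records
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the family mean
#' function on all non-missing records pooled across individuals, with a
#' Gaussian residual. Used for family screening; the association stage
#' refits the selected family as a mixed model. The Richards family is
#' fitted with `sign = -1` and `m` free (its logistic-compatible branch)
#' unless a `sign` is given.
#'
#' @param phenotypes Phenotype tibble (`individual_id`, `day`, `weight_g`).
#' @param family Family name or [growth_family()].
#' @param start Optional named starting vector; defaults to log-linearized
#'   values.
#' @param sign Richards sign (see [growth_family()]); default -1 here.
#' @param tol Convergence tolerance passed to the optimizer.
#' @return A `growth_fit`: family, `estimates`, `sigma2` (ML residual
#'   variance), `logLik`, `n_params` (curve parameters + 1 for the residual
#'   variance), `n_obs`, `aic`, `bic`, `converged`. Non-convergence is
#'   reported via `converged = FALSE`, never raised.
#' @export
fit_growth <- function(phenotypes, family = "logistic", start = NULL,
                       sign = if (identical(family, "richards")) -1 else 1,
                       tol = 1e-8) {
  check_phenotypes(phenotypes)
  fam <- if (inherits(family, "growth_family")) family else growth_family(family, sign)
  dat <- phenotypes |> filter(!is.na(.data$weight_g))
  if (length(unique(dat$day)) < length(fam$par_names)) {
    abort("Need at least as many distinct time points as curve parameters.")
  }
  if (is.null(start)) start <- growth_start(fam, dat$day, dat$weight_g)

  fit <- tryCatch({
    res_fn <- function(p) {
      names(p) <- fam$par_names
      r <- dat$weight_g - fam$fn(dat$day, p)
      r[!is.finite(r)] <- 1e6
      r
    }
    jac_fn <- function(p) {
      names(p) <- fam$par_names
      J <- -fam$grad(dat$day, p)
      J[!is.finite(J)] <- 0
      J
    }
    nl <- minpack.lm::nls.lm(par = start, fn = res_fn, jac = jac_fn,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = tol, ptol = tol))
    list(par = setNames(coef(nl), fam$par_names),
         rss = sum(res_fn(coef(nl))^2),
         ok = nl$info %in% 1:4)
  }, error = function(e) NULL)

  n <- nrow(dat)
  if (is.null(fit) || !all(is.finite(fit$par)) || !fit$ok) {
    est <- if (is.null(fit)) setNames(rep(NA_real_, length(fam$par_names)),
                                      fam$par_names) else fit$par
    out <- list(family = fam$name, sign = fam$sign, estimates = est,
                sigma2 = NA_real_, logLik = NA_real_,
                n_params = length(fam$par_names) + 1L, n_obs = n,
                aic = NA_real_, bic = NA_real_, converged = FALSE)
    return(structure(out, class = "growth_fit"))
  }
  sigma2 <- fit$rss / n # ML variance estimate
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- length(fam$par_names) + 1L
  structure(list(
    family = fam$name, sign = fam$sign, estimates = fit$par, sigma2 = sigma2,
    logLik = ll, n_params = k, n_obs = n,
    aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll, converged = TRUE
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> ", x$family,
      if (!x$converged) " (NOT converged)" else "", "\n", sep = "")
  if (x$converged) {
    print(round(x$estimates, 5))
    cat("  logLik ", sprintf("%.2f", x$logLik),
        "  AIC ", sprintf("%.2f", x$aic),
        "  BIC ", sprintf("%.2f", x$bic), "\n", sep = "")
  }
  invisible(x)
}

#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(family = x$family, logLik = x$logLik, AIC = x$aic, BIC = x$bic,
         sigma2 = x$sigma2, n_params = x$n_params, n_obs = x$n_obs,
         converged = x$converged)
}

#' Fit every growth-curve family to the same records
#'
#' @inheritParams fit_growth
#' @param families Character vector of family names.
#' @return Named list of `growth_fit` objects.
#' @export
fit_growth_families <- function(phenotypes,
                                families = c("logistic", "gompertz", "brody",
                                             "von_bertalanffy", "richards"),
                                tol = 1e-8) {
  fits <- lapply(families, function(f) fit_growth(phenotypes, f, tol = tol))
  names(fits) <- families
  fits
}

#' Select the best-fitting growth family
#'
#' Among converged fits, picks the lowest AIC; ties break by lowest BIC,
#' then fewest parameters.
#'
#' @param fits List of `growth_fit` objects (e.g. from
#'   [fit_growth_families()]).
#' @return The winning `growth_fit`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "growth_fit")) fits <- list(fits)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) abort("No converged growth fit to select from.")
  tab <- purrr::map_dfr(conv, glance)
  ord <- order(tab$AIC, tab$BIC, tab$n_params)
  conv[[ord[1]]]
}
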
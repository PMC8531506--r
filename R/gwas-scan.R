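#' False-discovery-rate adjustment of scan p-values
#'
#' Default method is the Storey q-value: the null proportion \eqn{\pi_0}
#' is estimated on a lambda grid (0.05 to 0.90 in steps of 0.05) with a
#' cubic-spline smoother evaluated at the largest lambda, and
#' \eqn{q = \pi_0 \times} the Benjamini-Hochberg step-up value (the minimum
#' tail of \eqn{\pi_0 m p / rank}). With fewer than 100 p-values, or an
#' unstable \eqn{\pi_0} estimate (> 1 or < 0.1), the function falls back to
#' plain Benjamini-Hochberg with a warning. Missing p-values propagate to
#' missing q-values and do not enter the adjustment.
#'
#' @param p_values Numeric vector of p-values in [0, 1]; NA allowed.
#' @param method `"storey"` or `"BH"`.
#' @param pi0 Optional: force the null proportion (``pi0 = 1`` reproduces
#'   Benjamini-Hochberg exactly).
#' @return q-values, same length and order as the input.
#' @export
#' @examples
#' fdr_adjust(c(0.001, 0.01, 0.02, 0.8), method = "BH")
fdr_adjust <- function(p_values, method = c("storey", "BH"), pi0 = NULL) {
  method <- match.arg(method)
  if (length(p_values) == 0) return(numeric(0))
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  q <- rep(NA_real_, length(p_values))
  if (length(p) == 0) return(q)
  bh <- p.adjust(p, method = "BH")

  if (method == "BH" && is.null(pi0)) {
    q[ok] <- bh
    return(q)
  }
  if (is.null(pi0)) {
    pi0 <- estimate_pi0(p)
    if (is.na(pi0)) {
      warn("Storey pi0 estimate unstable (or m < 100); falling back to BH.")
      q[ok] <- bh
      return(q)
    }
  }
  q[ok] <- pmin(pi0 * bh, 1)
  q
}

# Storey's smoother estimate of the null proportion; NA signals "fall back".
estimate_pi0 <- function(p, lambda = seq(0.05, 0.90, by = 0.05)) {
  m <- length(p)
  if (m < 100) return(NA_real_)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- tryCatch(smooth.spline(lambda, pi0_l, df = 3), error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  pi0 <- predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 > 1 || pi0 < 0.1) return(NA_real_)
  pi0
}

#' Genome-wide scan of SNP effects on the growth-curve parameters
#'
#' Fits the null model M0 once, then for every SNP and requested
#' hypothesis refits the alternative nonlinear mixed model (warm-started at
#' the null solution) and performs the likelihood-ratio test:
#' M1 = SNP on both mature weight A and maturity rate K (2 df),
#' M2 = SNP on A only, M3 = SNP on K only (1 df each). q-values are
#' computed within each hypothesis family.
#'
#' Monomorphic SNPs are skipped with a reason; missing dosages are
#' mean-imputed per SNP before centering. Non-convergent per-SNP fits
#' yield missing p (and q) and are flagged.
#'
#' @param phenotypes QC'd phenotype tibble.
#' @param genotypes A [geno_matrix()] covering the phenotyped individuals.
#' @param covariates Optional covariate tibble (individual_id, sex,
#'   PC1..PC5, ...), entering both linear predictors.
#' @param hypotheses Subset of `c("M1", "M2", "M3")`.
#' @param q_method Passed to [fdr_adjust()].
#' @param m0 Optional pre-fitted null `nmm_fit` to reuse.
#' @param control See [nmm_control()].
#' @return A `gwas_scan` tibble: snp_id, chrom, pos, hypothesis, statistic,
#'   df, p_value, q_value, converged. Attributes: `m0` (the null fit) and
#'   `skipped` (tibble of skipped SNPs with reasons).
#' @export
run_scan <- function(phenotypes, genotypes, covariates = NULL,
                     hypotheses = c("M1", "M2", "M3"),
                     q_method = "storey", m0 = NULL,
                     control = nmm_control()) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  bad <- setdiff(hypotheses, c("M1", "M2", "M3"))
  if (length(bad)) abort(paste("Unknown hypotheses:", paste(bad, collapse = ", ")))
  ids <- sort(unique(phenotypes$individual_id))
  if (!all(ids %in% rownames(genotypes$dosages))) {
    abort("Every phenotyped individual needs a genotype row.")
  }
  D <- genotypes$dosages[ids, , drop = FALSE]
  targets <- c(M1 = "both", M2 = "A", M3 = "K")[hypotheses]

  if (is.null(m0)) {
    m0 <- fit_nmm(phenotypes, covariates, snp_target = "none", control = control)
  }
  if (!m0$converged) abort("Null model (M0) did not converge.")

  if (length(hypotheses) == 0) {
    out <- tibble(snp_id = character(), chrom = character(), pos = integer(),
                  hypothesis = character(), statistic = numeric(),
                  df = integer(), p_value = numeric(), q_value = numeric(),
                  converged = logical())
    return(structure(out, m0 = m0, skipped = tibble(), class = c("gwas_scan", class(out))))
  }

  skipped <- list()
  rows <- vector("list", ncol(D) * length(hypotheses))
  r <- 0
  for (j in seq_len(ncol(D))) {
    dos <- D[, j]
    if (anyNA(dos)) dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
    meta <- genotypes$snps[j, ]
    if (sd(dos) == 0) {
      skipped[[length(skipped) + 1]] <- tibble(snp_id = meta$snp_id,
                                               reason = "monomorphic")
      next
    }
    names(dos) <- ids
    for (h in seq_along(targets)) {
      alt <- fit_nmm(phenotypes, covariates, snp = dos,
                     snp_target = unname(targets[h]), start = m0,
                     control = control)
      tst <- lrt(alt, m0)
      r <- r + 1
      rows[[r]] <- tibble(
        snp_id = meta$snp_id, chrom = meta$chrom, pos = meta$pos,
        hypothesis = names(targets)[h], statistic = tst$statistic,
        df = tst$df, p_value = tst$p_value, converged = alt$converged
      )
    }
  }
  out <- bind_rows(rows[seq_len(r)])
  out <- out |>
    group_by(.data$hypothesis) |>
    mutate(q_value = fdr_adjust(.data$p_value, method = q_method)) |>
    ungroup() |>
    select("snp_id", "chrom", "pos", "hypothesis", "statistic", "df",
           "p_value", "q_value", "converged")
  structure(out, m0 = m0, skipped = bind_rows(skipped),
            class = c("gwas_scan", class(out)))
}

#' Significant SNPs of a scan at an FDR threshold
#'
#' @param records A scan tibble (from [run_scan()]) with a `q_value`
#'   column.
#' @param q_threshold Significance is `q_value < q_threshold`.
#' @param hypothesis Optional: restrict to one hypothesis (e.g. "M1").
#' @return The subset of records called significant.
#' @export
call_significant <- function(records, q_threshold = 0.05, hypothesis = NULL) {
  if (!"q_value" %in% names(records)) abort("`records` needs a q_value column.")
  out <- records |> filter(!is.na(.data$q_value), .data$q_value < q_threshold)
  if (!is.null(hypothesis)) out <- out |> filter(.data$hypothesis %in% !!hypothesis)
  out
}
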
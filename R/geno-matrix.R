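#' Construct a genotype matrix object
#'
#' Light container pairing an individuals-by-SNPs dosage matrix (0/1/2
#' copies of the alternate allele, `NA` for missing) with per-SNP metadata.
#'
#' @param dosages Numeric matrix, individuals in rows (rownames = sample
#'   ids), SNPs in columns (colnames = SNP ids); entries in {0, 1, 2, NA}.
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos` (1-based),
#'   one row per column of `dosages`, positions strictly increasing within
#'   chromosome.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, snps) {
  snps <- as_tibble(snps)
  stopifnot(is.matrix(dosages), nrow(snps) == ncol(dosages),
            all(c("snp_id", "chrom", "pos") %in% names(snps)))
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) abort("Dosages must be 0, 1, 2 or NA.")
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("ind%04d", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) colnames(dosages) <- snps$snp_id
  bad <- snps |>
    group_by(.data$chrom) |>
    summarise(mono = all(diff(.data$pos) > 0) || n() == 1) |>
    pull(.data$mono)
  if (!all(bad)) abort("Positions must be strictly increasing within chromosome.")
  structure(list(dosages = dosages, snps = snps), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$dosages), " individuals x ", ncol(x$dosages),
      " SNPs on ", length(unique(x$snps$chrom)), " chromosome(s); ",
      sum(is.na(x$dosages)), " missing call(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Sample ids of a genotype matrix
#' @param gm A [geno_matrix()].
#' @return Character vector of individual ids.
#' @export
sample_ids <- function(gm) rownames(gm$dosages)

#' Subset a genotype matrix by individuals and/or SNPs
#' @param x A [geno_matrix()].
#' @param i,j Individual and SNP indices (any form `[` accepts).
#' @param ... Unused.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  # no re-validation: a subset (or reordering) of valid metadata stays paired
  structure(list(dosages = x$dosages[i, j, drop = FALSE],
                 snps = x$snps[j, , drop = FALSE]),
            class = "geno_matrix")
}

#' Per-SNP summary of a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per SNP: id, chromosome, position,
#'   alternate-allele frequency, minor allele frequency, missing fraction
#'   and genotype counts.
#' @method tidy geno_matrix
#' @export
tidy.geno_matrix <- function(x, ...) {
  D <- x$dosages
  nobs <- colSums(!is.na(D))
  af <- colMeans(D, na.rm = TRUE) / 2
  x$snps |>
    mutate(
      n_called = nobs,
      alt_freq = af,
      maf = pmin(af, 1 - af),
      missing_frac = 1 - nobs / nrow(D),
      n_homref = colSums(D == 0, na.rm = TRUE),
      n_het = colSums(D == 1, na.rm = TRUE),
      n_homalt = colSums(D == 2, na.rm = TRUE)
    )
}
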
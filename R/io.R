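#' Read and write the long-format phenotype table
#'
#' Tab-separated with columns `individual_id`, `sex`, `day`, `weight_g`;
#' missing weights are written as `NA`.
#'
#' @param phenotypes Phenotype tibble.
#' @param path File path.
#' @return `read_phenotypes()` returns the tibble; `write_phenotypes()`
#'   returns `path` invisibly.
#' @name phenotype_io
#' @export
write_phenotypes <- function(phenotypes, path) {
  check_phenotypes(phenotypes)
  readr::write_tsv(phenotypes, path)
  invisible(path)
}

#' @rdname phenotype_io
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE)
  check_phenotypes(ph)
  ph
}

#' Write simulation ground truth as a sidecar TSV
#'
#' Per-individual realized values (sex, subpopulation, deviations eps_A and
#' eps_K, curve parameters A and K) of a simulated cohort.
#'
#' @param bundle A `cohort_bundle`.
#' @param path File path.
#' @export
write_truth <- function(bundle, path) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  readr::write_tsv(bundle$truth$individuals, path)
  invisible(path)
}

#' Write a genotype matrix as VCF
#'
#' One record per SNP with GT fields (`0/0`, `0/1`, `1/1`, `./.`), 1-based
#' positions, synthetic REF/ALT alleles A/G. Output is bgzip-compressed
#' when the path ends in `.gz`.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path (`.vcf` or `.vcf.gz`).
#' @export
write_genotypes_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  D <- gm$dosages
  gt_code <- c("0/0", "0/1", "1/1")
  GT <- matrix("./.", nrow = ncol(D), ncol = nrow(D),
               dimnames = list(NULL, rownames(D)))
  idx <- which(!is.na(t(D)), arr.ind = TRUE)
  GT[idx] <- gt_code[t(D)[idx] + 1]
  fix <- cbind(
    CHROM = gm$snps$chrom, POS = as.character(gm$snps$pos),
    ID = gm$snps$snp_id, REF = "A", ALT = "G", QUAL = ".",
    FILTER = "PASS", INFO = "."
  )
  contigs <- unique(gm$snps$chrom)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##contig=<ID=", contigs, ">"),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  v <- new(methods::getClass("vcfR", where = asNamespace("vcfR")),
           meta = meta, fix = fix, gt = cbind(FORMAT = "GT", GT))
  if (grepl("\\.gz$", path)) {
    vcfR::write.vcf(v, file = path)
  } else {
    tmp <- paste0(path, ".gz")
    vcfR::write.vcf(v, file = tmp)
    con <- gzfile(tmp, "rt")
    writeLines(readLines(con), path)
    close(con)
    unlink(tmp)
  }
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Accepts biallelic SNPs only; GT fields are converted to alternate-allele
#' dosages (`./.` to NA). Phased separators are tolerated.
#'
#' @param path VCF path (optionally gzipped).
#' @return A [geno_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 |
    nchar(fix[, "ALT"]) != 1
  if (any(multi)) {
    warn(paste(sum(multi), "non-biallelic-SNP record(s) dropped."))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0")] <- 0
  dos[gt %in% c("0/1", "1/0")] <- 1
  dos[gt %in% c("1/1")] <- 2
  keep <- !multi
  snps <- tibble(
    snp_id = ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                    paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"]),
                    fix[keep, "ID"]),
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"])
  )
  geno_matrix(t(dos[keep, , drop = FALSE]), snps)
}

#' Write a scan as TSV, plus Manhattan-ready coordinates
#'
#' @param scan A `gwas_scan` tibble.
#' @param path Output TSV path.
#' @param manhattan_path Optional second file with chrom, pos and
#'   -log10(p) per hypothesis.
#' @export
write_scan <- function(scan, path, manhattan_path = NULL) {
  readr::write_tsv(scan, path)
  if (!is.null(manhattan_path)) {
    man <- scan |>
      filter(!is.na(.data$p_value)) |>
      mutate(neg_log10_p = -log10(pmax(.data$p_value, 1e-300))) |>
      select("chrom", "pos", "hypothesis", "neg_log10_p")
    readr::write_tsv(man, manhattan_path)
  }
  invisible(path)
}

#' Write QTL intervals as TSV and BED
#'
#' The TSV keeps 1-based inclusive bounds; the BED export converts to
#' 0-based half-open.
#'
#' @param qtls A `qtl_set`.
#' @param path TSV path.
#' @param bed_path Optional BED path.
#' @export
write_qtls <- function(qtls, path, bed_path = NULL) {
  flat <- qtls |>
    mutate(snp_pos = purrr::map_chr(.data$snp_pos,
                                    ~ paste(.x, collapse = ",")),
           genes = if ("genes" %in% names(qtls)) {
             purrr::map_chr(.data$genes, ~ paste(.x, collapse = ","))
           } else NA_character_)
  readr::write_tsv(flat, path)
  if (!is.null(bed_path)) {
    bed <- tibble(chrom = qtls$chrom, start = qtls$start - 1L, end = qtls$end)
    readr::write_tsv(bed, bed_path, col_names = FALSE)
  }
  invisible(path)
}
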
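#' Cluster significant SNPs into QTL intervals
#'
#' Single-linkage clustering per chromosome: SNPs sorted by position join
#' one cluster while the gap to the previous SNP is at most `flank`
#' (100 kb by default). Each cluster's interval is
#' `[min(position) - flank, max(position) + flank]`, floored at 1, i.e. a
#' +/-100 kb window around each cluster of significant SNPs. Note this is
#' gap-based linkage, not interval merging: two clusters more than `flank`
#' apart keep distinct — possibly overlapping — intervals.
#'
#' @param significant_snps Tibble with columns `chrom` and `pos`
#'   (1-based bp); e.g. the output of [call_significant()].
#' @param flank Half-width of the window and the maximum within-cluster
#'   gap, in bp.
#' @return A `qtl_set` tibble: chrom, start, end, n_snps, snp_pos
#'   (list-column of member positions, sorted).
#' @export
#' @examples
#' snps <- tibble::tibble(chrom = "OCU2", pos = c(10501993, 10591957))
#' cluster_snps_to_qtls(snps)  # one QTL: gap 89,964 <= 100 kb
cluster_snps_to_qtls <- function(significant_snps, flank = 100000) {
  if (!all(c("chrom", "pos") %in% names(significant_snps))) {
    abort("`significant_snps` needs chrom and pos columns.")
  }
  out <- significant_snps |>
    distinct(.data$chrom, .data$pos) |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(cluster = cumsum(c(1, diff(.data$pos) > flank))) |>
    group_by(.data$chrom, .data$cluster) |>
    summarise(start = max(min(.data$pos) - flank, 1),
              end = max(.data$pos) + flank,
              n_snps = n(),
              snp_pos = list(sort(.data$pos)), .groups = "drop") |>
    select(-"cluster") |>
    arrange(.data$chrom, .data$start)
  class(out) <- c("qtl_set", class(out))
  out
}

#' Read gene models from GFF3 or BED
#'
#' Imports an annotation file and normalizes it to the tibble the QTL
#' helpers consume. GFF3 `gene`, `mRNA`/`transcript`, `exon` and UTR
#' features are kept; BED records are treated as gene spans (coordinates
#' converted to 1-based inclusive).
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @return Tibble: type, chrom, start, end, strand, gene_id, gene_name.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  is_bed <- is.null(df$type)
  keep_types <- c("gene", "mRNA", "transcript", "exon",
                  "five_prime_UTR", "three_prime_UTR", "UTR")
  out <- tibble(
    type = if (is_bed) "gene" else as.character(df$type),
    chrom = as.character(df$seqnames),
    start = df$start, end = df$end,
    strand = as.character(df$strand),
    gene_id = df$ID %||% df$name %||% NA_character_,
    gene_name = df$Name %||% df$gene_id %||% df$name %||% NA_character_
  )
  if (!is_bed) {
    # propagate gene identity to child features via Parent
    parent <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                     character(1))
    out$parent <- parent
    out <- out |> filter(.data$type %in% keep_types)
    gene_of <- setNames(out$gene_id, out$gene_id)
    tx <- out |> filter(.data$type %in% c("mRNA", "transcript"))
    tx_gene <- setNames(tx$parent, tx$gene_id)
    resolve <- function(id) {
      if (is.na(id)) return(NA_character_)
      seen <- character(0)
      while (!is.na(id) && id %in% names(tx_gene) && !(id %in% seen)) {
        seen <- c(seen, id); id <- tx_gene[[id]]
      }
      id
    }
    out <- out |>
      mutate(gene_id = ifelse(.data$type == "gene", .data$gene_id,
                              vapply(.data$parent, resolve, character(1)))) |>
      select(-"parent")
    genes <- out |> filter(.data$type == "gene")
    nm <- setNames(genes$gene_name, genes$gene_id)
    out <- out |>
      mutate(gene_name = ifelse(!is.na(.data$gene_id) & .data$gene_id %in% names(nm),
                                nm[.data$gene_id], .data$gene_name))
  }
  out
}

models_granges <- function(gene_models, types) {
  gm <- gene_models |> filter(.data$type %in% types)
  GenomicRanges::GRanges(
    seqnames = gm$chrom,
    ranges = IRanges::IRanges(start = gm$start, end = gm$end),
    gene_id = gm$gene_id, gene_name = gm$gene_name
  )
}

#' Classify SNP positions relative to gene models
#'
#' Hierarchical call on any overlapping transcript of either strand:
#' UTR beats exon beats intron (inside a gene span but outside exons)
#' beats intergenic.
#'
#' @param snps Tibble with `chrom` and `pos` (1-based).
#' @param gene_models Tibble from [read_gene_models()].
#' @return `snps` with a `location` column in
#'   `{"5'-UTR", "3'-UTR", "exon", "intron", "intergenic"}`.
#' @export
classify_snp_location <- function(snps, gene_models) {
  if (nrow(snps) == 0) return(mutate(snps, location = character(0)))
  pts <- GenomicRanges::GRanges(snps$chrom,
                                IRanges::IRanges(snps$pos, snps$pos))
  hit <- function(types) {
    if (!any(gene_models$type %in% types)) return(rep(FALSE, nrow(snps)))
    IRanges::overlapsAny(pts, models_granges(gene_models, types))
  }
  in5 <- hit("five_prime_UTR")
  in3 <- hit(c("three_prime_UTR", "UTR"))
  inex <- hit("exon")
  ingene <- hit(c("gene", "mRNA", "transcript"))
  snps |>
    mutate(location = dplyr::case_when(
      in5 ~ "5'-UTR",
      in3 ~ "3'-UTR",
      inex ~ "exon",
      ingene ~ "intron",
      TRUE ~ "intergenic"
    ))
}

#' Attach overlapping genes to QTL intervals
#'
#' A gene is reported for a QTL when the two spans intersect, 1-based
#' inclusive at both ends and strand-agnostic (a gene ending exactly at the
#' QTL start is reported).
#'
#' @param qtls A `qtl_set` from [cluster_snps_to_qtls()].
#' @param gene_models Tibble from [read_gene_models()] (only `gene` rows
#'   are used).
#' @return `qtls` with list-column `genes` (gene names, falling back to
#'   ids) and `n_genes`.
#' @export
overlap_genes <- function(qtls, gene_models) {
  genes <- gene_models |> filter(.data$type == "gene")
  if (nrow(genes) == 0 || nrow(qtls) == 0) {
    return(qtls |> mutate(genes = rep(list(character(0)), dplyr::n()),
                          n_genes = 0L))
  }
  qr <- GenomicRanges::GRanges(qtls$chrom,
                               IRanges::IRanges(qtls$start, qtls$end))
  gr <- models_granges(gene_models, "gene")
  ov <- GenomicRanges::findOverlaps(qr, gr)
  lab <- ifelse(is.na(genes$gene_name), genes$gene_id, genes$gene_name)
  glist <- split(lab[S4Vectors::subjectHits(ov)],
                 factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(qtls))))
  qtls |>
    mutate(genes = purrr::map(unname(glist), unique),
           n_genes = lengths(.data$genes))
}
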
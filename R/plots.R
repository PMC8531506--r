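#' Manhattan plot of a scan
#'
#' One panel per hypothesis, SNPs along cumulative genomic position,
#' -log10 p on the y axis, with a dashed line at the largest p still called
#' at the FDR threshold (drawn only when something is significant).
#'
#' @param object A `gwas_scan` tibble from [run_scan()].
#' @param q_threshold FDR threshold used for the significance line/marks.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gwas_scan
#' @export
autoplot.gwas_scan <- function(object, q_threshold = 0.05, ...) {
  dat <- object |>
    filter(!is.na(.data$p_value)) |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(.xwithin = .data$pos - min(.data$pos)) |>
    ungroup()
  offsets <- dat |>
    distinct(.data$chrom, .data$.xwithin) |>
    group_by(.data$chrom) |>
    summarise(span = max(.data$.xwithin) + 1) |>
    mutate(offset = cumsum(dplyr::lag(.data$span, default = 0)))
  dat <- dat |>
    left_join(offsets |> select("chrom", "offset"), by = "chrom") |>
    mutate(x = .data$.xwithin + .data$offset,
           y = -log10(pmax(.data$p_value, 1e-300)),
           significant = !is.na(.data$q_value) & .data$q_value < q_threshold)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_point(data = dat |> filter(.data$significant),
                        shape = 17, size = 1.6, colour = "red") +
    ggplot2::facet_wrap(~hypothesis, ncol = 1) +
    ggplot2::labs(x = "genomic position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  sig <- dat |> filter(.data$significant)
  if (nrow(sig) > 0) {
    thr <- sig |> group_by(.data$hypothesis) |>
      summarise(yline = min(.data$y))
    p <- p + ggplot2::geom_hline(data = thr,
                                 ggplot2::aes(yintercept = .data$yline),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot fitted growth curves over the observed weights
#'
#' @param phenotypes Phenotype tibble.
#' @param fits A single `growth_fit` or a list of them.
#' @return A ggplot object: per-day mean weights (points, +/- SD bars) and
#'   each family's fitted mean curve.
#' @export
plot_growth_fits <- function(phenotypes, fits) {
  if (inherits(fits, "growth_fit")) fits <- list(fits)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  obs <- describe_weights(phenotypes)
  grid <- seq(min(obs$day), max(obs$day), length.out = 200)
  curves <- purrr::map_dfr(fits, function(f) {
    fam <- growth_family(f$family, f$sign)
    tibble(family = f$family, day = grid,
           weight_g = fam$fn(grid, f$estimates))
  })
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 1, colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$weight_g,
                                    colour = .data$family)) +
    ggplot2::labs(x = "day of age", y = "body weight (g)",
                  colour = "family") +
    ggplot2::theme_minimal()
}

#' Scatter of the leading genotype principal components
#'
#' @param pca A `pca_covariates` object from [pca_genotypes()].
#' @param components Which two components to plot.
#' @param groups Optional per-individual grouping (e.g. subpopulation).
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, components = c(1, 2), groups = NULL) {
  stopifnot(inherits(pca, "pca_covariates"))
  cx <- paste0("PC", components[1]); cy <- paste0("PC", components[2])
  dat <- pca$scores
  if (!is.null(groups)) dat$group <- factor(groups)
  pct <- function(k) sprintf("%s (%.1f%%)", paste0("PC", k),
                             100 * pca$explained_fraction[k])
  g <- ggplot2::ggplot(dat, ggplot2::aes(x = .data[[cx]], y = .data[[cy]]))
  g <- if (is.null(groups)) g + ggplot2::geom_point() else
    g + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  g + ggplot2::labs(x = pct(components[1]), y = pct(components[2])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
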
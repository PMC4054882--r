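#' Bar chart of SNP counts at locus versus control orthologs
#'
#' One pair of bars per population: SNPs at locus-ortholog territory and
#' SNPs at control territory (the observed/expected pair of the
#' chi-square), optionally faceted by association class.
#'
#' @param tally An `assignment_tally` from [tally_assignments()].
#' @param by_class Facet by association class instead of pooling.
#' @return A ggplot object.
#' @export
plot_snp_counts <- function(tally, by_class = FALSE) {
  dat <- tally$by_population |>
    dplyr::filter(.data$region_group %in% c("loci", "control")) |>
    dplyr::mutate(region_group = factor(.data$region_group,
                                        levels = c("loci", "control")))
  if (!by_class) {
    dat <- dplyr::summarise(dat, n = sum(.data$n),
                            .by = c("population", "region_group"))
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$population, y = .data$n,
                                         fill = .data$region_group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(
      values = c(loci = "grey25", control = "grey70"),
      labels = c(loci = "locus orthologs", control = "control orthologs"),
      name = NULL
    ) +
    ggplot2::labs(x = NULL, y = "GWA-nominated SNPs") +
    ggplot2::theme_minimal()
  if (by_class) p <- p + ggplot2::facet_wrap(~assoc_class)
  p
}

#' Bar chart of SNP counts by carcinogen induction group
#'
#' SNPs at locus orthologs split by how the underlying rat locus was
#' identified (DMBA versus beta-estradiol induction); SNPs hitting
#' overlapping loci of both kinds count once in each group.
#'
#' @param tally An `assignment_tally`.
#' @return A ggplot object.
#' @export
plot_carcinogen_counts <- function(tally) {
  ggplot2::ggplot(tally$by_carcinogen,
                  ggplot2::aes(x = .data$carcinogen, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "induction group", y = "GWA-nominated SNPs at loci") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_report <- function(object, ...) {
  plot_snp_counts(object$tally, ...)
}

#' @exportS3Method ggplot2::autoplot
autoplot.assignment_tally <- function(object, ...) {
  plot_snp_counts(object, ...)
}
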
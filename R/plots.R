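#' Plot NTRK fusion prevalence by tumour type
#'
#' Horizontal bar chart of per-type prevalence from [prevalence_table()],
#' ordered by prevalence; the overall row is drawn as a dashed reference
#' line.
#'
#' @param prevalence Output of [prevalence_table()].
#' @return A ggplot object.
#' @export
plot_prevalence <- function(prevalence) {
  abort_cols(prevalence, c("tumor_type", "percent"), "prevalence table")
  per_type <- prevalence[prevalence$tumor_type != "overall", ]
  overall <- prevalence$percent[prevalence$tumor_type == "overall"]
  p <- ggplot2::ggplot(per_type, ggplot2::aes(
    x = stats::reorder(.data$tumor_type, .data$percent),
    y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data$n_positive, .data$n_total)),
      hjust = -0.1, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "NTRK fusion prevalence (%)") +
    ggplot2::theme_minimal()
  if (length(overall) == 1) {
    p <- p + ggplot2::geom_hline(yintercept = overall, linetype = "dashed")
  }
  p
}

#' Plot a biomarker comparison
#'
#' Boxplots of a biomarker by NTRK fusion status in a stratum, on the same
#' scale the corresponding test uses (log10(x + 1) for TMB, raw score for
#' PD-L1).
#'
#' @inheritParams biomarker_comparison
#' @return A ggplot object.
#' @export
plot_biomarker <- function(cohort, flags, biomarker = c("tmb", "pdl1"),
                           tumor_types = NULL, score_type = NULL) {
  biomarker <- match.arg(biomarker)
  df <- dplyr::mutate(cohort, status = ifelse(
    .data$specimen_id %in% positive_ids(flags),
    "NTRK fusion-positive", "NTRK fusion-negative"))
  if (!is.null(tumor_types)) {
    df <- dplyr::filter(df, .data$tumor_type %in% tumor_types)
  }
  if (biomarker == "tmb") {
    df$value <- log10(df$tmb + 1)
    ylab <- "log10(TMB + 1)"
  } else {
    if (!is.null(score_type)) {
      df <- dplyr::filter(df, .data$pdl1_score_type %in% score_type)
    }
    df$value <- df$pdl1_score
    ylab <- paste0("PD-L1 score",
                   if (!is.null(score_type)) sprintf(" (%s)", score_type))
  }
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot MSI-H proportions by NTRK status
#'
#' Bar chart of the MSI-H share among fusion-positive and fusion-negative
#' specimens from [msi_proportions()].
#'
#' @param msi Output of [msi_proportions()].
#' @return A ggplot object.
#' @export
plot_msi <- function(msi) {
  abort_cols(msi, c("ntrk_positive", "percent"), "MSI proportion table")
  msi$status <- ifelse(msi$ntrk_positive, "NTRK fusion-positive",
                       "NTRK fusion-negative")
  ggplot2::ggplot(msi, ggplot2::aes(x = .data$status, y = .data$percent)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data$n_msi_h, .data$n)), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "MSI-high (%)") +
    ggplot2::theme_minimal()
}

#' Plot the co-occurring alteration oncoprint
#'
#' Tile plot of the oncoprint matrix from [cooccurrence_summary()]: one row
#' per gene (ordered by alteration frequency), one column per
#' fusion-positive specimen, tiles coloured by alteration class (mixed
#' classes shown as their own category).
#'
#' @param cooccurrence Output of [cooccurrence_summary()].
#' @return A ggplot object.
#' @export
plot_oncoprint <- function(cooccurrence) {
  mat <- cooccurrence$matrix
  long <- tidyr::pivot_longer(mat, -"gene", names_to = "specimen_id",
                              values_to = "alteration")
  long$gene <- factor(long$gene, levels = rev(cooccurrence$gene_freq$gene))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$specimen_id, y = .data$gene,
                                     fill = .data$alteration)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_discrete(na.value = "grey92") +
    ggplot2::labs(x = "fusion-positive specimen", y = NULL,
                  fill = "alteration class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
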
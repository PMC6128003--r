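# ggplot2 visual summaries for the main result types.

#' Chromosome map of family genes
#'
#' Chromosomes as vertical bars with family genes marked at their
#' coordinates, the standard gene-family distribution figure.
#'
#' @param placements output of [place_genes()].
#' @return a ggplot object.
#' @export
plot_chromosome_map <- function(placements) {
  chrom <- placements |>
    group_by(.data$seq_id) |>
    summarise(len = max(.data$end), .groups = "drop")
  fam <- filter(placements, .data$is_family)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = chrom,
      ggplot2::aes(x = .data$seq_id, xend = .data$seq_id, y = 0,
                   yend = .data$len / 1e6),
      linewidth = 4, colour = "grey85", lineend = "round") +
    ggplot2::geom_segment(data = fam,
      ggplot2::aes(x = .data$seq_id, xend = .data$seq_id,
                   y = .data$start / 1e6, yend = .data$end / 1e6 + 0.01),
      linewidth = 4, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "position (Mb)") +
    ggplot2::theme_minimal()
}

#' Clustered expression heatmap
#'
#' Tile heatmap of a (normalized) expression matrix with rows in
#' dendrogram order.
#'
#' @param clustered output of [cluster_expression()].
#' @return a ggplot object.
#' @export
plot_expression_heatmap <- function(clustered) {
  m <- clustered$matrix
  long <- tidyr::pivot_longer(m, -"gene_id", names_to = "sample",
                              values_to = "z")
  long$gene_id <- factor(long$gene_id, levels = rev(clustered$order))
  long$sample <- factor(long$sample, levels = setdiff(names(m), "gene_id"))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$gene_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "row z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' qPCR fold-change bars
#'
#' Group-mean 2^(-ddCt) fold changes with standard-deviation error bars.
#'
#' @param folds output of [ddct()].
#' @return a ggplot object.
#' @export
plot_fold_change <- function(folds) {
  summ <- folds |>
    group_by(.data$gene, .data$group) |>
    summarise(mean_fold = mean(.data$fold), sd_fold = sd(.data$fold),
              .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$group, .data$mean_fold,
                                     fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_fold - .data$sd_fold,
      ymax = .data$mean_fold + .data$sd_fold), width = 0.2) +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(x = NULL, y = "fold change (2^-ddCt)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Physiology group comparison bars
#'
#' @param report output of [physiology_report()].
#' @return a ggplot object.
#' @export
plot_physiology <- function(report) {
  long <- tidyr::pivot_longer(report,
    c("control_mean", "silenced_mean"), names_to = "group",
    values_to = "mean")
  long$sd <- ifelse(long$group == "control_mean", report$control_sd[
    match(long$trait, report$trait)], report$silenced_sd[
      match(long$trait, report$trait)])
  long$group <- sub("_mean$", "", long$group)
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
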
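#' Manhattan-style plot of a BSR-seq association profile
#'
#' ED^k values per locus with the LOESS fit and the genome-wide
#' median + 3 SD threshold, facetted by chromosome.
#'
#' @param object A [bsa_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bsa_profile <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$informative, ]
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$ed_k),
                        colour = "steelblue", size = 0.3, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "black") +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        colour = "red", linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(ED^k)) +
    ggplot2::theme_minimal()
}

#' VIP / fold-change plot of differential lipid species
#'
#' @param object A [differential_species()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lipid_diff <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$vip,
                                   colour = .data$is_differential)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold-change (mutant / WT)", y = "VIP",
                  colour = "VIP > 1 & p < 0.05") +
    ggplot2::theme_minimal()
}

#' Bar plot of per-subclass intensities with significance tiers
#'
#' @param subclass_table Output of [subclass_tests()].
#' @param top_n Show the `top_n` subclasses by WT intensity (default 20).
#' @return A ggplot.
#' @export
plot_subclass_totals <- function(subclass_table, top_n = 20) {
  df <- dplyr::slice_max(subclass_table, .data$mean_wt, n = top_n)
  long <- tidyr::pivot_longer(
    dplyr::select(df, "subclass", "tier", WT = "mean_wt",
                  mutant = "mean_mutant"),
    cols = c("WT", "mutant"), names_to = "group", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$subclass,
                                                        -.data$intensity),
                                     y = .data$intensity,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = df[df$tier != "ns", ],
      ggplot2::aes(x = .data$subclass, label = .data$tier,
                   y = pmax(.data$mean_wt, .data$mean_mutant) * 1.05),
      inherit.aes = FALSE) +
    ggplot2::labs(x = "lipid subclass", y = "intensity", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Chain-length / saturation profile plot
#'
#' @param profiles Output of [chain_profiles()].
#' @return A ggplot facetted by subclass and dimension.
#' @export
plot_chain_profiles <- function(profiles) {
  long <- tidyr::pivot_longer(
    dplyr::select(profiles, "subclass", "dimension", "bin", "tier",
                  WT = "mean_wt", mutant = "mean_mutant"),
    cols = c("WT", "mutant"), names_to = "group", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$bin),
                                     y = .data$intensity,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$subclass, .data$dimension),
                        scales = "free") +
    ggplot2::labs(x = "total carbons / double bonds", y = "intensity",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of clustered differential species
#'
#' Tile heatmap of row z-scores with species in dendrogram leaf order.
#'
#' @param clust A [cluster_heatmap_order()] result.
#' @return A ggplot.
#' @export
plot_lipid_heatmap <- function(clust) {
  stopifnot(inherits(clust, "lipid_clust"))
  long <- tidyr::pivot_longer(clust$z, -"species", names_to = "sample",
                              values_to = "z")
  long$species <- factor(long$species, levels = clust$order)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$species,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
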
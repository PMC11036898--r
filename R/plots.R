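#' Alpha diversity by group
#'
#' Boxplots with jittered points of an alpha-diversity index per group.
#'
#' @param alpha Tibble from [alpha_diversity()].
#' @param meta Metadata with `sample_id` and `group`.
#' @param index `"shannon"`, `"pielou"` or `"observed"`.
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(alpha, meta, index = "shannon") {
  df <- dplyr::inner_join(alpha, tibble::as_tibble(meta), by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data[[index]],
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = index) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Principal-coordinate ordination of a distance matrix
#'
#' Classical multidimensional scaling (PCoA) of the beta-diversity
#' distances, coloured by group.
#'
#' @param dm Distance matrix from [beta_distance_matrix()].
#' @param meta Metadata with `sample_id` and `group`.
#' @return A ggplot object.
#' @export
plot_ordination <- function(dm, meta) {
  pc <- stats::cmdscale(stats::as.dist(dm), k = 2, eig = TRUE)
  rel <- pc$eig / sum(pmax(pc$eig, 0))
  df <- tibble::tibble(sample_id = rownames(dm),
                       pco1 = pc$points[, 1], pco2 = pc$points[, 2]) %>%
    dplyr::inner_join(tibble::as_tibble(meta), by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pco1, y = .data$pco2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::stat_ellipse(level = 0.9) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", 100 * rel[1]),
                  y = sprintf("PCo2 (%.1f%%)", 100 * rel[2])) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential-abundance results
#'
#' @param da Tibble from [differential_abundance()].
#' @param q_threshold,lfc_threshold Significance and effect cutoffs used to
#'   colour points.
#' @return A ggplot object.
#' @export
plot_volcano <- function(da, q_threshold = 0.05, lfc_threshold = 1) {
  df <- dplyr::mutate(da, significant = .data$q < q_threshold &
                        abs(.data$log2_fc) > lfc_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc, y = -log10(.data$q),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(q_threshold), linetype = 2,
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (EIM vs C)", y = "-log10 q") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Module-association forest plot
#'
#' Logistic slopes with 95% Wald intervals per co-abundance module.
#'
#' @param assoc Tibble from [associate_modules()].
#' @return A ggplot object.
#' @export
plot_module_associations <- function(assoc) {
  df <- dplyr::mutate(assoc,
                      lo = .data$slope - 1.96 * .data$se,
                      hi = .data$slope + 1.96 * .data$se)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slope,
                                   y = stats::reorder(.data$module, .data$slope),
                                   colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "log-odds per SD of log10 module abundance", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.mb_da <- function(object, ...) plot_volcano(object, ...)

#' @export
autoplot.mb_module_assoc <- function(object, ...) plot_module_associations(object, ...)
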